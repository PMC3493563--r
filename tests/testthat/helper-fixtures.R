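# shared fixtures: tiny deterministic cells and noiseless kinetics

noiseless <- function(rate = 0.5) {
  kinetics_params(rate_constant = rate, noise_sd = 0)
}

# three cells with hand-picked ground truth spanning the efflux boundary
toy_cells <- function() {
  tibble::tibble(
    cell_id = c("cell_a", "cell_b", "cell_c"),
    cl_i_mM = c(34.1, 13.2, critical_cli(equilibrium_context())),
    ksv_per_M = c(14.4, 14.4, 10),
    f0 = c(100, 80, 120)
  )
}

flat_trace <- function(n = 60, value = 100, dt = 0.5) {
  tibble::tibble(time_s = seq_len(n) * dt, fluorescence = rep(value, n))
}
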