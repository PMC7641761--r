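# Independent brute-force oracle for the Marko-Siggia interpolation:
# evaluates the residual on a fine grid of fractional extensions and
# returns the grid point closest to the sign change. Deliberately naive
# and separate from the package's bisection solver.
oracle_wlc_x <- function(force, P = 50, kT = 4.11, n_grid = 2e6) {
  x <- seq(0, 1 - 1e-9, length.out = n_grid)
  g <- x + 1 / (4 * (1 - x)^2) - 0.25 - force * P / kT
  i <- which(g >= 0)[1L]
  x[i]
}

# small noiseless trace with planted events for recovery tests
noiseless_trace <- function(kinetics, bridge_bp = 610, n_cycles = 30,
                            rate = 5, seed = 42) {
  simulate_trace(
    forceps_construct(bridge_length = bridge_bp),
    force_protocol(n_cycles = n_cycles, sampling_rate = rate),
    kinetics,
    noise_model(extension_noise_sd_high = 0, extension_noise_sd_low = 0),
    seed = seed
  )
}
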