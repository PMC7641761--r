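test_that("traces are byte-identical for identical inputs and seed", {
  pre <- condition_presets("DPK+LINP1_0.6kbp")
  pr <- force_protocol(n_cycles = 20, sampling_rate = 5)
  t1 <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 11)
  t2 <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 11)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$truth, t2$truth)
  t3 <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 12)
  expect_false(identical(t1$data$extension_nm, t3$data$extension_nm))
})

test_that("null kinetics give an empty truth log and baseline-only traces", {
  con <- forceps_construct(bridge_length = 610)
  kin <- kinetic_preset("null", p_specific = 0, tau_specific = 1,
                        p_nonspecific = 0)
  pr <- force_protocol(n_cycles = 8, sampling_rate = 5)
  tr <- simulate_trace(con, pr, kin,
                       noise_model(extension_noise_sd_high = 15,
                                   extension_noise_sd_low = 60),
                       seed = 3)
  expect_identical(nrow(tr$truth), 0L)
  hi <- tr$data$extension_nm[tr$data$force_pN == 1.4]
  expect_equal(mean(hi), tr$baseline_nm, tolerance = 1e-2)
  expect_equal(sd(hi), 15, tolerance = 0.2)
})

test_that("trace structure follows the protocol", {
  con <- forceps_construct(bridge_length = 610)
  kin <- kinetic_preset("k", p_specific = 0.3, tau_specific = 2,
                        p_nonspecific = 0.2)
  pr <- force_protocol(n_cycles = 6, sampling_rate = 4)
  tr <- simulate_trace(con, pr, kin, noise_model(), seed = 5)
  d <- tr$data
  expect_identical(nrow(d), 6L * (120L + 120L) * 4L)
  expect_setequal(unique(d$force_pN), c(0.01, 1.4))
  expect_equal(diff(d$time_s), rep(0.25, nrow(d) - 1L))
  # at most one event per cycle
  expect_lte(nrow(tr$truth), pr$n_cycles)
  expect_false(any(duplicated(tr$truth$cycle)))
})

test_that("a noiseless planted event is a rectangular deficit of exact size", {
  con <- forceps_construct(bridge_length = 6000)
  kin <- kinetic_preset("certain", p_specific = 1, tau_specific = 5,
                        amp_specific_sd = 0)
  pr <- force_protocol(n_cycles = 1, sampling_rate = 10)
  tr <- simulate_trace(con, pr,  kin,
                       noise_model(extension_noise_sd_high = 0,
                                   extension_noise_sd_low = 0),
                       seed = 9)
  expect_identical(nrow(tr$truth), 1L)
  expect_equal(tr$truth$amplitude_nm, expected_amplitude(con, 1.4))
  hi <- tr$data$extension_nm[tr$data$force_pN == 1.4]
  dur <- tr$truth$duration_s
  n_bound <- ceiling(dur * 10)
  expect_true(all(hi[seq_len(n_bound)] ==
                    tr$baseline_nm - tr$truth$amplitude_nm))
  expect_true(all(hi[(n_bound + 1):length(hi)] == tr$baseline_nm))
})

test_that("planted event fractions match the preset probabilities", {
  pre <- condition_presets("DPK+LINP1_0.6kbp")
  pr <- force_protocol(n_cycles = 4000, sampling_rate = 0.5)
  tr <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 21)
  n_sp <- sum(tr$truth$class == "specific")
  ci <- qbinom(c(0.005, 0.995), 4000, pre$kinetics$p_specific)
  expect_gte(n_sp, ci[1])
  expect_lte(n_sp, ci[2])
})

test_that("censoring in the truth log is consistent with the high phase", {
  kin <- kinetic_preset("slow", p_specific = 0.6, tau_specific = 80,
                        amp_specific_sd = 5)
  con <- forceps_construct(bridge_length = 610)
  pr <- force_protocol(n_cycles = 40, sampling_rate = 2)
  tr <- simulate_trace(con, pr, kin,
                       noise_model(extension_noise_sd_high = 0,
                                   extension_noise_sd_low = 0), seed = 8)
  expect_identical(tr$truth$censored, tr$truth$duration_s > 120)
  # censored events show no rupture step: deficit persists to phase end
  cen <- tr$truth[tr$truth$censored, ]
  expect_gt(nrow(cen), 0)
  for (i in seq_len(nrow(cen))) {
    cyc <- cen$cycle[i]
    hi_idx <- which(tr$data$force_pN == 1.4)
    cyc_hi <- hi_idx[(cyc - 1) * 240 + seq_len(240)]
    expect_true(all(tr$data$extension_nm[cyc_hi] <
                      tr$baseline_nm - cen$amplitude_nm[i] / 2))
  }
})

test_that("amplitude samples follow the two-component mixture", {
  pre <- condition_presets("DPK+LINP1_6kbp")
  expect_length(
    simulate_amplitude_sample(0, 0, pre$kinetics, pre$construct, seed = 1),
    0)
  amps <- simulate_amplitude_sample(95, 395, pre$kinetics, pre$construct,
                                    seed = 2)
  expect_length(amps, 490)
  comp <- attr(amps, "component")
  mu_sp <- expected_amplitude(pre$construct, 1.4)
  expect_lt(abs(mean(amps[comp == "specific"]) - mu_sp),
            3 * 101 / sqrt(95))
  expect_lt(abs(mean(amps[comp == "nonspecific"]) - 387),
            3 * 54 / sqrt(395))
  # zero spread collapses each component on its mean
  kin0 <- kinetic_preset("z", p_specific = 0.1, tau_specific = 1,
                         amp_specific_sd = 0, amp_nonspecific_sd = 0)
  a0 <- simulate_amplitude_sample(5, 5, kin0, pre$construct, seed = 3)
  expect_length(unique(a0), 2L)
})

test_that("binding curves evaluate the saturation models exactly", {
  # half-saturation at L = Kd, no noise
  bc <- simulate_binding_curve("single_site", kd = 1e-6,
                               titration = c(1e-8, 1e-6, 1e-4),
                               noise_frac = 0, seed = 1)
  expect_equal(bc$signal[2], 0.5)
  # Hill with h = 1 reduces to the single-site curve
  b1 <- simulate_binding_curve("hill", kd = 5e-7, hill_h = 1,
                               noise_frac = 0, seed = 1)
  b2 <- simulate_binding_curve("single_site", kd = 5e-7,
                               noise_frac = 0, seed = 1)
  expect_equal(b1$signal, b2$signal)
  # near-saturated top point for the weak-binding preset
  b3 <- simulate_binding_curve("single_site", kd = 740e-9,
                               noise_frac = 0, seed = 1)
  expect_gt(max(b3$signal), 0.99)
  expect_error(simulate_binding_curve("single_site", kd = -1, seed = 1),
               "positive")
})

test_that("invalid kinetic presets are rejected", {
  expect_error(kinetic_preset("bad", p_specific = 0.7, tau_specific = 1,
                              p_nonspecific = 0.5), "<= 1")
  expect_error(kinetic_preset("bad", p_specific = 0.1, tau_specific = 0),
               "tau_specific")
})
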