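test_that("segmentation yields one cycle per high phase", {
  pre <- condition_presets("DPK+LINP1_0.6kbp")
  pr <- force_protocol(n_cycles = 5, sampling_rate = 4)
  tr <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 2)
  cy <- segment_cycles(tr)
  expect_identical(nrow(cy), 5L)
  expect_true(all(cy$high_start < cy$high_end))
  expect_true(all(cy$baseline_extension > 0))

  # a constant-force trace has no cycles
  flat <- list(data = data.frame(time_s = 0:9 / 4,
                                 extension_nm = rnorm(10),
                                 force_pN = rep(1.4, 10)))
  expect_identical(nrow(segment_cycles(flat)), 0L)
})

test_that("baseline matches the open state on noiseless traces", {
  kin0 <- kinetic_preset("null", p_specific = 0, tau_specific = 1)
  tr <- noiseless_trace(kin0, n_cycles = 4)
  cy <- segment_cycles(tr)
  expect_equal(cy$baseline_extension[1], tr$baseline_nm, tolerance = 1e-6)
  hi <- tr$data$extension_nm[tr$data$force_pN == 1.4]
  expect_true(all(abs(hi - cy$baseline_extension[1]) < 1e-6))
})

test_that("segmentation is unaffected by drift", {
  pre <- condition_presets("DPK+LINP1_0.6kbp")
  pr <- force_protocol(n_cycles = 6, sampling_rate = 4)
  tr <- simulate_trace(pre$construct, pr, pre$kinetics,
                       noise_model(drift_rate = 0.5), seed = 2)
  expect_identical(nrow(segment_cycles(tr)), 6L)
  # per-cycle baseline tracks the drift while global does not
  cyc <- segment_cycles(tr, baseline = "per_cycle")
  expect_gt(cyc$baseline_extension[6], cyc$baseline_extension[1])
})

test_that("noiseless planted events are recovered exactly", {
  kin <- kinetic_preset("mix", p_specific = 0.5, tau_specific = 4,
                        p_nonspecific = 0.3, amp_specific_sd = 10)
  tr <- noiseless_trace(kin, n_cycles = 40, rate = 5, seed = 14)
  cy <- segment_cycles(tr)
  ev <- detect_events(tr, cy, noise_sd = 1)
  expect_identical(nrow(ev), nrow(tr$truth))
  m <- merge(ev, tr$truth, by.x = "cycle_index", by.y = "cycle")
  expect_identical(m$censored.x, m$censored.y)
  ok <- !m$censored.x
  expect_true(all(abs(m$delta_l_nm - m$amplitude_nm) < 1))
  expect_true(all(abs(m$t_synapsis_s[ok] - m$duration_s[ok]) <= 1 / 5))
})

test_that("a flat noiseless trace contains zero events", {
  kin0 <- kinetic_preset("null", p_specific = 0, tau_specific = 1)
  tr <- noiseless_trace(kin0, n_cycles = 5)
  ev <- detect_events(tr, segment_cycles(tr), noise_sd = 1)
  expect_identical(nrow(ev), 0L)
})

test_that("detection recovers planted events at realistic noise", {
  pre <- condition_presets("DPK+LINP1_6kbp")
  pr <- force_protocol(n_cycles = 600, sampling_rate = 5)
  tr <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 31)
  cy <- segment_cycles(tr)
  ev <- detect_events(tr, cy)
  detected <- intersect(ev$cycle_index, tr$truth$cycle)
  expect_gte(length(detected) / nrow(tr$truth), 0.95)
  false_pos <- setdiff(ev$cycle_index, tr$truth$cycle)
  expect_lte(length(false_pos) / nrow(cy), 0.02)
  # amplitudes reproduce the planted values to within measurement noise;
  # the top-quartile-median open-state estimate sits ~1.15 noise-sd above
  # the true baseline on noisy data, so allow two noise-sd of slack
  m <- merge(ev, tr$truth, by.x = "cycle_index", by.y = "cycle")
  expect_lt(median(abs(m$delta_l_nm - m$amplitude_nm)), 30)
})

test_that("events must satisfy the basic count invariants", {
  pre <- condition_presets("DPK+PAXX_0.6kbp")
  pr <- force_protocol(n_cycles = 300, sampling_rate = 4)
  tr <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 17)
  cy <- segment_cycles(tr)
  ev <- detect_events(tr, cy)
  ev <- classify_events(ev, expected_amplitude(pre$construct, 1.4),
                        pre$kinetics$amp_specific_sd)
  n_syn <- sum(ev$specificity == "specific")
  expect_lte(n_syn, nrow(ev))
  expect_lte(nrow(ev), nrow(cy))
  expect_true(all(ev$delta_l_nm > 0))
  expect_false(any(duplicated(ev$cycle_index)))
  ok <- !ev$censored
  expect_true(all(ev$t_synapsis_s[ok] >= 0 & ev$t_synapsis_s[ok] <= 120))
  expect_true(all(is.na(ev$t_synapsis_s[!ok])))
})

test_that("the 3-sigma amplitude rule separates the two peaks", {
  ev <- data.frame(cycle_index = 1:3,
                   delta_l_nm = c(1737, 387, 1754.193),
                   t_synapsis_s = c(5, 1, 2), censored = FALSE,
                   specificity = NA_character_)
  class(ev) <- c("end_binding_events", "data.frame")
  out <- classify_events(ev, expected = 1754.193, sigma = 101)
  expect_identical(out$specificity,
                   c("specific", "nonspecific", "specific"))
  # exactly at the 3-sigma boundary is still specific
  b <- classify_events(ev, expected = 1737 + 3 * 101, sigma = 101)
  expect_identical(b$specificity[1], "specific")
  # idempotent
  expect_identical(classify_events(out, 1754.193, 101), out)
  expect_error(classify_events(ev, expected = -1, sigma = 101), "expected")
  expect_error(classify_events(ev, expected = 1700, sigma = 0), "sigma")
})

test_that("censored events are detected, flagged and excluded from durations", {
  kin <- kinetic_preset("slow", p_specific = 0.5, tau_specific = 100,
                        amp_specific_sd = 5)
  tr <- noiseless_trace(kin, n_cycles = 30, rate = 2, seed = 23)
  cy <- segment_cycles(tr)
  ev <- detect_events(tr, cy, noise_sd = 1)
  ev <- classify_events(ev, expected_amplitude(tr$construct, 1.4), 15)
  m <- merge(ev, tr$truth, by.x = "cycle_index", by.y = "cycle")
  expect_identical(m$censored.x, m$censored.y)
  cen <- ev[ev$censored, ]
  expect_gt(nrow(cen), 0)
  # censored specific events still count as synaptic ...
  expect_true(all(cen$specificity == "specific"))
  # ... but contribute no duration
  expect_true(all(is.na(cen$t_synapsis_s)))
})

test_that("detection rejects invalid noise", {
  pre <- condition_presets("DPK+LINP1_0.6kbp")
  pr <- force_protocol(n_cycles = 2, sampling_rate = 2)
  tr <- simulate_trace(pre$construct, pr, pre$kinetics, noise_model(),
                       seed = 1)
  cy <- segment_cycles(tr)
  expect_error(detect_events(tr, cy, noise_sd = 0), "noise_sd")
  empty <- cy[0, ]
  class(empty) <- class(cy)
  expect_error(detect_events(tr, empty), "nonempty")
})
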