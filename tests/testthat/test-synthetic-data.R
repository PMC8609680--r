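test_that("zero-noise phantoms reproduce planted intensities exactly and seeds are reproducible", {
  truth <- small_truth(noise_sd = 0)
  ph <- gen_nm_phantom(truth, seed = 1)
  for (k in seq_len(nrow(ph$rois))) {
    st <- roi_stats(ph$volume, ph$rois[k, ])
    expect_identical(st$mean_si, truth$si_map[[ph$rois$structure[k]]])
    expect_identical(st$sd_si, 0)
  }
  # background untouched away from the discs
  expect_identical(ph$volume$intensities[1, 1, 1], truth$si_map[["background"]])

  truth_n <- small_truth(noise_sd = 10)
  a <- gen_nm_phantom(truth_n, seed = 42)
  b <- gen_nm_phantom(truth_n, seed = 42)
  c <- gen_nm_phantom(truth_n, seed = 43)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_false(identical(a$volume$intensities, c$volume$intensities))
  expect_identical(a$rois, b$rois)
})

test_that("planted phantom truth stores the exact contrast and rejects bad geometry", {
  truth <- small_truth(noise_sd = 10)
  expect_identical(truth$true_cnr[["LC"]], (120 - 100) / 10)
  expect_identical(truth$true_cnr[["SN"]], (110 - 90) / 10)
  # LC disc overlapping the PT disc is rejected
  expect_error(
    small_truth(lc_centers = list(left = c(32.5, 43), right = c(41.5, 22.5))),
    "overlap")
  # discs must fit inside the volume
  expect_error(small_truth(cp_center = c(2, 2)), "inside")
})

test_that("noisy phantoms recover the planted CNR in Monte-Carlo mean", {
  truth <- small_truth(noise_sd = 10)
  ests <- vapply(1:300, function(s) phantom_cnr_estimate(truth, s), numeric(1))
  expect_lt(abs(mean(ests) - truth$true_cnr[["LC"]]) / truth$true_cnr[["LC"]],
            0.05)
})

test_that("oscillator generator is deterministic and hits the synchrony limits", {
  p <- oscillator_params(coupling = 1, seed = 7)
  expect_identical(gen_oscillator_bold(p)$values, gen_oscillator_bold(p)$values)

  # coupling -> infinity limit: identical phases and frequencies, no noise
  full <- oscillator_params(n_nodes = 33, coupling = 0,
                            natural_freqs = rep(0.055, 33),
                            init_phases = rep(0.3, 33),
                            obs_noise_sd = 0, seed = 1)
  b <- gen_oscillator_bold(full)
  expect_equal(max(abs(sweep(b$values, 2, b$values[1, ]))), 0)
  s <- somatomotor_sync(bandpass_ts(detrend_ts(b)))
  expect_equal(s$mean_sync, 1, tolerance = 1e-9)
})

test_that("uncoupled oscillators match the closed-form solution and stay incoherent", {
  freqs <- seq(0.04, 0.07, length.out = 33)
  th0 <- seq(-3, 3, length.out = 33)
  p <- oscillator_params(coupling = 0, natural_freqs = freqs,
                         init_phases = th0, obs_noise_sd = 0, seed = 2)
  b <- gen_oscillator_bold(p)
  # with K = 0 the fixed-step integration is exact: theta(t) = theta0 + w t
  t_s <- (0:(p$n_timepoints - 1)) * p$sampling_interval
  expected <- sapply(t_s, function(tt) th0 + 2 * pi * freqs * tt)
  expect_equal(unname(b$values), sin(expected), tolerance = 1e-8)
  # downstream synchronization is low for spread frequencies
  sync <- somatomotor_sync(bandpass_ts(detrend_ts(drop_initial_volumes(b))))
  expect_lt(sync$mean_sync, 0.5)
})

test_that("mean synchronization rises with coupling strength", {
  ks <- c(0, 2)
  m <- vapply(ks, function(K) {
    mean(vapply(1:10, function(s) {
      b <- gen_oscillator_bold(oscillator_params(coupling = K,
                                                 obs_noise_sd = 0.05,
                                                 seed = s))
      somatomotor_sync(bandpass_ts(detrend_ts(drop_initial_volumes(b))))$mean_sync
    }, numeric(1)))
  }, numeric(1))
  expect_gt(m[2], m[1])
})

test_that("cohort generator is deterministic, valid, and plants the partial correlation", {
  p <- cohort_params(seed = 11)
  co <- gen_cohort(p)
  expect_identical(co, gen_cohort(p))
  expect_equal(nrow(co), 57)
  expect_true(all(co$updrs3_off > 0) && all(co$updrs3_on >= 0))
  expect_true(all(co$sync_off >= 0 & co$sync_off <= 1))
  expect_true(all(co$sync_on >= 0 & co$sync_on <= 1))

  # null case: estimated partial correlation centred on zero
  r0 <- vapply(1:200, function(s) {
    co <- gen_cohort(cohort_params(target_r = 0, seed = s))
    rate <- rate_of_change_updrs(co$updrs3_off, co$updrs3_on)
    partial_correlation(co$cnr_lc, rate,
                        co[, c("age", "duration_med", "ledd")])$r
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.03)

  # large-n convergence of the planted value
  big <- gen_cohort(cohort_params(n_subjects = 5000, seed = 3))
  rate <- rate_of_change_updrs(big$updrs3_off, big$updrs3_on)
  r_hat <- partial_correlation(big$cnr_lc, rate,
                               big[, c("age", "duration_med", "ledd")])$r
  expect_equal(r_hat, 0.42, tolerance = 0.05)
})

test_that("infeasible cohort parameters are rejected", {
  expect_error(cohort_params(target_r = 1.2), "target_r")
  expect_error(cohort_params(n_subjects = 5), "n_subjects")
  expect_error(cohort_params(rate_mean = 1.5), "infeasible")
})
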