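test_that("track simulation matches the stated sampling and statistics", {
  det <- detector_config()
  tr <- simulate_tracks(motion_model(0.01, 0.01), det, n_spots = 5, seed = 1)
  expect_equal(sum(tr$data$spot_id == 1), 121)  # 3 s at 25 ms/frame
  steps <- diff(tr$data$t[tr$data$spot_id == 1])
  expect_true(all(abs(steps - 0.025) < 1e-12))

  # zero-diffusivity model: all tracks constant, all excluded as motionless
  tr0 <- simulate_tracks(motion_model(0, 0), det, n_spots = 10, seed = 2)
  expect_true(all(tr0$data$theta == 0))
  flt <- filter_tracks(tr0)
  expect_equal(nrow(flt$kept$spots), 0)

  # law of large numbers: variance of 1-frame increments = 2 D dt within 5%
  long <- simulate_tracks(motion_model(0.01, 0.004),
                          detector_config(track_duration = 250),
                          n_spots = 1, seed = 3)
  expect_lt(abs(var(diff(long$data$theta)) / (2 * 0.01 * 0.025) - 1), 0.05)
  expect_lt(abs(var(diff(long$data$chi)) / (2 * 0.004 * 0.025) - 1), 0.05)

  # seeded reproducibility
  a <- simulate_tracks(motion_model(0.02, 0.008, 0.2), det, 50, seed = 9)
  b <- simulate_tracks(motion_model(0.02, 0.008, 0.2), det, 50, seed = 9)
  expect_identical(a, b)
})

test_that("filtering excludes exactly the constructed static and edge spots", {
  det <- detector_config(edge_fraction = 0.1)
  tr <- simulate_tracks(motion_model(0.02, 0.008, static_fraction = 0.3),
                        det, n_spots = 200, seed = 4)
  flt <- filter_tracks(tr)
  expect_setequal(flt$excluded$spots$spot_id,
                  union(tr$truth$static_ids, tr$truth$edge_ids))

  # partition property: exhaustive and disjoint, over fuzzed inputs
  for (s in 1:5) {
    trf <- simulate_tracks(motion_model(runif(1, 0, 0.03), 0.01,
                                        static_fraction = runif(1, 0, 0.5)),
                           det, n_spots = 50, seed = 100 + s)
    f <- filter_tracks(trf)
    expect_setequal(c(f$kept$spots$spot_id, f$excluded$spots$spot_id),
                    trf$spots$spot_id)
    expect_length(intersect(f$kept$spots$spot_id, f$excluded$spots$spot_id), 0)
  }

  # threshold 0: only edge tracks go
  det0 <- detector_config(motionless_threshold = 0, edge_fraction = 0.1)
  tr0 <- simulate_tracks(motion_model(0, 0, static_fraction = 1), det0,
                         n_spots = 50, seed = 5)
  f0 <- filter_tracks(tr0)
  expect_setequal(f0$excluded$spots$spot_id, tr0$truth$edge_ids)
})

test_that("MSD: closed forms and Brownian linearity", {
  det <- detector_config()
  # deterministic ramp theta = v t: MSD = v^2 tau^2 exactly
  ramp <- simulate_tracks(motion_model(0, 0, drift = c(0.05, 0)), det,
                          n_spots = 3, seed = 1)
  msd <- compute_msd(ramp, "theta")
  expect_equal(msd$msd, (0.05 * msd$lag)^2, tolerance = 1e-12)

  # constant track: MSD identically zero
  const <- simulate_tracks(motion_model(0, 0), det, n_spots = 2, seed = 1)
  expect_true(all(compute_msd(const, "theta")$msd == 0))

  # pure diffusion, 500 tracks: slope = 2 D within 10%, linear (R2 > 0.99)
  tr <- simulate_tracks(motion_model(0.012, 0.005), det, n_spots = 500,
                        seed = 6)
  msd_th <- compute_msd(tr, "theta")
  est <- estimate_diffusivity(msd_th, n_lags = 8)
  expect_lt(abs(est$d / 0.012 - 1), 0.1)
  r2 <- summary(lm(msd ~ lag, data = msd_th[1:8, ]))$r.squared
  expect_gt(r2, 0.99)

  expect_error(compute_msd(tr, "theta", max_lag = 0.01), "lag")
})

test_that("displacement distributions: moments, symmetry, delta case", {
  det <- detector_config()
  tr <- simulate_tracks(motion_model(0.01, 0.01), det, n_spots = 200,
                        seed = 7)
  dd <- displacement_distribution(tr, "theta", lag = 0.2)
  expect_equal(sum(dd$density), 1, tolerance = 1e-12)
  # Gaussian oracle: sd = sqrt(2 D lag) within 5% at >= 1e4 pairs
  expect_gte(dd$n, 1e4)
  expect_lt(abs(sd(dd$samples_mrad) / 1000 / sqrt(2 * 0.01 * 0.2) - 1), 0.05)
  # symmetry for drift-free motion
  skew <- mean(((dd$samples_mrad - mean(dd$samples_mrad)) /
                  sd(dd$samples_mrad))^3)
  expect_lt(abs(skew), 0.1)

  # static tracks kept under threshold 0: delta at zero
  det0 <- detector_config(motionless_threshold = 0, edge_fraction = 0)
  tr0 <- simulate_tracks(motion_model(0, 0, static_fraction = 1), det0,
                         n_spots = 10, seed = 8)
  dd0 <- displacement_distribution(tr0, "theta", lag = 0.2)
  ctr_bin <- findInterval(0, dd0$bin_edges)
  expect_equal(dd0$density[ctr_bin], 1)

  expect_error(displacement_distribution(tr, "theta", lag = 0.21), "multiple")
})

test_that("difference histograms show the broadened-WT sign pattern", {
  det <- detector_config()
  wt <- simulate_tracks(motion_model(0.02, 0.008), det, 300, seed = 10)
  mut <- simulate_tracks(motion_model(0.008, 0.008), det, 300, seed = 11)
  dwt <- displacement_distribution(wt, "theta")
  dmut <- displacement_distribution(mut, "theta")
  dh <- difference_histogram(dwt, dmut)
  expect_equal(sum(dh$values), 0, tolerance = 1e-12)
  # negative centre (Mut more peaked), positive tails (WT broader)
  mids <- (dh$bin_edges[-1] + dh$bin_edges[-length(dh$bin_edges)]) / 2
  expect_lt(sum(dh$values[abs(mids) < 2]), 0)
  expect_gt(sum(dh$values[abs(mids) > 5]), 0)

  # identical inputs: all-zero histogram
  self <- difference_histogram(dwt, dwt)
  expect_true(all(self$values == 0))

  dd_other <- displacement_distribution(mut, "theta",
                                        bin_edges = seq(-10, 10, 0.5))
  expect_error(difference_histogram(dwt, dd_other), "mismatch")
})

test_that("diffusivity estimator: exact line and recovery study", {
  msd <- structure(data.frame(lag = (1:8) * 0.025,
                              msd = 2 * 0.01 * (1:8) * 0.025,
                              n_pairs = rep(1000, 8)),
                   class = c("msd_curve", "data.frame"),
                   angle_label = "theta", units = "rad^2")
  est <- estimate_diffusivity(msd)
  expect_equal(est$d, 0.01, tolerance = 1e-12)

  det <- detector_config()
  for (d_true in c(0.005, 0.02)) {
    tr <- simulate_tracks(motion_model(d_true, 0.005), det, 500,
                          seed = round(d_true * 1e4))
    est <- estimate_diffusivity(compute_msd(tr, "theta"))
    expect_lt(abs(est$d / d_true - 1), 0.1)
  }

  expect_error(estimate_diffusivity(msd[1, , drop = FALSE]), "2 lags")
})

test_that("default WT/Mut contrast is theta-specific with separated estimates", {
  det <- detector_config()
  wt <- filter_tracks(simulate_tracks(motion_model(0.02, 0.008, 0.2), det,
                                      500, seed = 21))$kept
  mut <- filter_tracks(simulate_tracks(motion_model(0.008, 0.008, 0.2), det,
                                       500, seed = 22))$kept
  dth_wt <- estimate_diffusivity(compute_msd(wt, "theta"))
  dth_mut <- estimate_diffusivity(compute_msd(mut, "theta"))
  # non-overlapping standard errors
  expect_gt(dth_wt$d - 2 * dth_wt$se, dth_mut$d + 2 * dth_mut$se)
  # chi channel statistically indistinguishable
  expect_gt(displacement_ks_test(wt, mut, "chi")$p.value, 0.05)
  expect_lt(displacement_ks_test(wt, mut, "theta")$p.value, 1e-6)
})

test_that("track tables round-trip through CSV", {
  tr <- simulate_tracks(motion_model(0.01, 0.01, 0.2),
                        detector_config(edge_fraction = 0.1), 20, seed = 30)
  f <- tempfile(fileext = ".csv")
  write_tracks(tr, f)
  back <- read_tracks(f)
  expect_equal(back$data$theta, tr$data$theta, tolerance = 1e-8)
  expect_equal(back$spots$edge, tr$spots$edge)
  expect_equal(back$detector$frame_interval, 0.025, tolerance = 1e-9)
})
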