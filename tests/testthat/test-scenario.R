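test_that("activation normalization forces baseline 0 and peak 1", {
  expect_equal(normalize_activation(c(0.2, 0.2, 1.0, 0.6)),
               c(0, 0, 1, 0.5))
  expect_error(normalize_activation(rep(0.3, 4)), "degenerate")
  set.seed(5)
  for (k in 1:10) {
    x <- cumsum(stats::rnorm(20))
    x <- x - min(x) + 0.1
    if (max(x) > x[1]) {
      y <- normalize_activation(x)
      expect_identical(y[1], 0)
      expect_identical(max(y), 1)
      # idempotence
      expect_equal(normalize_activation(y), y)
    }
  }
})

test_that("depletion normalization maps rest to 1 and the minimum to 0", {
  expect_equal(normalize_depletion(c(1.0, 0.1, 0.55)), c(1, 0, 0.5))
  # overshoot above the resting level is allowed (unclamped map)
  y <- normalize_depletion(c(1.0, 0.2, 1.3))
  expect_gt(max(y), 1)
  # series whose minimum is at t = 0 is degenerate
  expect_error(normalize_depletion(c(0.1, 0.5, 0.9)), "degenerate")
})

test_that("combined RMSD pools residuals with equal weight per point", {
  tr <- default_traj()
  times <- c(10, 30, 60)
  model_nn <- nfkbcbp:::normalized_model_at(tr, "nuclear_nfkb", times)
  model_ik <- nfkbcbp:::normalized_model_at(tr, "total_ikba", times)
  # data exactly on the model curves: RMSD 0
  d0 <- timecourse_data(rep(c("nuclear_nfkb", "total_ikba"), each = 3),
                        rep(times, 2), c(model_nn, model_ik))
  expect_equal(combined_rmsd(tr, d0), 0)
  # one series offset by 0.1 at each of 3 points, other exact:
  # pooled RMSD = sqrt(3 * 0.01 / 6)
  d1 <- timecourse_data(rep(c("nuclear_nfkb", "total_ikba"), each = 3),
                        rep(times, 2), c(model_nn, model_ik + 0.1))
  expect_equal(combined_rmsd(tr, d1), sqrt(0.03 / 6), tolerance = 1e-9)
  # a single point with residual 0.3 scores 0.3
  d2 <- timecourse_data("nuclear_nfkb", 10, model_nn[1] + 0.3)
  expect_equal(combined_rmsd(tr, d2), 0.3, tolerance = 1e-9)
  # data outside the simulated span are rejected
  d3 <- timecourse_data("nuclear_nfkb", 1e4, 0.5)
  expect_error(combined_rmsd(tr, d3), "span")
})

test_that("scan with a single unit scale reproduces the plain simulation", {
  p <- default_parameters()
  curve <- default_ikk_curve()
  scan <- scan_kmrna(p, curve, scales = 1, t_end = 60)
  tr <- simulate_nfkb(p, curve, t_end = 60)
  expect_equal(scan$trajectories[[1]]$species, tr$species, tolerance = 1e-8)
})

test_that("resting NF-kB in the abundance scan is proportional to the scale", {
  scan <- default_nfkb_scan()
  rest <- vapply(seq_along(scan$scales), function(k) {
    total_nfkb_in(scan$trajectories[[k]]$species[1, ],
                  scan$trajectories[[k]]$params)
  }, numeric(1))
  expect_equal(rest, 0.1 * scan$scales, tolerance = 1e-6)
})

test_that("noiseless self-recovery returns the generating scale with RMSD 0", {
  p <- default_parameters()
  curve <- default_ikk_curve()
  scan <- default_kmrna_scan()
  d <- gen_timecourse(p, curve, true_scale = 1, kind = "kmrna_scale",
                      sigma = 0)
  fit <- select_best_scale(scan, d)
  expect_identical(fit$best_scale, 1)
  expect_lt(min(fit$rmsd), 1e-8)
  expect_false(fit$tie)
})

test_that("exact ties are broken toward the larger scale and flagged", {
  scan <- default_kmrna_scan()
  # duplicate the scale-1 trajectory under two labels
  tied <- structure(list(scales = c(0.5, 1),
                         trajectories = scan$trajectories[c(1, 1)],
                         kind = "kmrna_scale"), class = "nfkb_scan")
  d <- gen_timecourse(default_parameters(), default_ikk_curve(), 1,
                      "kmrna_scale", sigma = 0)
  fit <- select_best_scale(tied, d)
  expect_identical(fit$best_scale, 1)
  expect_true(fit$tie)
})

test_that("suppressing IkBa production delays recovery monotonically", {
  scan <- default_kmrna_scan()
  rec120 <- vapply(seq_along(scan$scales), function(k) {
    tr <- scan$trajectories[[k]]
    tr$total_ikba[match(120, tr$time)] / tr$total_ikba[1]
  }, numeric(1))
  ord <- order(scan$scales)
  expect_true(all(diff(rec120[ord]) >= 0))
  expect_gte(rec120[scan$scales == 1], 0.9)
  expect_lt(rec120[scan$scales == 0.0625], 1)
})

test_that("time-course files round-trip", {
  d <- gen_timecourse(default_parameters(), default_ikk_curve(), 0.25,
                      sigma = 0.05, seed = 3, times = c(10, 30, 60))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(d, path)
  back <- read_timecourse(path)
  expect_equal(back$value_normalized, d$value_normalized, tolerance = 1e-9)
})
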