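test_that("free energy of dissociation follows RT ln Kd", {
  expect_equal(delta_g(1e9), 0)                       # Kd = 1 M
  # frozen values computed independently from R*T*ln(Kd[M])
  expect_equal(delta_g(57.0), -9.8823, tolerance = 1e-4)
  expect_equal(delta_g(244.4), -9.0195, tolerance = 1e-4)
  expect_error(delta_g(-1), "positive")
  expect_error(delta_g(0), "positive")
})

test_that("the entropic term closes the thermodynamic cycle exactly", {
  set.seed(1)
  kd <- 10^stats::runif(20, 0, 5)
  dh <- stats::rnorm(20, -5, 3)
  expect_equal(delta_g(kd) + tds_from(kd, dh) - dh, rep(0, 20))
  # dh equal to dG gives zero entropy term
  expect_equal(tds_from(100, delta_g(100)), 0)
})

test_that("published one-decimal entropic terms are reproduced", {
  expect_equal(round(tds_from(244.4, -7.2), 1), 1.8)
  expect_equal(round(tds_from(1706.8, -2.4), 1), 5.5)
  expect_equal(round(tds_from(1604.5, -5.4), 1), 2.5)
  expect_equal(round(tds_from(173.9, -7.8), 1), 1.4)
})

test_that("the packaged binding table is thermodynamically consistent", {
  tab <- packaged_binding_table()
  res <- check_table_consistency(tab, tolerance = 0.1)
  expect_true(attr(res, "all_pass"))
  expect_identical(nrow(res), 7L)                 # NB row skipped
  expect_identical(attr(res, "skipped"), "425-508 F473A")
  expect_lt(max(res$residual), 0.09)
})

test_that("a corrupted record fails and an empty set passes vacuously", {
  tab <- packaged_binding_table()
  tab$tds_kcal[3] <- tab$tds_kcal[3] + 1.0
  res <- check_table_consistency(tab, tolerance = 0.1)
  expect_false(attr(res, "all_pass"))
  expect_identical(sum(!res$pass), 1L)
  empty <- tab[0, ]
  expect_warning(res0 <- check_table_consistency(empty), "vacuous")
  expect_true(attr(res0, "all_pass"))
})

test_that("fold changes reproduce the in-text rounding conventions", {
  expect_identical(fold_change(244.4, 57.0), 4)
  expect_identical(fold_change(386.8, 244.4, "one_decimal"), 1.6)
  expect_identical(fold_change(100, 100, "one_decimal"), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("predicted heats honour the limiting cases", {
  sch <- default_itc_schedule()
  expect_equal(predict_heats(list(n = 1, kd_nM = 57, dh_kcal = 0), sch),
               rep(0, 25))
  # saturating titrant: all heat in the first injection
  sat <- itc_schedule(1.4, 1, 5000, c(20, rep(10, 5)))
  q <- predict_heats(list(n = 1, kd_nM = 10, dh_kcal = -8), sat)
  expect_equal(q[1], 1 * 1 * 1.4 * -8, tolerance = 0.05)
  expect_true(all(abs(q[-1]) < 0.05 * abs(q[1])))
  # total heat when saturation precedes any appreciable displacement
  # approaches the closed form n * M0 * V0 * dH
  fine <- itc_schedule(1.4, 1, 20000, rep(2.5, 8))
  q2 <- predict_heats(list(n = 1.1, kd_nM = 10, dh_kcal = -6), fine)
  expect_equal(sum(q2), 1.1 * 1 * 1.4 * -6, tolerance = 0.01)
})

test_that("noiseless heats are refit to within one percent", {
  sch <- default_itc_schedule()
  truth <- list(n = 1.0, kd_nM = 57, dh_kcal = -5.9)
  fit <- fit_one_site(predict_heats(truth, sch), sch)
  expect_equal(coef(fit)[["n"]], 1.0, tolerance = 0.01)
  expect_equal(coef(fit)[["kd_nM"]], 57, tolerance = 0.01 * 57)
  expect_equal(coef(fit)[["dh_kcal"]], -5.9, tolerance = 0.01 * 5.9)
})

test_that("the round-trip holds across a wide Wiseman c range", {
  sch <- default_itc_schedule()
  for (kd in c(2800, 560, 100, 28)) {   # c from 5 to 500 at 14 uM cell
    truth <- list(n = 1.0, kd_nM = kd, dh_kcal = -6)
    fit <- fit_one_site(predict_heats(truth, sch), sch,
                        init = list(n = 0.8, kd_nM = 200, dh_kcal = -4))
    expect_equal(coef(fit)[["kd_nM"]], kd, tolerance = 0.01 * kd)
    expect_equal(coef(fit)[["n"]], 1, tolerance = 0.01)
  }
})

test_that("two percent heat noise keeps the median Kd error under ten percent", {
  sch <- default_itc_schedule()
  truth <- list(n = 1, kd_nM = 57, dh_kcal = -5.9)
  errs <- vapply(1:20, function(s) {
    q <- gen_itc(truth, sch, rel_sigma = 0.02, seed = s)
    abs(coef(fit_one_site(q, sch))[["kd_nM"]] - 57) / 57
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("degenerate heats are rejected", {
  sch <- default_itc_schedule()
  expect_error(fit_one_site(rep(0, 25), sch), "degenerate")
  expect_error(fit_one_site(rep(NA_real_, 25), sch), "informative")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  sch <- default_itc_schedule()
  q <- gen_itc(list(n = 1, kd_nM = 57, dh_kcal = -5.9), sch,
               rel_sigma = 0.02, seed = 9)
  fit <- fit_one_site(q, sch)
  expect_named(coef(fit), c("n", "kd_nM", "dh_kcal"))
  expect_length(predict(fit), 25)
  expect_length(residuals(fit), 24)   # first injection excluded
  expect_output(print(fit), "Kd")
  s <- summary(fit)
  expect_s3_class(s, "summary.itc_fit")
  expect_true(all(fit$se > 0))
})
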