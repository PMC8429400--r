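# Calibration fitting/inversion, rate estimation, binned regression,
# mixture detection, group comparisons. Simulation-based checks use the
# synthetic generators with fixed seed lists.

test_that("noiseless sigmoid points are recovered to 1e-6 relative", {
  truth <- truth_sigmoid()
  ph <- seq(4.5, 8, by = 0.5)
  r <- truth$r_min + (truth$r_max - truth$r_min) /
    (1 + 10^(truth$hill * (truth$midpoint - ph)))
  cv <- fit_calibration(ph, r)
  expect_equal(cv$r_min, truth$r_min, tolerance = 1e-6)
  expect_equal(cv$r_max, truth$r_max, tolerance = 1e-6)
  expect_equal(cv$midpoint_pH, truth$midpoint, tolerance = 1e-6)
  expect_equal(cv$hill_slope, truth$hill, tolerance = 1e-6)
  expect_lt(cv$residual_sd, 1e-8)
})

test_that("calibration precondition and degeneracy errors", {
  expect_error(fit_calibration(c(5, 6, 7), c(0.5, 1, 1.5)), ">= 4")
  expect_error(fit_calibration(c(5, 6, 7, 8), rep(1.0, 4)), "degenerate")
})

test_that("midpoint recovered within 0.05 pH at 2% noise (100 seeds)", {
  errs <- vapply(1:100, function(s) {
    tab <- gen_calibration(s, cv = 0.02)
    fit <- tryCatch(fit_calibration(tab$ph, tab$ratio),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$midpoint_pH - truth_sigmoid()$midpoint)
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.05)
})

test_that("ratio_to_ph is the exact algebraic inverse and flags range", {
  ph <- seq(5, 7.5, by = 0.1)
  tab <- gen_calibration(7, cv = 0)     # exact sigmoid values
  curve <- fit_calibration(tab$ph, tab$ratio)
  r <- predict_ratio(curve, ph)
  expect_equal(as.numeric(ratio_to_ph(curve, r)), ph, tolerance = 1e-9)
  # midpoint ratio maps to midpoint pH
  mid_r <- predict_ratio(curve, curve$midpoint_pH)
  expect_equal(as.numeric(ratio_to_ph(curve, mid_r)), curve$midpoint_pH,
               tolerance = 1e-9)
  # boundary and outside values are flagged, not clamped
  out <- ratio_to_ph(curve, c(curve$r_max, curve$r_min - 0.1, mid_r))
  expect_true(all(attr(out, "out_of_range")[1:2]))
  expect_false(attr(out, "out_of_range")[3])
  expect_true(all(is.na(out[1:2])))
})

test_that("initial rate: closed-form exponential recovered exactly", {
  tt <- seq(0, 8, by = 0.25)            # 15-s sampling
  ph <- 5.2 + (7.0 - 5.2) * exp(-1.0 * tt)
  est <- estimate_initial_rate(tt, ph)
  expect_equal(est$initial_rate, -1.8, tolerance = 1e-6)
  expect_equal(est$plateau_pH, 5.2, tolerance = 1e-6)
  expect_equal(est$rate_constant, 1.0, tolerance = 1e-6)
  expect_false(est$flat)

  # constant series -> rate 0 with flat flag
  flat <- estimate_initial_rate(tt, rep(6.5, length(tt)))
  expect_identical(flat$initial_rate, 0)
  expect_true(flat$flat)

  # invariance to time origin, equivariance to pH offset
  est2 <- estimate_initial_rate(tt + 13.7, ph)
  expect_equal(est2$initial_rate, est$initial_rate, tolerance = 1e-9)
  est3 <- estimate_initial_rate(tt, ph + 0.4)
  expect_equal(est3$initial_rate, est$initial_rate, tolerance = 1e-6)
  expect_equal(est3$plateau_pH, est$plateau_pH + 0.4, tolerance = 1e-6)

  # rising relaxation (leak direction) has positive rate
  up <- estimate_initial_rate(tt, 6.6 - 1.3 * exp(-0.8 * tt))
  expect_equal(up$initial_rate, 0.8 * 1.3, tolerance = 1e-6)

  expect_error(estimate_initial_rate(1:4, c(7, 6.5, 6.2, 6.0)), ">= 6")
})

test_that("initial rate within 10% under 0.02-pH noise (100 seeds)", {
  rel_err <- vapply(1:100, function(s) {
    tab <- gen_timecourse(s, p0 = 7.0, p_inf = 5.2, k = 1.0,
                          sd_ph = 0.02)
    curve <- fit_calibration(gen_calibration(s + 1000, cv = 0)$ph,
                             gen_calibration(s + 1000, cv = 0)$ratio)
    ph <- as.numeric(ratio_to_ph(curve, tab$ratio))
    keep <- is.finite(ph)
    est <- estimate_initial_rate(tab$time_min[keep], ph[keep])
    abs(est$initial_rate - (-1.8)) / 1.8
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("linear-secant rate option works", {
  tt <- seq(0, 8, by = 0.25)
  ph <- 5.2 + 1.8 * exp(-tt)
  est <- estimate_initial_rate(tt, ph, method = "linear")
  expect_lt(est$initial_rate, 0)   # acidification, shallower than -1.8
  expect_gt(est$initial_rate, -1.8)
})

test_that("binned regression: exact linear data give R^2 = 1 and clean
           bin bookkeeping", {
  # cells placed symmetrically inside each class so bin means sit
  # exactly on the line
  au <- rep(seq(500, 4700, by = 600), each = 5) +
    rep(c(-100, -50, 0, 50, 100), times = 8)
  ph <- 6.3 + (au - 200) * (0.7 / 4800)
  br <- bin_and_regress(au, ph)
  expect_equal(br$r_squared, 1.0, tolerance = 1e-9)
  expect_identical(length(br$midpoints), 8L)
  expect_identical(sum(br$n), br$n_included)
  expect_identical(br$n_included, length(au))   # all inside [200, 5000)
  # edge handling: 200 included, 5000 excluded, below-range excluded
  br2 <- bin_and_regress(c(au, 200, 5000, 199, 5001), c(ph, 6.3, 7, 6, 7))
  expect_identical(br2$n_included, length(au) + 1L)
  expect_error(bin_and_regress(c(10, 20, 30), c(6, 6, 6)), "non-empty")
})

test_that("Fig-1E-like synthetic population gives R^2 >= 0.9 (50 seeds)", {
  r2 <- vapply(1:50, function(s) {
    cells <- gen_cell_population(s, n = 2000, sd_cell = 0.15)
    bin_and_regress(cells$expression_au, cells$true_ph)$r_squared
  }, numeric(1))
  expect_gte(stats::median(r2), 0.9)
})

test_that("mixture detection selects the right model (100 seeds each)", {
  one_ok <- vapply(1:100, function(s) {
    x <- golgiph:::.with_seed(s, stats::rnorm(4000, 6.5, 0.1))
    detect_populations(x, seed = s)$n_components == 1L
  }, logical(1))
  expect_gte(mean(one_ok), 0.95)

  two <- lapply(1:100, function(s) {
    cells <- gen_cell_population(s, n = 4000, bimodal = TRUE,
                                 ratio_cv = 0)
    detect_populations(cells$true_ph, seed = s)
  })
  two_ok <- vapply(two, function(m) m$n_components == 2L, logical(1))
  expect_gte(mean(two_ok), 0.95)
  mean_err <- vapply(two[two_ok], function(m)
    max(abs(m$means - c(6.5, 7.1))), numeric(1))
  expect_lt(stats::median(mean_err), 0.05)

  expect_error(detect_populations(rnorm(20)), "n >= 50")
})

test_that("group_compare: pooled-t oracle on an embedded 6+6 table and
           ANOVA type-I control", {
  a <- c(6.41, 6.52, 6.38, 6.47, 6.55, 6.44)
  b <- c(6.71, 6.62, 6.85, 6.78, 6.66, 6.74)
  gc <- group_compare(list(ctrl = a, over = b))
  # hand-computed pooled t
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) *
            stats::var(b)) / (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  expect_equal(gc$statistic, t_oracle, tolerance = 1e-12)
  expect_identical(gc$method, "student_t")
  expect_lt(gc$p_value, 0.01)
  expect_s3_class(gc$summaries$ctrl, "box_summary")
  expect_true(gc$summaries$ctrl$p10 <= gc$summaries$ctrl$median)

  # identical groups: t ~ 0, p ~ 1
  same <- group_compare(list(a = a, b = a))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  # three null groups, 1000 sims: rejection rate ~ 5%
  rej <- golgiph:::.with_seed(42, {
    vapply(1:1000, function(i) {
      g <- list(x = stats::rnorm(8), y = stats::rnorm(8),
                z = stats::rnorm(8))
      group_compare(g)$p_value < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)

  expect_error(group_compare(list(a = c(1, 1), b = c(1, 1))), "variance")
})

test_that("box_summary quantiles are ordered and counted", {
  bs <- box_summary(c(1:100, NA))
  expect_identical(bs$n, 100L)
  expect_true(bs$p10 <= bs$median && bs$median <= bs$p90)
})
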