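test_that("the Fourier basis hits quarter-period values and is periodic", {
  p <- 365.25
  b <- fourier_basis(p / 4, order = 1, period = p)
  expect_equal(unname(b[1, ]), c(1, 0), tolerance = 1e-12)
  b2 <- fourier_basis(c(10, 100), order = 2, period = p)
  expect_equal(colnames(b2), c("sin1", "cos1", "sin2", "cos2"))
  t <- c(0, 17, 200.5)
  expect_equal(fourier_basis(t, 2, p), fourier_basis(t + p, 2, p),
               tolerance = 1e-12)
  expect_error(fourier_basis(1, order = 3), "order")
})

test_that("the natural spline basis satisfies the natural constraints", {
  knots <- c(3, 9, 15)
  bnd <- c(0, 24)
  grid <- seq(-2, 26, by = 0.01)
  B <- natural_spline_basis(grid, knots, bnd)
  expect_equal(ncol(B), length(knots) + 1L)
  set.seed(401)
  coef <- stats::rnorm(ncol(B))
  f <- as.numeric(B %*% coef)
  h <- 0.01
  d2 <- (f[-(1:2)] - 2 * f[-c(1, length(f))] + f[-((length(f) - 1):length(f))]) / h^2
  x2 <- grid[-c(1, length(grid))]
  # zero curvature at and beyond the boundary knots (linear extrapolation)
  expect_lt(max(abs(d2[x2 < -0.05 | x2 > 24.05])), 1e-6)
  expect_lt(max(abs(d2[abs(x2 - 0) < 1e-9])), 1e-4)
  expect_lt(max(abs(d2[abs(x2 - 24) < 1e-9])), 1e-4)
  # continuity at a boundary knot
  left <- f[which.min(abs(grid - (24 - h)))]
  at <- f[which.min(abs(grid - 24))]
  expect_lt(abs(at - left), 1e-1 * max(abs(coef)) + 1e-10)
  expect_error(natural_spline_basis(1, c(5, 3)), "strictly increasing")
})

test_that("the basis reproduces an arbitrary natural cubic spline exactly", {
  knots <- c(4, 10, 16)
  x <- seq(0, 24, by = 0.25)
  # reference natural interpolating spline through random values at the knots
  set.seed(402)
  kx <- c(0, knots, 24)
  ky <- stats::rnorm(length(kx))
  ref <- stats::spline(kx, ky, xout = x, method = "natural")$y
  B <- cbind(1, natural_spline_basis(x, knots, c(0, 24)))
  fit <- stats::lm.fit(B, ref)
  expect_lt(sqrt(mean(fit$residuals^2)), 1e-8)
})

test_that("the design frame has the documented columns and interactions", {
  v <- make_visits(list(list(id = "A", dob = "1993-01-01",
                             age_days = c(30, 200, 400), laz = -1, wlz = -1)))
  fr <- build_growth_design(v, growth_design_spec(knots = c(6, 12, 18)))
  expect_equal(nrow(fr), 3L)
  expect_true(all(fr$subject_id == "A"))
  expect_true(all(c("ns1", "ns2", "ns3", "ns4", "sin1", "cos1", "sin2", "cos2",
                    "age_sin1", "age_cos1") %in% names(fr)))
  expect_equal(fr$age_sin1, fr$age_mo * fr$sin1)
  expect_equal(fr$age_cos1, fr$age_mo * fr$cos1)
  # all visits on 1 March (non-leap): annual sine column is constant at
  # sin(2 pi 59 / 365.25)
  v2 <- make_visits(list(
    list(id = "A", dob = "1992-12-01", dates = c("1993-03-01"), laz = -1, wlz = -1),
    list(id = "B", dob = "1991-06-01", dates = c("1993-03-01"), laz = -1, wlz = -1)))
  fr2 <- build_growth_design(v2, growth_design_spec(knots = c(6, 12, 18)))
  expect_equal(fr2$sin1, rep(sin(2 * pi * 59 / 365.25), 2))
  expect_error(build_growth_design(v[0, ], growth_design_spec()), "empty")
})

test_that("design specs validate knots, period and random order", {
  expect_error(growth_design_spec(knots = c(10, 5)), "strictly increasing")
  expect_error(growth_design_spec(knots = c(0, 5)), "strictly inside")
  expect_error(growth_design_spec(period = -1), "period")
  expect_error(growth_design_spec(fourier_order = 1, random_fourier_order = 2),
               "random Fourier order")
})

# small simulated cohort reused across the model-fitting tests
.sim_growth <- function(n = 120, seed = 403, amplitude = 0.35, sd_seas = 0.3) {
  cfg <- synthetic_config(n_subjects = n, amplitude = amplitude,
                          sd_seasonal = sd_seas, amp_age_slope = 0, seed = seed)
  co <- generate_cohort(cfg)
  list(visits = add_zscores(co$visits, toy_lms_reference()), truth = co$truth)
}

test_that("zero-amplitude data yield seasonal fixed effects near zero", {
  sim <- .sim_growth(n = 150, seed = 404, amplitude = 0, sd_seas = 0)
  fit <- fit_growth_model(sim$visits, "wlz")
  se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))
  for (term in c("sin1", "cos1", "sin2", "cos2")) {
    expect_lt(abs(fit$fixef[[term]]), 3 * se[[term]] + 1e-12)
  }
})

test_that("the fit is deterministic and invariant to row order", {
  sim <- .sim_growth(n = 60, seed = 405)
  v <- sim$visits
  fit1 <- fit_growth_model(v, "wlz")
  set.seed(1)
  fit2 <- fit_growth_model(v[sample(nrow(v)), ], "wlz")
  # row order only perturbs the optimiser path, not the solution
  expect_equal(fit1$fixef, fit2$fixef, tolerance = 5e-3)
  fit3 <- fit_growth_model(v, "wlz")
  expect_identical(fit1$fixef, fit3$fixef)
})

test_that("predicted random effects are shrunken relative to their variance", {
  sim <- .sim_growth(n = 150, seed = 406)
  fit <- fit_growth_model(sim$visits, "wlz")
  vc <- as.data.frame(fit$varcorr)
  re <- fit$ranef_table
  map <- c(u0 = "(Intercept)", u1 = "age_mo", a = "sin1", b = "cos1")
  for (nm in names(map)) {
    est_var <- vc$vcov[vc$grp == "subject_id" & vc$var1 == map[[nm]] & is.na(vc$var2)]
    expect_lte(stats::var(re[[nm]]), est_var * 1.05)
  }
})

test_that("the CCV is the seasonal-pair amplitude", {
  expect_equal(compute_ccv(0, 0), 0)
  expect_equal(compute_ccv(3, 4), 5)
  set.seed(407)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  expect_equal(compute_ccv(a, b), compute_ccv(b, -a))  # phase rotation
  expect_true(all(compute_ccv(a, b) >= 0))
})

test_that("trajectories are periodic in the date of birth and seasonal terms are mean-zero", {
  sim <- .sim_growth(n = 120, seed = 408)
  fit <- fit_growth_model(sim$visits, "wlz")
  # 1993 and 1994 are both non-leap: same day of year -> identical curves
  t1 <- predict_trajectory(fit, "1993-03-01")
  t2 <- predict_trajectory(fit, "1994-03-01")
  expect_equal(t1$predicted, t2$predicted, tolerance = 1e-10)
  # zeroing the seasonal coefficients removes all dependence on dob
  fit0 <- fit
  fit0$fixef[c("sin1", "cos1", "sin2", "cos2", "age_sin1", "age_cos1")] <- 0
  z1 <- predict_trajectory(fit0, "1993-03-01")
  z2 <- predict_trajectory(fit0, "1993-08-20")
  expect_equal(z1$predicted, z2$predicted, tolerance = 1e-12)
  # averaging the seasonal deviation over a full year of birth dates
  # recovers the aseasonal curve (Fourier terms integrate to zero)
  dobs <- as.Date("1993-01-01") + 0:364
  preds <- vapply(dobs, function(d) {
    predict_trajectory(fit, d, age_grid = 12)$predicted
  }, numeric(1))
  expect_equal(mean(preds), predict_trajectory(fit0, "1993-01-01", 12)$predicted,
               tolerance = 0.02)
})

test_that("seasonal amplitude and individual CCV rank are recovered from truth", {
  sim <- .sim_growth(n = 500, seed = 409, amplitude = 0.4, sd_seas = 0.5)
  fit <- fit_growth_model(sim$visits, "wlz")
  amp <- sqrt(fit$fixef[["sin1"]]^2 + fit$fixef[["cos1"]]^2)
  expect_gt(amp, 0.4 * 0.7)
  expect_lt(amp, 0.4 * 1.3)
  re <- subject_seasonal_summary(fit)
  tru <- sim$truth$subjects
  rho <- stats::cor(re$ccv, tru$true_amplitude[match(re$subject_id, tru$subject_id)],
                    method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("LAZ seasonality lags WLZ when the generator imposes a phase delay", {
  sim <- .sim_growth(n = 400, seed = 410)
  phase_doy <- function(fit) {
    a <- fit$fixef[["sin1"]]; b <- fit$fixef[["cos1"]]
    (365.25 / (2 * pi)) * (atan2(-a, -b) %% (2 * pi))
  }
  fw <- fit_growth_model(sim$visits, "wlz")
  fl <- fit_growth_model(sim$visits, "laz")
  lag <- (phase_doy(fl) - phase_doy(fw)) %% 365.25
  expect_gt(lag, 40)   # generator truth: 90 days
  expect_lt(lag, 140)
})

test_that("stratified fits run per stratum and skip small ones with a warning", {
  sim <- .sim_growth(n = 150, seed = 411)
  out <- outcome_stunted_20_24(sim$visits)
  fits <- fit_by_outcome_group(sim$visits, out, min_subjects = 10)
  expect_true(length(fits) >= 2)
  expect_true(all(vapply(fits, inherits, logical(1), "growth_fit")))
  w <- capture_warnings(fit_by_outcome_group(sim$visits, out, min_subjects = 1e5))
  expect_true(length(w) >= 1 && all(grepl("skipped", w)))
  expect_error(fit_by_outcome_group(sim$visits, data.frame(subject_id = "x")),
               "stunted_20_24")
})
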