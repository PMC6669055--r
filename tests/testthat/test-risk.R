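test_that("odds ratios and Wald intervals are internally consistent with glm", {
  set.seed(501)
  d <- data.frame(x1 = stats::rnorm(300), x2 = stats::rbinom(300, 1, 0.4))
  d$y <- stats::rbinom(300, 1, stats::plogis(-0.5 + 0.8 * d$x1 + 0.5 * d$x2))
  fit <- fit_logistic(y ~ x1 + x2, d)
  ref <- stats::glm(y ~ x1 + x2, data = d, family = stats::binomial())
  expect_equal(fit$summary$estimate, unname(stats::coef(ref)), tolerance = 1e-10)
  se <- sqrt(diag(stats::vcov(ref)))
  expect_equal(fit$summary$or, exp(unname(stats::coef(ref))), tolerance = 1e-10)
  expect_equal(fit$summary$ci_lo, exp(unname(stats::coef(ref) - 1.96 * se)),
               tolerance = 1e-10)
  expect_equal(fit$summary$ci_hi, exp(unname(stats::coef(ref) + 1.96 * se)),
               tolerance = 1e-10)
  expect_equal(fit$n, 300L)
})

test_that("separation errors are explicit and constant predictors are dropped", {
  d <- data.frame(y = rep(c(0, 1), each = 25))
  d$x <- d$y  # outcome identical to a predictor
  expect_error(suppressWarnings(fit_logistic(y ~ x, d)), "separation.*x")
  d2 <- data.frame(y = stats::rbinom(60, 1, 0.5), x = stats::rnorm(60), z = 0)
  expect_warning(fit2 <- fit_logistic(y ~ x + z, d2), "dropped")
  expect_false("z" %in% fit2$summary$term)
  expect_equal(fit2$dropped, "z")
})

test_that("the consecutive-wet-season model responds to planted persistence", {
  # simulate episode summaries directly: wasting in the second wet season
  # driven only by dry-season wasting
  set.seed(502)
  n <- 800
  ep <- data.frame(
    subject_id = sprintf("S%04d", 1:n),
    wasted_wet1 = stats::runif(n) < 0.15,
    wasted_dry = stats::runif(n) < 0.2)
  ep$wasted_wet2 <- stats::runif(n) < stats::plogis(-2 + 2.0 * ep$wasted_dry)
  ep$eligible <- TRUE
  ep$n_wet1 <- ep$n_dry <- ep$n_wet2 <- 1L
  fit <- season_repeat_model(ep)
  s <- fit$summary
  expect_equal(s$term, c("(Intercept)", "wasted_wet1", "wasted_dry"))
  expect_gt(s$or[s$term == "wasted_dry"], 2)
  expect_lt(abs(s$estimate[s$term == "wasted_wet1"]), 0.5)
  # both effects planted -> both ORs above 1
  ep$wasted_wet2 <- stats::runif(n) <
    stats::plogis(-2.2 + 1.2 * ep$wasted_wet1 + 2.0 * ep$wasted_dry)
  fit2 <- season_repeat_model(ep)
  expect_true(all(fit2$summary$or[-1] > 1))
  expect_error(season_repeat_model(ep[ep$n_wet1 == 99, ]), "no eligible")
  expect_warning(season_repeat_model(ep[1:30, ]), "only 30")
})

test_that("ever-stunted/ever-wasted features respect the 20-month boundary", {
  v <- make_visits(list(
    # stunted only at month 21 -> ever_stunted (< 20 mo) FALSE
    list(id = "A", age_days = c(200, 650, 700), laz = c(-1, -2.5, -2.5), wlz = -1),
    # wasted at month 7 -> ever_wasted TRUE
    list(id = "B", age_days = c(220, 650, 700), laz = -1, wlz = c(-2.4, -1, -1)),
    list(id = "C", age_days = c(100, 200), laz = -1, wlz = -1)))
  mo <- monthly_classification(v)
  out <- outcome_stunted_20_24(v)
  re <- data.frame(subject_id = c("A", "B", "C"), u0 = 0, u1 = 0, ccv = 0)
  feats <- build_stunting_features(mo, re, out)
  # C has no 20-24-mo visits -> excluded
  expect_setequal(feats$subject_id, c("A", "B"))
  expect_false(feats$ever_stunted[feats$subject_id == "A"])
  expect_true(feats$ever_wasted[feats$subject_id == "B"])
  expect_true(feats$stunted_20_24[feats$subject_id == "A"])
})

test_that("the three stunting models are nested with increasing likelihood", {
  set.seed(503)
  n <- 600
  feats <- data.frame(
    subject_id = sprintf("S%04d", 1:n),
    sex_boy = stats::rbinom(n, 1, 0.5),
    ever_stunted = stats::runif(n) < 0.3,
    ever_wasted = stats::runif(n) < 0.25,
    u0 = stats::rnorm(n), u1 = stats::rnorm(n, 0, 0.02),
    ccv = abs(stats::rnorm(n, 0, 0.4)))
  feats$stunted_20_24 <- stats::runif(n) < stats::plogis(
    -2 + 0.3 * feats$sex_boy + 2 * feats$ever_stunted + 0.5 * feats$ever_wasted -
      0.5 * feats$u0 + 0.8 * feats$ccv)
  fits <- fit_stunting_models(feats)
  expect_named(fits, c("I", "II", "III"))
  expect_lte(fits$I$logLik, fits$II$logLik + 1e-9)
  expect_lte(fits$II$logLik, fits$III$logLik + 1e-9)
  expect_equal(fits$I$n, fits$III$n)   # same rows for all three
  or_ew <- fits$II$summary$or[fits$II$summary$term == "ever_wasted"]
  expect_gt(or_ew, 1)
})

test_that("without coupling the ever-wasted odds ratio sits near 1", {
  set.seed(504)
  n <- 1500
  feats <- data.frame(
    subject_id = seq_len(n), sex_boy = stats::rbinom(n, 1, 0.5),
    ever_stunted = stats::runif(n) < 0.3, ever_wasted = stats::runif(n) < 0.25,
    u0 = 0, u1 = 0, ccv = 0)
  feats$stunted_20_24 <- stats::runif(n) < stats::plogis(-1.5 + 2 * feats$ever_stunted)
  fits <- suppressWarnings(fit_stunting_models(feats))
  est <- fits$II$summary$estimate[fits$II$summary$term == "ever_wasted"]
  se <- fits$II$summary$se[fits$II$summary$term == "ever_wasted"]
  expect_lt(abs(est), 3 * se)
})

test_that("classification diagnostics match a brute-force confusion matrix", {
  # degenerate constant predictor at 30% prevalence: all-negative classifier
  p <- rep(0.3, 200)
  obs <- c(rep(TRUE, 60), rep(FALSE, 140))
  d <- classification_diagnostics(p, obs, threshold = 0.5)
  expect_equal(d$error_rate, 30)
  expect_equal(d$fnr, 100)
  expect_equal(d$fpr, 0)
  # perfect predictor
  d2 <- classification_diagnostics(as.numeric(obs), obs, threshold = 0.5)
  expect_equal(unlist(d2[c("error_rate", "fnr", "fpr")]),
               c(error_rate = 0, fnr = 0, fpr = 0))
  # random fits against the oracle
  set.seed(505)
  for (i in 1:10) {
    p <- stats::runif(150)
    obs <- stats::runif(150) < p
    thr <- stats::runif(1, 0.2, 0.8)
    got <- classification_diagnostics(p, obs, thr)
    want <- oracle_diagnostics(p, obs, thr)
    expect_equal(got[c("error_rate", "fnr", "fpr")], want)
  }
  expect_error(classification_diagnostics(p, obs, threshold = 1.2), "threshold")
})

test_that("the intercept-only error rate never beats the base rate", {
  set.seed(506)
  for (i in 1:5) {
    n <- 200
    d <- data.frame(y = stats::rbinom(n, 1, stats::runif(1, 0.1, 0.9)))
    fit <- fit_logistic(y ~ 1, d)
    prev <- mean(d$y)
    diag <- classification_diagnostics(fit, threshold = 0.5)
    expect_lte(diag$error_rate / 100, max(prev, 1 - prev) + 1e-12)
  }
})

test_that("all three model shapes recover their coefficients by simulation", {
  # each shape is simulated from its own generative coefficients, fitted,
  # and every coefficient must land within 0.3 log-odds of truth
  truth <- c(`(Intercept)` = -2.0, sex_boy = 0.3, ever_stunted = 1.5,
             ever_wasted = 0.4, u0 = -0.5, u1 = 0.5, ccv = 0.8)
  shapes <- list(I = names(truth)[1:3], II = names(truth)[1:4],
                 III = names(truth))
  n <- 4000
  hits <- c(I = 0L, II = 0L, III = 0L)
  n_seeds <- 50L
  for (seed in seq_len(n_seeds)) {
    set.seed(5200 + seed)
    feats <- data.frame(
      subject_id = seq_len(n), sex_boy = stats::rbinom(n, 1, 0.5),
      ever_stunted = stats::runif(n) < 0.3, ever_wasted = stats::runif(n) < 0.25,
      u0 = stats::rnorm(n, 0, 1), u1 = stats::rnorm(n, 0, 0.5),
      ccv = abs(stats::rnorm(n, 0, 0.8)))
    X <- cbind(`(Intercept)` = rep(1, n), sex_boy = feats$sex_boy,
               ever_stunted = as.numeric(feats$ever_stunted),
               ever_wasted = as.numeric(feats$ever_wasted),
               u0 = feats$u0, u1 = feats$u1, ccv = feats$ccv)
    for (m in names(shapes)) {
      b <- truth[shapes[[m]]]
      feats$stunted_20_24 <- stats::runif(n) <
        stats::plogis(as.numeric(X[, shapes[[m]], drop = FALSE] %*% b))
      fit <- fit_stunting_models(feats)[[m]]
      if (all(abs(fit$summary$estimate - truth[fit$summary$term]) <= 0.3)) {
        hits[m] <- hits[m] + 1L
      }
    }
  }
  for (m in names(hits)) expect_gte(hits[[m]] / n_seeds, 0.9)
})
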