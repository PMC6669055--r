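# Plain logistic risk models: consecutive-wet-season wasting, the three
# nested stunting models, and in-sample classification diagnostics.

#' Fit a logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood fit via [stats::glm()]. Constant (aliased) predictors
#' are dropped with a warning; quasi-complete separation raises an error
#' naming the offending term. Wald 95% CIs are exp(coef +/- 1.96 SE).
#'
#' @param formula model formula with a binary (0/1 or logical) outcome.
#' @param data model data.
#' @return object of class `logit_fit`: `summary` (term, estimate, se, or,
#'   ci_lo, ci_hi), `n`, `logLik`, `fitted`, `y`, `dropped`, `glm`.
#' @export
fit_logistic <- function(formula, data) {
  glm_fit <- stats::glm(formula, data = data, family = stats::binomial())
  co <- stats::coef(glm_fit)
  dropped <- names(co)[is.na(co)]
  if (length(dropped) > 0L) {
    warning("dropped aliased/constant predictors: ", paste(dropped, collapse = ", "))
    co <- co[!is.na(co)]
  }
  p <- stats::fitted(glm_fit)
  if (max(abs(co)) > 15 && (min(p) < 1e-8 || max(p) > 1 - 1e-8)) {
    stop("fit_logistic: perfect separation detected for term '",
         names(co)[which.max(abs(co))], "'")
  }
  se <- sqrt(diag(stats::vcov(glm_fit)))[names(co)]
  summ <- data.frame(
    term = names(co), estimate = unname(co), se = unname(se),
    or = exp(unname(co)),
    ci_lo = exp(unname(co) - 1.96 * unname(se)),
    ci_hi = exp(unname(co) + 1.96 * unname(se)),
    stringsAsFactors = FALSE)
  structure(list(summary = summ, n = stats::nobs(glm_fit),
                 logLik = as.numeric(stats::logLik(glm_fit)),
                 fitted = p, y = glm_fit$y, dropped = dropped,
                 glm = glm_fit),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (n = %d)\n", x$n))
  s <- x$summary
  tab <- data.frame(term = s$term, OR = signif(s$or, digits),
                    ci_lo = signif(s$ci_lo, digits), ci_hi = signif(s$ci_hi, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Consecutive-wet-season wasting model
#'
#' Logistic regression over eligible subjects: wasted in the second wet
#' season as the outcome, wasted in the first wet season and wasted in the
#' intervening dry season as binary predictors (dry-season wasting included
#' to separate continuous from episodic wasting).
#'
#' @param episodes output of [summarize_episodes()].
#' @return a `logit_fit` (terms: intercept, `wasted_wet1`, `wasted_dry`).
#' @export
season_repeat_model <- function(episodes) {
  el <- episodes[episodes$eligible, , drop = FALSE]
  if (nrow(el) == 0L) stop("season_repeat_model: no eligible subjects")
  if (nrow(el) < 50L) {
    warning("season_repeat_model: only ", nrow(el), " eligible subjects")
  }
  d <- data.frame(y = as.integer(el$wasted_wet2),
                  wasted_wet1 = as.integer(el$wasted_wet1),
                  wasted_dry = as.integer(el$wasted_dry))
  fit_logistic(y ~ wasted_wet1 + wasted_dry, d)
}

#' Subject-level features for the stunting-risk models
#'
#' One row per subject with a non-missing 20-24-month outcome: sex
#' indicator (boy = 1), ever stunted / ever wasted before 20 completed
#' months (from the monthly-bin classifications at months 0-19), and the
#' growth-model random effects (intercept, slope, CCV).
#'
#' @param monthly output of [monthly_classification()].
#' @param ranef_table per-subject random effects
#'   ([subject_seasonal_summary()]), possibly pooled over per-sex fits.
#' @param outcome output of [outcome_stunted_20_24()].
#' @return data.frame: `subject_id`, `sex_boy`, `ever_stunted`,
#'   `ever_wasted`, `u0`, `u1`, `ccv`, `stunted_20_24`.
#' @export
build_stunting_features <- function(monthly, ranef_table, outcome) {
  keep <- !is.na(outcome$stunted_20_24)
  out <- outcome[keep, , drop = FALSE]
  pre <- monthly[monthly$month <= 19, , drop = FALSE]
  ever <- function(flag) {
    v <- tapply(flag, pre$subject_id, function(x) any(x %in% TRUE))
    as.logical(v[out$subject_id])
  }
  sexes <- tapply(as.character(monthly$sex), monthly$subject_id, `[`, 1L)
  i <- match(out$subject_id, ranef_table$subject_id)
  data.frame(
    subject_id = out$subject_id,
    sex_boy = as.integer(sexes[out$subject_id] == "M"),
    ever_stunted = ever(pre$stunted),
    ever_wasted = ever(pre$wasted),
    u0 = ranef_table$u0[i], u1 = ranef_table$u1[i], ccv = ranef_table$ccv[i],
    stunted_20_24 = out$stunted_20_24,
    stringsAsFactors = FALSE)
}

#' Fit the three nested stunting-risk models
#'
#' Model I: sex + ever stunted. Model II: model I + ever wasted. Model III:
#' model II + random-effect features (intercept, slope, CCV). All three are
#' fitted on the same rows (complete cases over the union of predictors), so
#' their log-likelihoods are nested.
#'
#' @param features output of [build_stunting_features()].
#' @return named list of `logit_fit`s (`I`, `II`, `III`) with attribute `n`.
#' @export
fit_stunting_models <- function(features) {
  vars <- c("sex_boy", "ever_stunted", "ever_wasted", "u0", "u1", "ccv",
            "stunted_20_24")
  cc <- stats::complete.cases(features[vars])
  d <- features[cc, , drop = FALSE]
  d$y <- as.integer(d$stunted_20_24)
  d$ever_stunted <- as.integer(d$ever_stunted)
  d$ever_wasted <- as.integer(d$ever_wasted)
  fits <- list(
    I = fit_logistic(y ~ sex_boy + ever_stunted, d),
    II = fit_logistic(y ~ sex_boy + ever_stunted + ever_wasted, d),
    III = fit_logistic(y ~ sex_boy + ever_stunted + ever_wasted + u0 + u1 + ccv, d))
  attr(fits, "n") <- nrow(d)
  fits
}

#' In-sample classification diagnostics
#'
#' Classifies at predicted probability >= `threshold` and reports the error
#' rate (% misclassified among all), false-negative rate (% of observed
#' positives classified negative) and false-positive rate (% of observed
#' negatives classified positive).
#'
#' @param fit a `logit_fit`, or a numeric vector of predicted probabilities.
#' @param observed observed binary outcomes (required when `fit` is a
#'   probability vector).
#' @param threshold classification threshold in (0, 1).
#' @return list: `threshold`, `error_rate`, `fnr`, `fpr` (percent).
#' @export
classification_diagnostics <- function(fit, observed = NULL, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (inherits(fit, "logit_fit")) {
    p <- fit$fitted
    observed <- fit$y
  } else {
    p <- fit
    if (is.null(observed)) stop("observed outcomes required")
  }
  obs <- as.logical(observed)
  pred <- p >= threshold
  list(threshold = threshold,
       error_rate = 100 * mean(pred != obs),
       fnr = 100 * mean(!pred[obs]),
       fpr = 100 * mean(pred[!obs]))
}
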