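# Time-lagged analysis: 3-month 1-to-1 matching, reciprocal multilevel
# logistic models, and scenario probability prediction.

#' Match each visit to a prior visit about 3 months earlier
#'
#' For every visit, the candidate prior visits of the same subject with lag
#' inside the window (in months at 30.4375 days/month) are enumerated and
#' the one minimising |lag - target| is chosen; an exact tie is broken
#' toward the longer lag. Visits with no candidate are dropped. Each current
#' visit appears in at most one pair; a prior visit may serve several
#' current visits.
#'
#' @param visits cleaned visit table with `subject_id`, `sex`, `visit_date`,
#'   `age_days`, `stunted`, `wasted` (flags at visit level).
#' @param target_lag target lag in months.
#' @param window allowed lag window in months (inclusive).
#' @return data.frame of pairs: `subject_id`, `sex`, `date_now`,
#'   `age_now_mo`, `stunted_now`, `wasted_now`, `date_prior`,
#'   `age_prior_mo`, `stunted_prior`, `wasted_prior`, `lag_months`.
#' @export
match_lagged <- function(visits, target_lag = 3, window = c(2.5, 3.5)) {
  v <- visits[order(visits$subject_id, as.Date(visits$visit_date)), , drop = FALSE]
  v$visit_date <- as.Date(v$visit_date)
  pieces <- lapply(split(seq_len(nrow(v)), v$subject_id), function(rows) {
    if (length(rows) < 2L) return(NULL)
    d <- as.numeric(v$visit_date[rows])
    now <- integer(0); prior <- integer(0)
    for (i in seq_along(rows)[-1L]) {
      lag <- (d[i] - d[seq_len(i - 1L)]) / DAYS_PER_MONTH
      cand <- which(lag >= window[1] & lag <= window[2])
      if (length(cand) == 0L) next
      score <- abs(lag[cand] - target_lag)
      best <- cand[score == min(score)]
      j <- best[which.max(lag[best])]  # tie toward the longer lag
      now <- c(now, rows[i]); prior <- c(prior, rows[j])
    }
    if (length(now) == 0L) return(NULL)
    data.frame(
      subject_id = v$subject_id[now], sex = v$sex[now],
      date_now = v$visit_date[now],
      age_now_mo = v$age_days[now] / DAYS_PER_MONTH,
      stunted_now = v$stunted[now], wasted_now = v$wasted[now],
      date_prior = v$visit_date[prior],
      age_prior_mo = v$age_days[prior] / DAYS_PER_MONTH,
      stunted_prior = v$stunted[prior], wasted_prior = v$wasted[prior],
      lag_months = as.numeric(v$visit_date[now] - v$visit_date[prior]) / DAYS_PER_MONTH,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Fit a time-lagged multilevel logistic model
#'
#' Current stunting (or wasting) as the binary outcome; sex, lagged age
#' (months), lagged stunted and lagged wasted as fixed effects; a
#' subject-level random intercept. Fitted by Laplace approximation (or
#' adaptive Gauss-Hermite quadrature for `nAGQ > 1`) via [lme4::glmer()];
#' on a hard failure the fit falls back to the coarser `nAGQ = 0`
#' approximation with a warning. No interaction terms are included.
#'
#' @param pairs output of [match_lagged()] (or any data.frame with the same
#'   columns).
#' @param outcome "stunting" or "wasting" (the current visit's flag).
#' @param nAGQ integration points (1 = Laplace).
#' @return object of class `lagged_fit`: `summary` (term, estimate, se, or,
#'   ci_lo, ci_hi), `sigma_u` (random-intercept SD), `n_pairs`,
#'   `n_subjects`, `method`, `messages`, `model`.
#' @export
fit_lagged_model <- function(pairs, outcome = c("stunting", "wasting"), nAGQ = 1) {
  outcome <- match.arg(outcome)
  if (nrow(pairs) < 100L) stop("fit_lagged_model: fewer than 100 matched pairs")
  d <- data.frame(
    y = as.integer(if (outcome == "stunting") pairs$stunted_now else pairs$wasted_now),
    sex_boy = as.integer(pairs$sex == "M" | pairs$sex == 1),
    age_lag = pairs$age_prior_mo,
    stunted_lag = as.integer(pairs$stunted_prior),
    wasted_lag = as.integer(pairs$wasted_prior),
    subject_id = as.character(pairs$subject_id))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  messages <- character(0)
  fit_once <- function(q) {
    withCallingHandlers(
      lme4::glmer(y ~ sex_boy + age_lag + stunted_lag + wasted_lag +
                    (1 | subject_id),
                  data = d, family = stats::binomial(), nAGQ = q,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  method <- if (nAGQ == 0) "nAGQ0" else if (nAGQ == 1) "laplace"
            else sprintf("agq%d", nAGQ)
  model <- tryCatch(fit_once(nAGQ), error = function(e) e)
  if (inherits(model, "error") && nAGQ >= 1) {
    warning("fit_lagged_model: ", conditionMessage(model),
            "; falling back to nAGQ = 0")
    messages <- c(messages, conditionMessage(model))
    model <- fit_once(0)
    method <- "nAGQ0-fallback"
  }
  co <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  summ <- data.frame(
    term = names(co), estimate = unname(co), se = unname(se),
    or = exp(unname(co)),
    ci_lo = exp(unname(co) - 1.96 * unname(se)),
    ci_hi = exp(unname(co) + 1.96 * unname(se)),
    stringsAsFactors = FALSE)
  structure(list(
    summary = summ, outcome = outcome,
    sigma_u = sqrt(unname(lme4::VarCorr(model)$subject_id[1, 1])),
    n_pairs = nrow(d), n_subjects = length(unique(d$subject_id)),
    method = method, messages = messages, model = model
  ), class = "lagged_fit")
}

#' @export
print.lagged_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Time-lagged multilevel logistic model: outcome %s\n", x$outcome))
  cat(sprintf("  %d pairs on %d subjects; random-intercept SD %.3f (%s)\n",
              x$n_pairs, x$n_subjects, x$sigma_u, x$method))
  s <- x$summary
  print(data.frame(term = s$term, OR = signif(s$or, digits),
                   ci_lo = signif(s$ci_lo, digits),
                   ci_hi = signif(s$ci_hi, digits)), row.names = FALSE)
  invisible(x)
}

#' Predicted probabilities for lagged-state scenarios
#'
#' Evaluates logistic(linear predictor) at the population level (random
#' intercept 0) over a grid of sex x lagged stunted x lagged wasted x
#' lagged age, labelling the four lagged-state groups (neither, stunted
#' only, wasted only, both).
#'
#' @param fit a `lagged_fit`, or a named coefficient vector on the log-odds
#'   scale with names `(Intercept)`, `sex_boy`, `age_lag`, `stunted_lag`,
#'   `wasted_lag`.
#' @param lagged_age lagged ages in months.
#' @param sex sex indicator values (boy = 1, girl = 0).
#' @return data.frame: `sex_boy`, `age_lag`, `stunted_lag`, `wasted_lag`,
#'   `group`, `probability`.
#' @export
predict_scenarios <- function(fit, lagged_age, sex = c(0, 1)) {
  beta <- if (inherits(fit, "lagged_fit")) {
    stats::setNames(fit$summary$estimate, fit$summary$term)
  } else fit
  need <- c("(Intercept)", "sex_boy", "age_lag", "stunted_lag", "wasted_lag")
  if (!all(need %in% names(beta))) {
    stop("coefficients must be named: ", paste(need, collapse = ", "))
  }
  g <- expand.grid(sex_boy = sex, age_lag = lagged_age,
                   stunted_lag = c(0, 1), wasted_lag = c(0, 1))
  eta <- beta[["(Intercept)"]] + beta[["sex_boy"]] * g$sex_boy +
    beta[["age_lag"]] * g$age_lag + beta[["stunted_lag"]] * g$stunted_lag +
    beta[["wasted_lag"]] * g$wasted_lag
  g$group <- c("neither", "stunted only", "wasted only", "both")[
    1L + g$stunted_lag + 2L * g$wasted_lag]
  g$probability <- stats::plogis(eta)
  g
}
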