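# Mixed-effects growth curves: natural-spline age trend, Fourier (cosinor)
# seasonality with an age interaction, and individual seasonal random
# effects summarised by the coefficient of cyclic variation (CCV).

#' Day of year of a date
#' @param date `Date` vector.
#' @return integer day of year, 0-based (1 January = 0).
#' @export
day_of_year <- function(date) as.POSIXlt(as.Date(date))$yday

#' Fourier (cosinor) seasonal basis
#'
#' Columns `sin(2 pi k t / period)`, `cos(2 pi k t / period)` for
#' k = 1..order. `t` may be a numeric time (e.g. day of year) or a `Date`,
#' in which case its day of year is used.
#'
#' @param t numeric time or `Date` vector.
#' @param order 1 (annual) or 2 (annual + semi-annual).
#' @param period period in the units of `t` (default 365.25 days).
#' @return matrix with columns `sin1`, `cos1` and, for order 2, `sin2`,
#'   `cos2`.
#' @export
fourier_basis <- function(t, order = 2, period = 365.25) {
  stopifnot(order %in% 1:2, period > 0)
  if (inherits(t, "Date")) t <- day_of_year(t)
  out <- matrix(NA_real_, nrow = length(t), ncol = 2L * order)
  cols <- character(2L * order)
  for (k in seq_len(order)) {
    out[, 2L * k - 1L] <- sin(2 * pi * k * t / period)
    out[, 2L * k] <- cos(2 * pi * k * t / period)
    cols[2L * k - 1L] <- paste0("sin", k)
    cols[2L * k] <- paste0("cos", k)
  }
  colnames(out) <- cols
  out
}

#' Natural cubic spline basis for age
#'
#' Thin wrapper around [splines::ns()] with explicit boundary knots; the
#' basis is linear beyond the boundary knots (natural constraint) and has
#' one column per interior knot plus one.
#'
#' @param age_months numeric ages.
#' @param knots interior knots (months), strictly increasing.
#' @param boundary boundary knots (default `c(0, 24)`).
#' @return basis matrix with columns `ns1`, `ns2`, ...
#' @export
natural_spline_basis <- function(age_months, knots, boundary = c(0, 24)) {
  if (length(knots) > 0 && any(diff(knots) <= 0)) {
    stop("interior knots must be strictly increasing")
  }
  b <- splines::ns(age_months, knots = knots, Boundary.knots = boundary)
  m <- matrix(b, nrow = length(age_months))
  colnames(m) <- paste0("ns", seq_len(ncol(m)))
  m
}

#' Specification of the growth-curve design
#'
#' @param knots interior spline knots in months, or NULL to place three
#'   knots at the 25th/50th/75th age percentiles at design-build time.
#' @param boundary spline boundary knots in months.
#' @param fourier_order Fourier order for the fixed seasonal terms (2 =
#'   annual + semi-annual).
#' @param random_fourier_order Fourier order of the per-subject seasonal
#'   random effects (must not exceed `fourier_order`).
#' @param period seasonal period in days.
#' @return list of class `growth_design_spec`.
#' @export
growth_design_spec <- function(knots = NULL, boundary = c(0, 24),
                               fourier_order = 2, random_fourier_order = 1,
                               period = 365.25) {
  if (!is.null(knots)) {
    if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
    if (any(knots <= boundary[1] | knots >= boundary[2])) {
      stop("knots must lie strictly inside the boundary knots")
    }
  }
  if (period <= 0) stop("period must be positive")
  if (random_fourier_order > fourier_order) {
    stop("random Fourier order must not exceed the fixed Fourier order")
  }
  structure(list(knots = knots, boundary = boundary,
                 fourier_order = fourier_order,
                 random_fourier_order = random_fourier_order,
                 period = period),
            class = "growth_design_spec")
}

#' Build the growth-model frame
#'
#' Fixed part: natural spline in age + Fourier terms of the visit date's day
#' of year + linear-age x first-order Fourier interaction. Random part per
#' subject: intercept + age + first-order Fourier pair. Column names are
#' stable: `ns1..nsK`, `sin1`, `cos1` (`sin2`, `cos2`), `age_sin1`,
#' `age_cos1`.
#'
#' @param visits cleaned visit table with `subject_id`, `visit_date`,
#'   `age_days` and the response column(s) (`wlz`, `laz`).
#' @param spec a [growth_design_spec()] (NULL knots are resolved here and
#'   returned in the `spec` attribute).
#' @return data.frame with design columns plus `subject_id`, `age_mo` and
#'   any of `wlz`/`laz` present in the input; attribute `spec` holds the
#'   resolved design spec.
#' @export
build_growth_design <- function(visits, spec = growth_design_spec()) {
  if (nrow(visits) == 0L) stop("build_growth_design: empty input")
  age_mo <- visits$age_days / DAYS_PER_MONTH
  if (is.null(spec$knots)) {
    spec$knots <- unname(stats::quantile(age_mo, c(0.25, 0.5, 0.75)))
  }
  ns <- natural_spline_basis(age_mo, spec$knots, spec$boundary)
  fb <- fourier_basis(as.Date(visits$visit_date), spec$fourier_order, spec$period)
  out <- data.frame(subject_id = as.character(visits$subject_id), age_mo = age_mo)
  out <- cbind(out, as.data.frame(ns), as.data.frame(fb))
  out$age_sin1 <- age_mo * fb[, "sin1"]
  out$age_cos1 <- age_mo * fb[, "cos1"]
  for (resp in intersect(c("wlz", "laz"), names(visits))) out[[resp]] <- visits[[resp]]
  attr(out, "spec") <- spec
  out
}

.growth_formula <- function(frame, response, diagonal = FALSE) {
  fixed <- c(grep("^ns[0-9]+$", names(frame), value = TRUE),
             grep("^(sin|cos)[0-9]$", names(frame), value = TRUE),
             "age_sin1", "age_cos1")
  bar <- if (diagonal) "||" else "|"
  stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "),
    sprintf("+ (1 + age_mo + sin1 + cos1 %s subject_id)", bar)))
}

#' Fit the mixed-effects growth model
#'
#' REML fit (via [lme4::lmer()]) of the spline + Fourier design with
#' per-subject random intercept, age slope, and first-order seasonal pair
#' (unstructured covariance; diagonal fallback on convergence failure,
#' recorded in the result). Per-subject predicted (shrunken) random effects
#' and their CCV are extracted.
#'
#' @param visits cleaned visit table (or a frame from
#'   [build_growth_design()]).
#' @param response "wlz" (default) or "laz".
#' @param spec a [growth_design_spec()].
#' @param diagonal force the diagonal random-effect covariance.
#' @return object of class `growth_fit`: the lme4 model, resolved spec,
#'   `fixef`, `varcorr`, residual `sigma`, `ranef_table` (subject_id, u0,
#'   u1, a, b, ccv), convergence metadata.
#' @export
fit_growth_model <- function(visits, response = "wlz",
                             spec = growth_design_spec(), diagonal = FALSE) {
  frame <- if (!is.null(attr(visits, "spec"))) visits
           else build_growth_design(visits, spec)
  spec <- attr(frame, "spec")
  if (is.null(frame[[response]])) stop("response column '", response, "' not found")
  frame <- frame[!is.na(frame[[response]]), , drop = FALSE]
  nvis <- table(frame$subject_id)
  if (sum(nvis >= 2L) < 10L) {
    stop("fit_growth_model: need >= 2 visits for >= 10 subjects")
  }
  messages <- character(0)
  fit_once <- function(diag) {
    withCallingHandlers(
      lme4::lmer(.growth_formula(frame, response, diag), data = frame,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  fallback <- FALSE
  model <- tryCatch(fit_once(diagonal), error = function(e) e)
  if (inherits(model, "error") && !diagonal) {
    fallback <- TRUE
    messages <- c(messages, conditionMessage(model))
    model <- tryCatch(fit_once(TRUE), error = function(e) e)
  }
  if (inherits(model, "error")) {
    stop("fit_growth_model failed to converge: ", conditionMessage(model))
  }
  re <- lme4::ranef(model)$subject_id
  ranef_table <- data.frame(
    subject_id = rownames(re),
    u0 = re[["(Intercept)"]], u1 = re[["age_mo"]],
    a = re[["sin1"]], b = re[["cos1"]],
    stringsAsFactors = FALSE)
  ranef_table$ccv <- compute_ccv(ranef_table$a, ranef_table$b)
  structure(list(
    model = model, spec = spec, response = response,
    fixef = lme4::fixef(model),
    varcorr = lme4::VarCorr(model),
    sigma = stats::sigma(model),
    ranef_table = ranef_table,
    n_subjects = length(unique(frame$subject_id)),
    n_obs = nrow(frame),
    logLik = as.numeric(stats::logLik(model)),
    diagonal = diagonal || fallback,
    fallback = fallback,
    messages = messages
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects growth model for %s: %d subjects, %d observations\n",
              x$response, x$n_subjects, x$n_obs))
  amp <- sqrt(x$fixef[["sin1"]]^2 + x$fixef[["cos1"]]^2)
  cat(sprintf("  fixed seasonal amplitude (annual harmonic): %.3f z\n", amp))
  cat(sprintf("  residual SD: %.3f; RE covariance: %s%s\n", x$sigma,
              if (x$diagonal) "diagonal" else "unstructured",
              if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

#' Per-subject seasonal summary
#'
#' @param fit a `growth_fit`.
#' @return data.frame `subject_id`, `u0`, `u1`, `a`, `b`, `ccv`.
#' @export
subject_seasonal_summary <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  fit$ranef_table
}

#' Coefficient of cyclic variation
#'
#' The amplitude (in z-score units) of a subject's annual-harmonic seasonal
#' random-effect pair: CCV = sqrt(a^2 + b^2). Zero iff both components are
#' zero; invariant under phase rotation of (a, b).
#'
#' @param a,b sine and cosine random-effect components.
#' @return non-negative numeric vector.
#' @export
compute_ccv <- function(a, b) sqrt(a^2 + b^2)

#' Fit growth models separately by 20-24-month stunting outcome and sex
#'
#' @param visits cleaned visit table.
#' @param outcome data.frame from [outcome_stunted_20_24()].
#' @param response response column.
#' @param spec design spec.
#' @param min_subjects strata smaller than this are skipped with a warning.
#' @return named list of `growth_fit`s, names like "F.stunted"/"M.not_stunted".
#' @export
fit_by_outcome_group <- function(visits, outcome, response = "wlz",
                                 spec = growth_design_spec(), min_subjects = 10) {
  if (is.null(outcome$stunted_20_24)) stop("outcome table lacks 'stunted_20_24'")
  grp <- outcome$stunted_20_24[match(visits$subject_id, outcome$subject_id)]
  keep <- !is.na(grp)
  visits <- visits[keep, , drop = FALSE]
  grp <- ifelse(grp[keep], "stunted", "not_stunted")
  fits <- list()
  for (sx in sort(unique(visits$sex))) for (g in c("not_stunted", "stunted")) {
    sub <- visits[visits$sex == sx & grp == g, , drop = FALSE]
    nm <- paste(sx, g, sep = ".")
    nsub <- length(unique(sub$subject_id))
    if (nsub < min_subjects) {
      warning(sprintf("stratum %s skipped: %d subjects (< %d)", nm, nsub, min_subjects))
      next
    }
    fits[[nm]] <- fit_growth_model(sub, response, spec)
  }
  fits
}

#' Predict a birth-date-specific population trajectory
#'
#' Population-level prediction (random effects at zero) along an age grid,
#' with calendar date = dob + age; the seasonal terms are evaluated at the
#' day of year of each predicted date.
#'
#' @param fit a `growth_fit`.
#' @param dob date of birth (`Date` or string).
#' @param age_grid ages in months.
#' @return data.frame `dob`, `age_mo`, `date`, `predicted`.
#' @export
predict_trajectory <- function(fit, dob, age_grid = seq(0, 24, by = 0.25)) {
  stopifnot(inherits(fit, "growth_fit"))
  dob <- as.Date(dob)
  spec <- fit$spec
  dates <- dob + round(age_grid * DAYS_PER_MONTH)
  ns <- natural_spline_basis(age_grid, spec$knots, spec$boundary)
  fb <- fourier_basis(dates, spec$fourier_order, spec$period)
  X <- cbind(1, ns, fb, age_sin1 = age_grid * fb[, "sin1"],
             age_cos1 = age_grid * fb[, "cos1"])
  colnames(X)[1] <- "(Intercept)"
  beta <- fit$fixef[colnames(X)]
  data.frame(dob = dob, age_mo = age_grid, date = dates,
             predicted = as.numeric(X %*% beta))
}
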