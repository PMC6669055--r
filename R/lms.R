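# LMS (Box-Cox) z-scores against a sex- and index-specific growth reference.

# Days per month used everywhere ages are converted (365.25 / 12).
DAYS_PER_MONTH <- 30.4375

#' Construct an LMS growth reference
#'
#' An LMS reference stores, per sex and axis, an ordered grid of index values
#' (age in days for length-for-age, length in cm for weight-for-length) with
#' the Box-Cox power `L`, median `M` and coefficient of variation `S` at each
#' grid point. Lookups interpolate linearly between grid points and reject
#' index values outside the grid.
#'
#' @param data data.frame with columns `sex` ("F"/"M"), `axis` ("age" or
#'   "length"), `index_value`, `L`, `M`, `S`.
#' @return An object of class `lms_reference`.
#' @seealso [toy_lms_reference()], [read_lms_reference()], [lookup_lms()]
#' @export
lms_reference <- function(data) {
  req <- c("sex", "axis", "index_value", "L", "M", "S")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0L) {
    stop("LMS reference is missing columns: ", paste(miss, collapse = ", "))
  }
  data <- as.data.frame(data)[req]
  if (!all(data$sex %in% c("F", "M"))) {
    stop("LMS reference 'sex' must be 'F' or 'M'")
  }
  if (!all(data$axis %in% c("age", "length"))) {
    stop("LMS reference 'axis' must be 'age' or 'length'")
  }
  if (any(!is.finite(data$M)) || any(data$M <= 0)) stop("LMS reference requires M > 0")
  if (any(!is.finite(data$S)) || any(data$S <= 0)) stop("LMS reference requires S > 0")
  key <- interaction(data$sex, data$axis, drop = TRUE)
  parts <- split(data, key)
  for (p in parts) {
    p <- p[order(p$index_value), ]
    if (any(diff(p$index_value) <= 0)) {
      stop("LMS reference grid must be strictly increasing within sex x axis")
    }
  }
  data <- data[order(data$axis, data$sex, data$index_value), ]
  rownames(data) <- NULL
  structure(list(table = data), class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  tab <- x$table
  cat("<lms_reference>\n")
  for (ax in unique(tab$axis)) {
    for (sx in unique(tab$sex)) {
      g <- tab[tab$axis == ax & tab$sex == sx, ]
      if (nrow(g) == 0L) next
      cat(sprintf("  %-6s sex %s: %d grid points, index %g..%g\n",
                  ax, sx, nrow(g), min(g$index_value), max(g$index_value)))
    }
  }
  invisible(x)
}

#' Read an LMS reference from CSV
#'
#' Expects columns `sex`, `axis`, `index_value`, `L`, `M`, `S`.
#'
#' @param path path to a CSV file.
#' @return An `lms_reference`.
#' @export
read_lms_reference <- function(path) {
  lms_reference(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Bundled toy LMS reference (synthetic)
#'
#' A smooth synthetic reference covering ages 0-26 months (length-for-age,
#' indexed by age in days) and lengths 30-120 cm (weight-for-length), both
#' sexes. The curves are analytic stand-ins with realistic magnitudes; they
#' are NOT the WHO 2006 standard, but share its schema so real LMS tables are
#' a drop-in replacement via [read_lms_reference()].
#'
#' @return An `lms_reference`.
#' @export
toy_lms_reference <- function() {
  months <- 0:26
  age_days <- months * DAYS_PER_MONTH
  laz <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    base <- if (sx == "F") 49.1 else 49.9
    gain <- if (sx == "F") 36.6 else 37.4
    data.frame(sex = sx, axis = "age", index_value = age_days,
               L = 1,
               M = base + gain * (months / 24)^0.65,
               S = 0.036 + 0.004 * months / 26)
  }))
  lengths <- seq(30, 120, by = 2)
  wfl <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    w50 <- if (sx == "F") 3.4 else 3.5   # median weight at 50 cm
    p <- 2.295                            # power-law exponent
    data.frame(sex = sx, axis = "length", index_value = lengths,
               L = -0.35,
               M = w50 / 50^p * lengths^p,
               S = (if (sx == "F") 0.078 else 0.074) + 0.0001 * lengths)
  }))
  lms_reference(rbind(laz, wfl))
}

#' Compute an LMS z-score
#'
#' z = ((x/M)^L - 1) / (L S); the log-limit form log(x/M)/S is used when
#' |L| < 1e-7 so the function is continuous in L at L = 0.
#'
#' @param x measurement (kg or cm), positive.
#' @param L,M,S Box-Cox power, median (> 0), coefficient of variation (> 0).
#'   Recycled against `x`.
#' @return Numeric z-score(s).
#' @export
compute_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  ok <- !is.na(x) & !is.na(L) & !is.na(M) & !is.na(S)
  if (any(ok & (x <= 0 | M <= 0 | S <= 0))) {
    stop("compute_zscore: measurement, M and S must all be positive")
  }
  z <- rep(NA_real_, n)
  loglim <- ok & abs(L) < 1e-7
  pow <- ok & !loglim
  z[loglim] <- log(x[loglim] / M[loglim]) / S[loglim]
  # expm1 keeps full precision as L approaches 0
  z[pow] <- expm1(L[pow] * log(x[pow] / M[pow])) / (L[pow] * S[pow])
  z
}

#' Invert an LMS z-score back to a raw measurement
#'
#' Exact inverse of [compute_zscore()]: x = M (1 + L S z)^(1/L), or
#' M exp(S z) in the log-limit. Errors if the Box-Cox inverse would be
#' non-positive (z too extreme for the given L, S).
#'
#' @param z z-score(s).
#' @inheritParams compute_zscore
#' @return Measurement(s) on the raw scale.
#' @export
invert_zscore <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  ok <- !is.na(z) & !is.na(L) & !is.na(M) & !is.na(S)
  if (any(ok & (M <= 0 | S <= 0))) stop("invert_zscore: M and S must be positive")
  x <- rep(NA_real_, n)
  loglim <- ok & abs(L) < 1e-7
  pow <- ok & !loglim
  x[loglim] <- M[loglim] * exp(S[loglim] * z[loglim])
  lsz <- L[pow] * S[pow] * z[pow]
  if (any(lsz <= -1)) {
    stop("invert_zscore: z-score outside the domain of the Box-Cox inverse")
  }
  x[pow] <- M[pow] * exp(log1p(lsz) / L[pow])
  x
}

#' Look up interpolated L, M, S values
#'
#' Linear interpolation of each of L, M and S in the index variable between
#' bracketing grid points; exact at grid points. Index values outside the
#' grid range for the requested sex and axis raise an error naming the axis
#' and its bounds.
#'
#' @param ref an `lms_reference`.
#' @param sex "F" or "M" (recycled).
#' @param index_value age in days (`axis = "age"`) or length in cm
#'   (`axis = "length"`).
#' @param axis "age" or "length".
#' @return data.frame with columns `L`, `M`, `S`.
#' @export
lookup_lms <- function(ref, sex, index_value, axis) {
  stopifnot(inherits(ref, "lms_reference"))
  axis <- match.arg(axis, c("age", "length"))
  n <- max(length(sex), length(index_value))
  sex <- rep_len(sex, n); index_value <- rep_len(index_value, n)
  out <- data.frame(L = rep(NA_real_, n), M = NA_real_, S = NA_real_)
  for (sx in unique(sex[!is.na(sex)])) {
    g <- ref$table[ref$table$sex == sx & ref$table$axis == axis, ]
    if (nrow(g) == 0L) stop("LMS reference has no rows for sex ", sx, ", axis ", axis)
    sel <- which(!is.na(index_value) & sex == sx)
    iv <- index_value[sel]
    bad <- iv < min(g$index_value) | iv > max(g$index_value)
    if (any(bad)) {
      stop(sprintf(
        "lookup_lms: index value %g outside the '%s' grid range [%g, %g] for sex %s",
        iv[bad][1], axis, min(g$index_value), max(g$index_value), sx))
    }
    out$L[sel] <- stats::approx(g$index_value, g$L, xout = iv)$y
    out$M[sel] <- stats::approx(g$index_value, g$M, xout = iv)$y
    out$S[sel] <- stats::approx(g$index_value, g$S, xout = iv)$y
  }
  out
}

#' Classify anthropometric state
#'
#' Applies the standard strict thresholds: wasted iff WLZ < -2, stunted iff
#' LAZ < -2, concurrent iff both, small MUAC iff MUAC < 12.5 cm. Missing
#' inputs give missing flags (never false-by-default).
#'
#' @param laz,wlz z-scores (may contain NA).
#' @param muac mid-upper arm circumference in cm, or NULL if unmeasured.
#' @return data.frame with logical columns `wasted`, `stunted`, `concurrent`,
#'   `small_muac`.
#' @export
classify_anthro <- function(laz, wlz, muac = NULL) {
  n <- max(length(laz), length(wlz), length(muac))
  laz <- rep_len(laz, n); wlz <- rep_len(wlz, n)
  wasted <- wlz < -2
  stunted <- laz < -2
  concurrent <- wasted & stunted
  small_muac <- if (is.null(muac)) rep(NA, n) else rep_len(muac, n) < 12.5
  data.frame(wasted = wasted, stunted = stunted,
             concurrent = concurrent, small_muac = small_muac)
}

#' Attach z-scores and classification flags to a visit table
#'
#' Computes age in days and completed months, LAZ (length against the
#' age-indexed reference) and WLZ (weight against the length-indexed
#' reference), and the classification flags. Completed months use
#' floor(age_days / 30.4375).
#'
#' @param visits data.frame with columns `subject_id`, `sex`, `dob`,
#'   `visit_date`, `weight_kg`, `length_cm` and optionally `muac_cm`
#'   (dates as `Date` or ISO-8601 strings).
#' @param ref an `lms_reference`.
#' @return The visit table with added columns `age_days`, `age_months`
#'   (completed), `laz`, `wlz`, `wasted`, `stunted`, `concurrent`,
#'   `small_muac`.
#' @export
add_zscores <- function(visits, ref) {
  req <- c("subject_id", "sex", "dob", "visit_date", "weight_kg", "length_cm")
  miss <- setdiff(req, names(visits))
  if (length(miss) > 0L) stop("visit table is missing columns: ", paste(miss, collapse = ", "))
  visits <- as.data.frame(visits)
  visits$dob <- as.Date(visits$dob)
  visits$visit_date <- as.Date(visits$visit_date)
  if (any(visits$visit_date < visits$dob, na.rm = TRUE)) {
    stop("add_zscores: visit_date before dob")
  }
  visits$age_days <- as.numeric(visits$visit_date - visits$dob)
  visits$age_months <- floor(visits$age_days / DAYS_PER_MONTH)
  la <- lookup_lms(ref, visits$sex, visits$age_days, axis = "age")
  visits$laz <- compute_zscore(visits$length_cm, la$L, la$M, la$S)
  wl <- lookup_lms(ref, visits$sex, visits$length_cm, axis = "length")
  visits$wlz <- compute_zscore(visits$weight_kg, wl$L, wl$M, wl$S)
  muac <- if ("muac_cm" %in% names(visits)) visits$muac_cm else NULL
  fl <- classify_anthro(visits$laz, visits$wlz, muac)
  visits$wasted <- fl$wasted
  visits$stunted <- fl$stunted
  visits$concurrent <- fl$concurrent
  visits$small_muac <- fl$small_muac
  visits
}
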