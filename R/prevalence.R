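# Cross-sectional prevalence by completed month of age, the monthly
# mean-then-classify rule, and the stunted-at-20-24-months outcome.

#' Monthly classification of subjects
#'
#' Collapses visits to one row per subject and completed month of age
#' (0-23): when a subject has more than one measurement in a month, the mean
#' z-score within the month is computed first and the classification applied
#' to the mean (mean-then-classify, not classify-then-any).
#'
#' @param visits cleaned visit table with z-scores and `age_months`.
#' @return data.frame: `subject_id`, `sex`, `month`, `mean_laz`, `mean_wlz`,
#'   `stunted`, `wasted`, `concurrent`.
#' @export
monthly_classification <- function(visits) {
  v <- visits[!is.na(visits$age_months) &
                visits$age_months >= 0 & visits$age_months <= 23, , drop = FALSE]
  if (nrow(v) == 0L) stop("monthly_classification: no visits at ages 0-23 months")
  key <- interaction(v$subject_id, v$month <- v$age_months, drop = TRUE)
  agg <- function(x) tapply(x, key, function(u) {
    u <- u[!is.na(u)]
    if (length(u) == 0L) NA_real_ else mean(u)
  })
  first <- function(x) tapply(x, key, `[`, 1L)
  out <- data.frame(
    subject_id = as.vector(first(as.character(v$subject_id))),
    sex = as.vector(first(as.character(v$sex))),
    month = as.integer(as.vector(agg(v$age_months))),
    mean_laz = as.vector(agg(v$laz)),
    mean_wlz = as.vector(agg(v$wlz)),
    stringsAsFactors = FALSE
  )
  fl <- classify_anthro(out$mean_laz, out$mean_wlz)
  out$stunted <- fl$stunted
  out$wasted <- fl$wasted
  out$concurrent <- fl$concurrent
  out <- out[order(out$subject_id, out$month), ]
  rownames(out) <- NULL
  out
}

#' Prevalence of stunting, wasting and concurrence by sex and month of age
#'
#' One row per sex and completed month of age 0-23; `n` counts subjects
#' contributing to the bin (after monthly collapsing, so each subject counts
#' once per bin) and percentages are 100 x flagged / classifiable subjects.
#' Empty bins carry `n = 0` and missing percentages.
#'
#' @param monthly output of [monthly_classification()].
#' @return data.frame: `sex`, `month`, `n`, `pct_stunted`, `pct_wasted`,
#'   `pct_concurrent`.
#' @export
prevalence_table <- function(monthly) {
  grid <- expand.grid(sex = sort(unique(monthly$sex)), month = 0:23,
                      stringsAsFactors = FALSE)
  pct <- function(flag) {
    flag <- flag[!is.na(flag)]
    if (length(flag) == 0L) NA_real_ else 100 * mean(flag)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- monthly[monthly$sex == grid$sex[i] & monthly$month == grid$month[i], ]
    data.frame(sex = grid$sex[i], month = grid$month[i], n = nrow(g),
               pct_stunted = pct(g$stunted), pct_wasted = pct(g$wasted),
               pct_concurrent = pct(g$concurrent))
  })
  out <- do.call(rbind, rows)
  out[order(out$sex, out$month), ]
}

#' Binary outcome: stunted between 20 and 24 months of age
#'
#' Default rule ("mean"): a subject is stunted iff the mean LAZ over all
#' visits at completed ages 20-23 months is < -2. Alternative rule ("any"):
#' stunted iff any monthly-bin classification in that window is stunted.
#' Subjects with no visits in the window get a missing outcome.
#'
#' @param visits cleaned visit table with `laz` and `age_months`.
#' @param rule "mean" (default) or "any".
#' @return data.frame: `subject_id`, `stunted_20_24` (logical, NA when the
#'   window holds no visits).
#' @export
outcome_stunted_20_24 <- function(visits, rule = c("mean", "any")) {
  rule <- match.arg(rule)
  subjects <- unique(as.character(visits$subject_id))
  win <- visits[!is.na(visits$age_months) &
                  visits$age_months >= 20 & visits$age_months <= 23 &
                  !is.na(visits$laz), , drop = FALSE]
  if (rule == "mean") {
    m <- tapply(win$laz, win$subject_id, mean)
    val <- m < -2
  } else {
    mo <- monthly_classification(win)
    val <- tapply(mo$stunted, mo$subject_id, function(x) any(x, na.rm = TRUE))
  }
  out <- data.frame(subject_id = subjects,
                    stunted_20_24 = as.logical(val[subjects]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Prevalence tables within groups
#'
#' Repeats [prevalence_table()] inside each level of a grouping variable:
#' the subject-level 20-24-month stunting outcome, or the observation-level
#' current wasted / current stunted flag.
#'
#' @param monthly output of [monthly_classification()].
#' @param grouping one of "outcome_20_24", "current_wasted",
#'   "current_stunted".
#' @param outcome for `grouping = "outcome_20_24"`, the data.frame from
#'   [outcome_stunted_20_24()].
#' @return stacked prevalence rows with a leading `group` column.
#' @export
grouped_prevalence <- function(monthly,
                               grouping = c("outcome_20_24", "current_wasted",
                                            "current_stunted"),
                               outcome = NULL) {
  grouping <- tryCatch(match.arg(grouping),
                       error = function(e) stop("unknown grouping label"))
  if (grouping == "outcome_20_24") {
    if (is.null(outcome)) stop("grouping = 'outcome_20_24' requires the outcome table")
    g <- outcome$stunted_20_24[match(monthly$subject_id, outcome$subject_id)]
  } else if (grouping == "current_wasted") {
    g <- monthly$wasted
  } else {
    g <- monthly$stunted
  }
  keep <- !is.na(g)
  monthly <- monthly[keep, , drop = FALSE]
  g <- g[keep]
  out <- do.call(rbind, lapply(sort(unique(g)), function(lev) {
    tab <- prevalence_table(monthly[g == lev, , drop = FALSE])
    cbind(group = lev, tab)
  }))
  rownames(out) <- NULL
  out
}

#' Smooth a prevalence series across age (presentation only)
#'
#' Local linear regression with tricube weights (loess, degree 1) at a fixed
#' span of 0.6, for Figure-style display of monthly prevalence curves.
#'
#' @param month month-of-age vector.
#' @param pct prevalence percentages.
#' @param span loess span (default 0.6).
#' @return data.frame `month`, `smoothed`.
#' @export
smooth_prevalence <- function(month, pct, span = 0.6) {
  ok <- !is.na(pct)
  fit <- stats::loess(pct[ok] ~ month[ok], span = span, degree = 1,
                      family = "gaussian")
  data.frame(month = month[ok], smoothed = stats::predict(fit))
}
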