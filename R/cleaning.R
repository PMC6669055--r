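# Cohort cleaning: implausible z-scores, extreme between-visit changes, and
# the participant-vs-visit exclusion accounting.

#' Exclude visits with biologically implausible z-scores
#'
#' A visit is excluded iff LAZ > 6, LAZ < -6, WLZ > 5 or WLZ < -5 (all
#' strict). Visits with missing z-scores are not excluded by this rule.
#'
#' @param visits visit table with `laz` and `wlz` columns.
#' @return list with `kept`, `excluded` (with a `reason` column) and
#'   `fragment` (named exclusion count).
#' @export
filter_implausible <- function(visits) {
  bad <- (!is.na(visits$laz) & (visits$laz > 6 | visits$laz < -6)) |
         (!is.na(visits$wlz) & (visits$wlz > 5 | visits$wlz < -5))
  excluded <- visits[bad, , drop = FALSE]
  if (nrow(excluded) > 0L) excluded$reason <- "implausible_z"
  else excluded$reason <- character(0)
  list(kept = visits[!bad, , drop = FALSE],
       excluded = excluded,
       fragment = c(implausible_z = sum(bad)))
}

# One measure's extreme-change pass over a single subject's chronologically
# ordered z values. Returns the indices (into z) to exclude. The subject
# median is fixed at entry; the pair member farther from it is excluded, ties
# going to the later visit; the scan repeats until no |delta z| > 3 remains.
.extreme_change_subject <- function(z, threshold = 3) {
  med <- stats::median(z, na.rm = TRUE)
  keep <- rep(TRUE, length(z))
  if (is.na(med) || sum(!is.na(z)) < 2L) return(integer(0))
  repeat {
    idx <- which(keep & !is.na(z))
    if (length(idx) < 2L) break
    dz <- abs(diff(z[idx]))
    v <- which(dz > threshold)
    if (length(v) == 0L) break
    a <- idx[v[1]]; b <- idx[v[1] + 1L]
    da <- abs(z[a] - med); db <- abs(z[b] - med)
    keep[if (db >= da) b else a] <- FALSE
  }
  which(!keep)
}

#' Exclude outlying visits in extreme between-visit z-score changes
#'
#' For each within-subject pair of consecutive visits whose z-scores differ
#' by more than 3 SD, the pair member farther from that subject's median
#' z-score is excluded; the pass repeats until no violating pair remains.
#' Applied to LAZ first, then to WLZ on the visits surviving the LAZ pass;
#' a visit failing either instance is excluded entirely.
#'
#' @param visits visit table with `subject_id`, `visit_date`, `laz`, `wlz`.
#' @param threshold change threshold in z-score units (default 3).
#' @return list with `kept`, `excluded` (reason `extreme_change_laz` or
#'   `extreme_change_wlz`) and `fragment`.
#' @export
filter_extreme_change <- function(visits, threshold = 3) {
  visits <- visits[order(visits$subject_id, as.Date(visits$visit_date)), , drop = FALSE]
  excluded <- visits[0, , drop = FALSE]
  excluded$reason <- character(0)
  fragment <- c(extreme_change_laz = 0L, extreme_change_wlz = 0L)
  for (measure in c("laz", "wlz")) {
    drop_rows <- unlist(lapply(split(seq_len(nrow(visits)), visits$subject_id),
                               function(rows) {
      if (length(rows) < 2L) return(integer(0))
      rows[.extreme_change_subject(visits[[measure]][rows], threshold)]
    }), use.names = FALSE)
    if (length(drop_rows) > 0L) {
      exc <- visits[drop_rows, , drop = FALSE]
      exc$reason <- paste0("extreme_change_", measure)
      excluded <- rbind(excluded, exc)
      fragment[paste0("extreme_change_", measure)] <- length(drop_rows)
      visits <- visits[-drop_rows, , drop = FALSE]
    }
  }
  list(kept = visits, excluded = excluded, fragment = fragment)
}

#' Assemble a participant-vs-visit cleaning report
#'
#' Verifies the conservation invariant (input visits = output visits + per-
#' rule exclusions) and moves subjects left with zero visits to the
#' participant-level exclusion list.
#'
#' @param input visit table before cleaning.
#' @param kept visit table after cleaning.
#' @param fragments named integer vector of per-rule exclusion counts.
#' @return An object of class `cleaning_report`.
#' @export
build_cleaning_report <- function(input, kept, fragments) {
  n_in_v <- nrow(input)
  n_out_v <- nrow(kept)
  if (n_in_v != n_out_v + sum(fragments)) {
    stop("cleaning report internal consistency error: ",
         n_in_v, " != ", n_out_v, " + ", sum(fragments))
  }
  subj_in <- unique(input$subject_id)
  subj_out <- unique(kept$subject_id)
  dropped_subjects <- setdiff(subj_in, subj_out)
  structure(list(
    n_subjects_in = length(subj_in),
    n_visits_in = n_in_v,
    visits_excluded = as.list(fragments),
    subjects_excluded = dropped_subjects,
    n_subjects_excluded = length(dropped_subjects),
    n_subjects_out = length(subj_out),
    n_visits_out = n_out_v
  ), class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cohort cleaning report\n")
  cat(sprintf("  input : %d subjects, %d visits\n", x$n_subjects_in, x$n_visits_in))
  for (rule in names(x$visits_excluded)) {
    cat(sprintf("  visits excluded (%s): %d\n", rule, x$visits_excluded[[rule]]))
  }
  cat(sprintf("  participants excluded (no visits left): %d\n", x$n_subjects_excluded))
  cat(sprintf("  output: %d subjects, %d visits\n", x$n_subjects_out, x$n_visits_out))
  invisible(x)
}

#' Apply the full cleaning sequence
#'
#' Implausible z-scores first, then extreme between-visit changes (computed
#' on the already-filtered sequences). Running the result through the
#' cleaning a second time excludes nothing.
#'
#' @param visits visit table with z-scores (see [add_zscores()]).
#' @param threshold extreme-change threshold in z units.
#' @return list of class `cleaning_result`: `visits` (kept), `excluded`
#'   (with reason codes), `report` (a `cleaning_report`).
#' @export
clean_cohort <- function(visits, threshold = 3) {
  s1 <- filter_implausible(visits)
  s2 <- filter_extreme_change(s1$kept, threshold)
  excluded <- rbind(s1$excluded, s2$excluded)
  report <- build_cleaning_report(visits, s2$kept, c(s1$fragment, s2$fragment))
  structure(list(visits = s2$kept, excluded = excluded, report = report),
            class = "cleaning_result")
}

#' Serialise a cleaning report to JSON
#' @param report a `cleaning_report`.
#' @return JSON string.
#' @export
cleaning_report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
}
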