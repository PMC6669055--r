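# Calendrical wet/dry seasons and per-infant episode windows.
# Wet season: July-October inclusive; dry season: November-June.

#' Season of a calendar date
#'
#' @param date `Date` vector (or coercible).
#' @return character vector, "wet" (months July-October) or "dry".
#' @export
season_of <- function(date) {
  m <- as.POSIXlt(as.Date(date))$mon + 1L
  ifelse(m %in% 7:10, "wet", "dry")
}

#' First-wet / intervening-dry / second-wet windows of life
#'
#' The first wet season is the wet window (1 July - 31 October) containing
#' the date of birth if the child was born during the wet season, otherwise
#' the first wet window starting after birth. The second wet season is the
#' following year's wet window and the intervening dry season (1 November -
#' 30 June) sits between them. Both window endpoints are inclusive.
#'
#' @param dob date of birth (single `Date` or coercible).
#' @return data.frame with columns `ordinal` ("wet1", "dry", "wet2"),
#'   `label` ("wet"/"dry"), `start`, `end`.
#' @export
life_season_windows <- function(dob) {
  dob <- as.Date(dob)
  stopifnot(length(dob) == 1L, !is.na(dob))
  lt <- as.POSIXlt(dob)
  y <- lt$year + 1900L
  m <- lt$mon + 1L
  wet1_year <- if (m <= 10L) y else y + 1L
  wet <- function(yy) c(as.Date(sprintf("%d-07-01", yy)), as.Date(sprintf("%d-10-31", yy)))
  w1 <- wet(wet1_year)
  w2 <- wet(wet1_year + 1L)
  data.frame(
    ordinal = c("wet1", "dry", "wet2"),
    label = c("wet", "dry", "wet"),
    start = c(w1[1], as.Date(sprintf("%d-11-01", wet1_year)), w2[1]),
    end = c(w1[2], as.Date(sprintf("%d-06-30", wet1_year + 1L)), w2[2])
  )
}

#' Per-subject seasonal episode summary
#'
#' For each subject, counts visits and computes the median WLZ inside each of
#' the three life windows (first wet, intervening dry, second wet). A window
#' is "wasted" iff its median WLZ < -2; a subject is eligible iff every
#' window holds at least one observation. Even-count medians use the
#' midpoint of the two central values.
#'
#' @param visits cleaned visit table with `subject_id`, `dob`, `visit_date`,
#'   `wlz`.
#' @param include_birth_visit logical; if `FALSE`, the visit on the day of
#'   birth is not counted as a within-window observation.
#' @return data.frame with one row per subject: `subject_id`, `n_wet1`,
#'   `n_dry`, `n_wet2`, `med_wlz_wet1`, `med_wlz_dry`, `med_wlz_wet2`,
#'   `wasted_wet1`, `wasted_dry`, `wasted_wet2`, `eligible`.
#' @export
summarize_episodes <- function(visits, include_birth_visit = TRUE) {
  visits <- as.data.frame(visits)
  visits$dob <- as.Date(visits$dob)
  visits$visit_date <- as.Date(visits$visit_date)
  if (!include_birth_visit) {
    visits <- visits[visits$visit_date != visits$dob, , drop = FALSE]
  }
  rows <- lapply(split(visits, visits$subject_id), function(v) {
    win <- life_season_windows(v$dob[1])
    out <- list(subject_id = v$subject_id[1])
    for (i in seq_len(3L)) {
      ord <- win$ordinal[i]
      inw <- v$visit_date >= win$start[i] & v$visit_date <= win$end[i]
      wlz <- v$wlz[inw & !is.na(v$wlz)]
      out[[paste0("n_", ord)]] <- length(wlz)
      med <- if (length(wlz) > 0L) stats::median(wlz) else NA_real_
      out[[paste0("med_wlz_", ord)]] <- med
      out[[paste0("wasted_", ord)]] <- if (length(wlz) > 0L) med < -2 else NA
    }
    out$eligible <- out$n_wet1 >= 1L && out$n_dry >= 1L && out$n_wet2 >= 1L
    as.data.frame(out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
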