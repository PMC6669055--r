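# Shared fixtures and independent brute-force oracles.

# Build a visit table directly from per-subject z-score sequences (bypassing
# raw anthropometry) for tests of cleaning, seasons, prevalence and lag
# logic. `visits` is a list of lists with fields: id, sex, dob, dates (or
# age_days), laz, wlz.
make_visits <- function(subjects) {
  rows <- lapply(subjects, function(s) {
    dob <- as.Date(s$dob %||% "1990-01-01")
    if (!is.null(s$age_days)) {
      dates <- dob + s$age_days
    } else {
      dates <- as.Date(s$dates)
    }
    n <- length(dates)
    laz <- rep_len(s$laz %||% -1, n)
    wlz <- rep_len(s$wlz %||% -1, n)
    data.frame(
      subject_id = s$id, sex = s$sex %||% "F", dob = dob, visit_date = dates,
      age_days = as.numeric(dates - dob),
      age_months = floor(as.numeric(dates - dob) / 30.4375),
      laz = laz, wlz = wlz,
      wasted = wlz < -2, stunted = laz < -2,
      concurrent = wlz < -2 & laz < -2,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent naive implementation of the full cleaning semantics, working
# over explicit pair enumeration: implausible rule first, then for each
# measure repeatedly scan all consecutive pairs and drop the member farther
# from the subject median (ties: later visit).
oracle_clean <- function(visits, threshold = 3) {
  v <- visits[order(visits$subject_id, visits$visit_date), , drop = FALSE]
  imp <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(v))) {
    laz <- v$laz[i]; wlz <- v$wlz[i]
    if (!is.na(laz) && (laz > 6 || laz < -6)) imp[i] <- TRUE
    if (!is.na(wlz) && (wlz > 5 || wlz < -5)) imp[i] <- TRUE
  }
  v <- v[!imp, , drop = FALSE]
  for (measure in c("laz", "wlz")) {
    for (sid in unique(v$subject_id)) {
      med <- stats::median(v[[measure]][v$subject_id == sid], na.rm = TRUE)
      repeat {
        rows <- which(v$subject_id == sid)
        if (length(rows) < 2L) break
        z <- v[[measure]][rows]
        found <- FALSE
        for (i in seq_len(length(rows) - 1L)) {
          if (is.na(z[i]) || is.na(z[i + 1])) next
          if (abs(z[i + 1] - z[i]) > threshold) {
            drop <- if (abs(z[i + 1] - med) >= abs(z[i] - med)) rows[i + 1] else rows[i]
            v <- v[-drop, , drop = FALSE]
            found <- TRUE
            break
          }
        }
        if (!found) break
      }
    }
  }
  v
}

# Independent lag matcher: enumerate every prior visit, filter the window,
# take argmin |lag - target| with ties toward the longer lag.
oracle_match <- function(visits, target = 3, window = c(2.5, 3.5)) {
  v <- visits[order(visits$subject_id, visits$visit_date), , drop = FALSE]
  out <- NULL
  for (sid in unique(v$subject_id)) {
    rows <- which(v$subject_id == sid)
    for (i in rows) {
      best <- NA_integer_; best_score <- Inf; best_lag <- -Inf
      for (j in rows) {
        lag <- as.numeric(v$visit_date[i] - v$visit_date[j]) / 30.4375
        if (lag <= 0 || lag < window[1] || lag > window[2]) next
        score <- abs(lag - target)
        if (score < best_score || (score == best_score && lag > best_lag)) {
          best <- j; best_score <- score; best_lag <- lag
        }
      }
      if (!is.na(best)) {
        out <- rbind(out, data.frame(subject_id = sid,
                                     date_now = v$visit_date[i],
                                     date_prior = v$visit_date[best],
                                     lag_months = best_lag))
      }
    }
  }
  out
}

# Brute-force confusion-matrix rates (percent).
oracle_diagnostics <- function(p, obs, threshold) {
  tp <- sum(p >= threshold & obs); fn <- sum(p < threshold & obs)
  fp <- sum(p >= threshold & !obs); tn <- sum(p < threshold & !obs)
  list(error_rate = 100 * (fn + fp) / (tp + fn + fp + tn),
       fnr = 100 * fn / (tp + fn),
       fpr = 100 * fp / (fp + tn))
}

# A random small cohort of z-score sequences for property tests.
random_small_cohort <- function(n_subjects, seed, p_spike = 0.1) {
  set.seed(seed)
  subs <- lapply(seq_len(n_subjects), function(i) {
    k <- sample(1:8, 1)
    dob <- as.Date("1990-01-01") + sample(0:600, 1)
    laz <- round(cumsum(c(stats::rnorm(1, -1, 1), stats::rnorm(k - 1, 0, 0.6))), 3)
    wlz <- round(cumsum(c(stats::rnorm(1, -0.5, 1), stats::rnorm(k - 1, 0, 0.6))), 3)
    spike <- stats::runif(k) < p_spike
    laz[spike] <- laz[spike] + sample(c(-1, 1), sum(spike), TRUE) * stats::runif(sum(spike), 3, 8)
    list(id = sprintf("R%03d", i), sex = sample(c("F", "M"), 1), dob = dob,
         age_days = sort(sample(0:750, k)), laz = laz, wlz = wlz)
  })
  make_visits(subs)
}
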