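# Seeded synthetic cohort generator with ground-truth manifests, plus a
# lagged binary Markov panel for logistic recovery testing. The two
# pathways are deliberately separate: the continuous z-score cohort feeds
# the cleaning/prevalence/growth modules, the binary panel feeds the
# multilevel logistic models; they are not forced to be mutually
# consistent.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a strongly seasonal subsistence-farming setting with a
#' July-October lean season: births spread across the calendar year; a visit
#' schedule of birth, 6 weeks, 3 months and then 3-monthly to 24 months with
#' imperfect attendance and jittered dates; an age-declining mean LAZ; a
#' seasonally forced mean WLZ with early postnatal catch-up and a
#' mid-wet-season trough; per-subject random intercepts, age slopes and
#' annual-harmonic seasonal pairs; a lagged wasting-to-stunting coupling;
#' and an optional rate of planted implausible/extreme-change outliers.
#'
#' @param n_subjects number of children.
#' @param birth_start,birth_end date range over which births are uniform.
#' @param attend_prob per-visit attendance probability (birth visit uses
#'   `attend_prob_birth`).
#' @param attend_prob_birth attendance probability of the birth visit.
#' @param jitter_sd SD (days) of normal visit-date jitter, truncated at
#'   `jitter_max`; the birth visit is not jittered.
#' @param jitter_max truncation bound for jitter (days).
#' @param laz_birth,laz_24 mean LAZ at birth and at 24 months (linear
#'   decline in between).
#' @param wlz_age_points,wlz_age_values control points (months; z) of the
#'   mean WLZ age curve, interpolated linearly.
#' @param amplitude fixed seasonal forcing amplitude of WLZ (z units).
#' @param peak_deficit_doy day of year of the largest WLZ deficit.
#' @param amp_age_slope relative change of the forcing amplitude per month
#'   of age about 12 months (0 = age-constant forcing).
#' @param laz_amplitude,laz_peak_deficit_doy seasonal forcing of LAZ
#'   (smaller, phase-delayed relative to WLZ).
#' @param sd_u0_wlz,sd_u1_wlz,sd_seasonal,resid_wlz WLZ random-effect SDs
#'   (intercept; slope per month; each seasonal pair component) and
#'   residual SD.
#' @param sd_u0_laz,sd_u1_laz,resid_laz LAZ counterparts.
#' @param coupling_wlz_to_laz LAZ deficit (z) added per earlier wasted
#'   visit, capped at `coupling_cap` episodes.
#' @param coupling_cap maximum number of wasted episodes that accumulate.
#' @param sex_deficit_laz,sex_deficit_wlz additional mean deficit in boys.
#' @param outlier_rate fraction of visits corrupted by [plant_outliers()]
#'   (0 to 0.1).
#' @param panel_ages ages (months) of the binary Markov panel.
#' @param panel_sd_u subject random-intercept SD of the panel transitions.
#' @param panel_init_p_stunt,panel_init_p_wast initial state probabilities.
#' @param b0_stunt,b_sex_stunt,b_age_stunt,b_stunt_stunt,b_wast_stunt
#'   transition log-odds of the stunting chain: baseline, sex (boy), lagged
#'   age per month, lagged stunting (persistence), lagged wasting
#'   (coupling).
#' @param b0_wast,b_sex_wast,b_age_wast,b_stunt_wast,b_wast_wast wasting
#'   chain counterparts.
#' @param seed integer seed fixing the entire output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_subjects = 500,
    birth_start = "1990-01-01", birth_end = "1993-12-31",
    attend_prob = 0.9, attend_prob_birth = 0.95,
    jitter_sd = 7, jitter_max = 21,
    laz_birth = -0.45, laz_24 = -1.45,
    wlz_age_points = c(0, 2.5, 12, 24),
    wlz_age_values = c(-0.55, 0.05, -0.9, -0.5),
    amplitude = 0.4, peak_deficit_doy = 258, amp_age_slope = 0.02,
    laz_amplitude = 0.15, laz_peak_deficit_doy = 348,
    sd_u0_wlz = 0.55, sd_u1_wlz = 0.02, sd_seasonal = 0.5, resid_wlz = 0.6,
    sd_u0_laz = 0.9, sd_u1_laz = 0.03, resid_laz = 0.45,
    coupling_wlz_to_laz = 0.18, coupling_cap = 3,
    sex_deficit_laz = 0.12, sex_deficit_wlz = 0.08,
    outlier_rate = 0,
    panel_ages = seq(3, 24, by = 3), panel_sd_u = 0.7,
    panel_init_p_stunt = 0.10, panel_init_p_wast = 0.10,
    b0_stunt = log(0.012), b_sex_stunt = log(1.6), b_age_stunt = log(1.1),
    b_stunt_stunt = log(8.2), b_wast_stunt = log(3.2),
    b0_wast = log(0.013), b_sex_wast = log(1.5), b_age_wast = 0,
    b_stunt_wast = log(1.5), b_wast_wast = log(2.9),
    seed = 20190207) {
  cfg <- as.list(environment())
  probs <- c("attend_prob", "attend_prob_birth", "panel_init_p_stunt",
             "panel_init_p_wast")
  sds <- c("jitter_sd", "amplitude", "laz_amplitude", "sd_u0_wlz", "sd_u1_wlz",
           "sd_seasonal", "resid_wlz", "sd_u0_laz", "sd_u1_laz", "resid_laz",
           "panel_sd_u")
  bad <- c(
    probs[vapply(probs, function(nm) cfg[[nm]] < 0 || cfg[[nm]] > 1, logical(1))],
    sds[vapply(sds, function(nm) cfg[[nm]] < 0, logical(1))],
    if (cfg$outlier_rate < 0 || cfg$outlier_rate > 0.1) "outlier_rate",
    if (cfg$n_subjects < 1) "n_subjects",
    if (length(cfg$wlz_age_points) != length(cfg$wlz_age_values)) "wlz_age_points",
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) "seed")
  if (length(bad) > 0L) {
    stop("invalid synthetic_config fields: ", paste(unique(bad), collapse = ", "))
  }
  structure(cfg, class = "synthetic_config")
}

# Scheduled visit ages in days: birth, 6 weeks, 3 months, then 3-monthly.
.visit_schedule_days <- function() c(0, 42, DAYS_PER_MONTH * 3 * (1:8))

.wlz_mean_curve <- function(age_mo, config) {
  stats::approx(config$wlz_age_points, config$wlz_age_values, xout = age_mo,
                rule = 2)$y
}

.laz_mean_curve <- function(age_mo, config) {
  config$laz_birth + (config$laz_24 - config$laz_birth) * age_mo / 24
}

.seasonal_forcing <- function(doy, age_mo, amplitude, peak_doy, age_slope) {
  scale <- pmax(1 + age_slope * (age_mo - 12), 0)
  -amplitude * scale * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subjects, visit schedules and random effects under the
#' configuration, computes true and noisy LAZ/WLZ, applies the lagged
#' wasting-to-stunting coupling, back-computes raw length and weight
#' through the LMS reference (so the z-score pathway is exercised
#' end-to-end), and plants outliers when `outlier_rate > 0`. Identical
#' seeds give identical output.
#'
#' @param config a [synthetic_config()].
#' @param lms the LMS reference used to invert z-scores to raw
#'   measurements.
#' @return list of class `synthetic_cohort`: `visits` (the raw visit-table
#'   schema consumed by the pipeline plus `visit_id`) and `truth` (subject
#'   random effects, per-visit true/observed z-scores, planted-outlier
#'   manifest, the config).
#' @export
generate_cohort <- function(config = synthetic_config(), lms = toy_lms_reference()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    dob = as.Date(config$birth_start) +
      sample.int(as.integer(as.Date(config$birth_end) - as.Date(config$birth_start)) + 1L,
                 n, replace = TRUE) - 1L,
    u0_wlz = stats::rnorm(n, 0, config$sd_u0_wlz),
    u1_wlz = stats::rnorm(n, 0, config$sd_u1_wlz),
    a_seas = stats::rnorm(n, 0, config$sd_seasonal),
    b_seas = stats::rnorm(n, 0, config$sd_seasonal),
    u0_laz = stats::rnorm(n, 0, config$sd_u0_laz),
    u1_laz = stats::rnorm(n, 0, config$sd_u1_laz),
    stringsAsFactors = FALSE)
  subjects$true_amplitude <- compute_ccv(subjects$a_seas, subjects$b_seas)

  sched <- .visit_schedule_days()
  k <- length(sched)
  idx <- rep(seq_len(n), each = k)
  slot <- rep(seq_len(k), times = n)
  attend <- stats::runif(n * k) <
    ifelse(slot == 1L, config$attend_prob_birth, config$attend_prob)
  jit <- pmin(pmax(stats::rnorm(n * k, 0, config$jitter_sd),
                   -config$jitter_max), config$jitter_max)
  age_days <- round(sched[slot] + ifelse(slot == 1L, 0, jit))
  age_days[slot != 1L] <- pmax(age_days[slot != 1L], 1)
  keep <- attend
  v <- data.frame(
    subject_idx = idx[keep],
    subject_id = subjects$subject_id[idx[keep]],
    sex = subjects$sex[idx[keep]],
    dob = subjects$dob[idx[keep]],
    age_days = age_days[keep],
    stringsAsFactors = FALSE)
  v$visit_date <- v$dob + v$age_days
  v <- v[order(v$subject_idx, v$age_days), ]
  # drop accidental same-day duplicates from jitter
  v <- v[!duplicated(v[c("subject_idx", "age_days")]), ]
  v$visit_id <- seq_len(nrow(v))
  age_mo <- v$age_days / DAYS_PER_MONTH
  doy <- day_of_year(v$visit_date)
  boy <- as.integer(v$sex == "M")
  s1 <- sin(2 * pi * doy / 365.25); c1 <- cos(2 * pi * doy / 365.25)

  wlz_true <- .wlz_mean_curve(age_mo, config) -
    boy * config$sex_deficit_wlz +
    .seasonal_forcing(doy, age_mo, config$amplitude, config$peak_deficit_doy,
                      config$amp_age_slope) +
    subjects$u0_wlz[v$subject_idx] + subjects$u1_wlz[v$subject_idx] * age_mo +
    subjects$a_seas[v$subject_idx] * s1 + subjects$b_seas[v$subject_idx] * c1
  wlz_obs <- wlz_true + stats::rnorm(nrow(v), 0, config$resid_wlz)

  # lagged coupling: each earlier wasted visit (observed WLZ < -2) deepens
  # the LAZ deficit, capped
  episodes <- unlist(lapply(split(seq_len(nrow(v)), v$subject_idx), function(rows) {
    w <- cumsum(c(0, (wlz_obs[rows] < -2)[-length(rows)]))
    pmin(w, config$coupling_cap)
  }), use.names = FALSE)

  laz_true <- .laz_mean_curve(age_mo, config) -
    boy * config$sex_deficit_laz -
    config$coupling_wlz_to_laz * episodes +
    .seasonal_forcing(doy, age_mo, config$laz_amplitude,
                      config$laz_peak_deficit_doy, 0) +
    subjects$u0_laz[v$subject_idx] + subjects$u1_laz[v$subject_idx] * age_mo
  laz_obs <- laz_true + stats::rnorm(nrow(v), 0, config$resid_laz)

  la <- lookup_lms(lms, v$sex, v$age_days, axis = "age")
  v$length_cm <- round(invert_zscore(laz_obs, la$L, la$M, la$S), 4)
  # recompute LAZ from the rounded length so raw data and truth agree
  laz_obs <- compute_zscore(v$length_cm, la$L, la$M, la$S)
  wl <- lookup_lms(lms, v$sex, v$length_cm, axis = "length")
  v$weight_kg <- round(invert_zscore(wlz_obs, wl$L, wl$M, wl$S), 4)
  wlz_obs <- compute_zscore(v$weight_kg, wl$L, wl$M, wl$S)
  v$muac_cm <- round(11.3 + 1.9 * (1 - exp(-age_mo / 6)) + 0.35 * wlz_obs +
                       stats::rnorm(nrow(v), 0, 0.3), 2)

  truth_visits <- data.frame(
    visit_id = v$visit_id, subject_id = v$subject_id,
    age_days = v$age_days,
    laz_true = laz_true, wlz_true = wlz_true,
    laz_obs = laz_obs, wlz_obs = wlz_obs,
    wasted_episodes_prior = episodes,
    stringsAsFactors = FALSE)
  visits <- v[c("visit_id", "subject_id", "sex", "dob", "visit_date",
                "weight_kg", "length_cm", "muac_cm")]
  rownames(visits) <- NULL
  cohort <- structure(list(
    visits = visits,
    truth = list(subjects = subjects, visits = truth_visits,
                 planted = data.frame(visit_id = integer(0), type = character(0),
                                      measure = character(0), z_value = numeric(0)),
                 config = config)
  ), class = "synthetic_cohort")
  if (config$outlier_rate > 0) {
    cohort <- plant_outliers(cohort, config$outlier_rate, lms = lms)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d visits, %d planted outliers (seed %d)\n",
              length(unique(x$visits$subject_id)), nrow(x$visits),
              nrow(x$truth$planted), x$truth$config$seed))
  invisible(x)
}

#' Plant implausible and extreme-change outliers
#'
#' Corrupts a fraction of visits: half become implausible z-scores (LAZ
#' pushed beyond +/-6 or WLZ beyond +/-5) and half become single-visit
#' spikes that create a > 3 SD change against the neighbouring visits while
#' staying inside the implausible bounds. Raw weight/length are recomputed
#' so the corruption survives the z-score pathway. Every planted record is
#' appended to the truth manifest with its intended violation type. Uses
#' the current RNG state (deterministic when called from
#' [generate_cohort()]).
#'
#' @param cohort a `synthetic_cohort`.
#' @param rate fraction of visits to corrupt, in 0 to 0.1.
#' @param lms the LMS reference for re-inverting z-scores.
#' @return the corrupted `synthetic_cohort` with an updated manifest.
#' @export
plant_outliers <- function(cohort, rate, lms = toy_lms_reference()) {
  stopifnot(inherits(cohort, "synthetic_cohort"), rate >= 0, rate <= 0.1)
  if (rate == 0) return(cohort)
  v <- cohort$visits
  tr <- cohort$truth$visits
  n_plant <- max(1L, round(rate * nrow(v)))
  # spikes need interior visits of subjects with >= 3 visits
  tab <- table(v$subject_id)
  ord <- stats::ave(seq_len(nrow(v)), v$subject_id, FUN = seq_along)
  len <- as.integer(tab[v$subject_id])
  interior <- which(len >= 3L & ord > 1L & ord < len)
  chosen <- sample(seq_len(nrow(v)), n_plant)
  planted <- data.frame(visit_id = integer(0), type = character(0),
                        measure = character(0), z_value = numeric(0))
  for (i in chosen) {
    spike_ok <- i %in% interior
    type <- if (spike_ok && stats::runif(1) < 0.5) "spike" else "implausible_z"
    measure <- sample(c("laz", "wlz"), 1L)
    if (type == "implausible_z") {
      z_new <- sample(c(-1, 1), 1L) *
        (if (measure == "laz") stats::runif(1, 6.6, 7.8) else stats::runif(1, 5.6, 6.8))
    } else {
      z_old <- if (measure == "laz") tr$laz_obs[i] else tr$wlz_obs[i]
      s <- if (z_old > 0) -1 else 1   # push away from the nearer bound
      z_new <- z_old + s * stats::runif(1, 4.4, 5.6)
      lim <- if (measure == "laz") 5.9 else 4.9
      z_new <- max(min(z_new, lim), -lim)
    }
    if (measure == "laz") {
      age <- tr$age_days[i]
      la <- lookup_lms(lms, v$sex[i], age, axis = "age")
      v$length_cm[i] <- round(invert_zscore(z_new, la$L, la$M, la$S), 4)
      tr$laz_obs[i] <- compute_zscore(v$length_cm[i], la$L, la$M, la$S)
      # keep WLZ as generated: recompute weight at the new length
      wl <- lookup_lms(lms, v$sex[i], v$length_cm[i], axis = "length")
      v$weight_kg[i] <- round(invert_zscore(tr$wlz_obs[i], wl$L, wl$M, wl$S), 4)
      tr$wlz_obs[i] <- compute_zscore(v$weight_kg[i], wl$L, wl$M, wl$S)
    } else {
      wl <- lookup_lms(lms, v$sex[i], v$length_cm[i], axis = "length")
      v$weight_kg[i] <- round(invert_zscore(z_new, wl$L, wl$M, wl$S), 4)
      tr$wlz_obs[i] <- compute_zscore(v$weight_kg[i], wl$L, wl$M, wl$S)
    }
    planted <- rbind(planted, data.frame(
      visit_id = v$visit_id[i], type = type, measure = measure, z_value = z_new))
  }
  cohort$visits <- v
  cohort$truth$visits <- tr
  cohort$truth$planted <- rbind(cohort$truth$planted, planted)
  cohort
}

#' Generate a lagged binary Markov panel with known transition log-odds
#'
#' Simulates per-subject 3-monthly binary (stunted, wasted) chains from the
#' logistic transition model with subject-level random intercepts (one per
#' outcome chain), returning the lagged panel in the [match_lagged()] pair
#' schema together with the true coefficient vectors for recovery tests.
#'
#' @param config a [synthetic_config()] (the `panel_*` and `b*` fields are
#'   used).
#' @return list: `panel` (subject_id, sex, age_now_mo, age_prior_mo,
#'   stunted_now, wasted_now, stunted_prior, wasted_prior, ...), `truth`
#'   (named true coefficient vectors and the random-intercept SD).
#' @export
generate_binary_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ages <- config$panel_ages
  k <- length(ages)
  sex <- stats::rbinom(n, 1, 0.5)
  u_s <- stats::rnorm(n, 0, config$panel_sd_u)
  u_w <- stats::rnorm(n, 0, config$panel_sd_u)
  st <- matrix(0L, n, k)
  wa <- matrix(0L, n, k)
  st[, 1] <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(config$panel_init_p_stunt) + u_s))
  wa[, 1] <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(config$panel_init_p_wast) + u_w))
  for (t in 2:k) {
    eta_s <- config$b0_stunt + config$b_sex_stunt * sex +
      config$b_age_stunt * ages[t - 1] + config$b_stunt_stunt * st[, t - 1] +
      config$b_wast_stunt * wa[, t - 1] + u_s
    eta_w <- config$b0_wast + config$b_sex_wast * sex +
      config$b_age_wast * ages[t - 1] + config$b_stunt_wast * st[, t - 1] +
      config$b_wast_wast * wa[, t - 1] + u_w
    st[, t] <- stats::rbinom(n, 1, stats::plogis(eta_s))
    wa[, t] <- stats::rbinom(n, 1, stats::plogis(eta_w))
  }
  id <- sprintf("P%05d", seq_len(n))
  panel <- do.call(rbind, lapply(2:k, function(t) data.frame(
    subject_id = id, sex = ifelse(sex == 1, "M", "F"),
    age_now_mo = ages[t], age_prior_mo = ages[t - 1],
    stunted_now = st[, t] == 1L, wasted_now = wa[, t] == 1L,
    stunted_prior = st[, t - 1] == 1L, wasted_prior = wa[, t - 1] == 1L,
    lag_months = ages[t] - ages[t - 1],
    stringsAsFactors = FALSE)))
  panel <- panel[order(panel$subject_id, panel$age_now_mo), ]
  rownames(panel) <- NULL
  truth <- list(
    stunting = c(`(Intercept)` = config$b0_stunt, sex_boy = config$b_sex_stunt,
                 age_lag = config$b_age_stunt, stunted_lag = config$b_stunt_stunt,
                 wasted_lag = config$b_wast_stunt),
    wasting = c(`(Intercept)` = config$b0_wast, sex_boy = config$b_sex_wast,
                age_lag = config$b_age_wast, stunted_lag = config$b_stunt_wast,
                wasted_lag = config$b_wast_wast),
    sd_u = config$panel_sd_u)
  list(panel = panel, truth = truth)
}
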