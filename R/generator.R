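#' Configuration for the synthetic hospital-year generator
#'
#' Builds a validated configuration object describing one year of surgical
#' activity at a large academic hospital: a weekly volume cycle with weekend
#' and holiday troughs, a long-tailed case mix over surgery types, a
#' zero-inflated length-of-stay (LOS) law per type (the point mass at zero is
#' same-day discharge), and a long-tailed comorbidity-code vocabulary whose
#' most frequent codes carry a genuine multiplicative effect on the positive
#' part of LOS.
#'
#' Defaults emulate a hospital performing roughly 75,000 surgeries per year
#' (about 278 cases on a typical day), with 72.4% of encounters handled as
#' outpatient procedures, a median LOS of 1 day with quartiles (1, 2) among
#' admitted patients, and a mean of 10.9 (SD 11.2, range 1-160) comorbidity
#' codes per patient drawn from a 2,000-code power-law vocabulary.
#'
#' @param n_days number of calendar days to simulate.
#' @param day0_weekday integer 0-6 anchoring the weekly cycle (0 = Monday;
#'   weekdays 5 and 6 are the weekend).
#' @param weekday_volume_mean,weekend_volume_mean,holiday_volume_mean expected
#'   daily case counts per calendar regime.
#' @param volume_dispersion negative-binomial size parameter for daily counts;
#'   `Inf` gives Poisson counts, `NULL` gives deterministic (rounded-mean)
#'   counts.
#' @param holidays integer day indices (0-based) flagged as hospital holidays.
#' @param n_surgery_types number of distinct surgery types.
#' @param surgery_type_popularity Zipf exponent of the categorical over types;
#'   larger values concentrate volume on the most common procedures.
#' @param outpatient_fraction target marginal probability that an encounter is
#'   a planned outpatient procedure.
#' @param n_codes comorbidity-code vocabulary size.
#' @param code_popularity_exponent Zipf exponent of code inclusion
#'   probabilities.
#' @param comorbidity_count_law list with `mean`, `sd`, `min`, `max` for the
#'   truncated-normal per-patient comorbidity count.
#' @param comorbidity_los_effect multiplicative effect on the positive-LOS
#'   mean per standard deviation of the latent comorbidity burden score
#'   (log scale); 0 removes all comorbidity signal.
#' @param comorbidity_effect_codes the burden score counts only the
#'   `comorbidity_effect_codes` most popular codes, concentrating the LOS
#'   signal where a frequency-based vocabulary can find it.
#' @param per_type_los optional data frame with columns `surgery_type`,
#'   `mean_pos_los` (mean LOS in days among admitted cases, > 1),
#'   `dispersion`, and `p_same_day`; when `NULL` a heterogeneous table is
#'   drawn deterministically from `seed` and calibrated so the
#'   popularity-weighted same-day rate reproduces `outpatient_fraction`.
#' @param planned_discharge_error_rate probability that the planned
#'   same-day-discharge flag disagrees with the realized LOS.
#' @param admission_class_error_rate probability that the plan-time
#'   inpatient/outpatient admission class disagrees with the realized
#'   same-day-discharge status (unplanned admissions after outpatient
#'   surgery and early discharges of planned inpatients). The admission
#'   class is a model feature; the finer-grained same-day-discharge flag is
#'   not, and only enters through the adjusted census scenario.
#' @param patient_pool_fraction patient pool size as a fraction of the
#'   expected case count; values below 1 make repeat patients common.
#' @param missingness_rates named list of blanking probabilities applied by
#'   [inject_missingness()] (fields: `asa_ps`, `scheduled_duration_min`,
#'   `los_days`, `surgery_type`).
#' @param n_service_departments number of clinical departments; the service
#'   line of a case is its department plus the inpatient/outpatient
#'   designation.
#' @param los_max hard cap on simulated LOS, days.
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   encounter table.
#'
#' @return an object of class `surgecast_config`.
#' @seealso [generate_encounters()], [generate_calendar()]
#' @export
gen_config <- function(n_days = 365L,
                       day0_weekday = 0L,
                       weekday_volume_mean = 320,
                       weekend_volume_mean = 170,
                       holiday_volume_mean = 120,
                       volume_dispersion = 60,
                       holidays = default_holidays(n_days),
                       n_surgery_types = 80L,
                       surgery_type_popularity = 1.1,
                       outpatient_fraction = 0.724,
                       n_codes = 2000L,
                       code_popularity_exponent = 1.05,
                       comorbidity_count_law = list(mean = 10.9, sd = 11.2,
                                                    min = 1L, max = 160L),
                       comorbidity_los_effect = 0.35,
                       comorbidity_effect_codes = 100L,
                       per_type_los = NULL,
                       planned_discharge_error_rate = 0.05,
                       admission_class_error_rate = 0.10,
                       patient_pool_fraction = 0.66,
                       missingness_rates = list(asa_ps = 0.05,
                                                scheduled_duration_min = 0.01,
                                                los_days = 0.001),
                       n_service_departments = 12L,
                       los_max = 160L,
                       seed = 1L) {
  n_days <- check_count(n_days, "n_days")
  day0_weekday <- check_count(day0_weekday, "day0_weekday", min = 0L)
  if (day0_weekday > 6L) stop("`day0_weekday` must be in 0..6", call. = FALSE)
  check_nonneg(weekday_volume_mean, "weekday_volume_mean")
  check_nonneg(weekend_volume_mean, "weekend_volume_mean")
  check_nonneg(holiday_volume_mean, "holiday_volume_mean")
  check_prob(outpatient_fraction, "outpatient_fraction")
  check_prob(planned_discharge_error_rate, "planned_discharge_error_rate")
  check_prob(admission_class_error_rate, "admission_class_error_rate")
  n_surgery_types <- check_count(n_surgery_types, "n_surgery_types")
  n_codes <- check_count(n_codes, "n_codes")
  comorbidity_effect_codes <- check_count(comorbidity_effect_codes,
                                          "comorbidity_effect_codes", min = 0L)
  holidays <- as.integer(holidays)
  if (length(holidays) && (any(holidays < 0L) || any(holidays >= n_days))) {
    stop("`holidays` must be day indices in [0, n_days)", call. = FALSE)
  }
  law <- comorbidity_count_law
  stopifnot(is.list(law), all(c("mean", "sd", "min", "max") %in% names(law)))
  if (law$min > law$max) {
    stop("comorbidity_count_law: `min` must be <= `max`", call. = FALSE)
  }
  if (law$min < 1L) {
    stop("comorbidity_count_law: `min` must be >= 1 (every patient carries at least one code)",
         call. = FALSE)
  }
  if (law$max > n_codes) {
    stop("comorbidity_count_law: `max` cannot exceed `n_codes`", call. = FALSE)
  }
  for (r in names(missingness_rates)) check_prob(missingness_rates[[r]], r)
  seed <- check_count(seed, "seed", min = 0L)

  cfg <- structure(list(
    n_days = n_days, day0_weekday = day0_weekday,
    weekday_volume_mean = weekday_volume_mean,
    weekend_volume_mean = weekend_volume_mean,
    holiday_volume_mean = holiday_volume_mean,
    volume_dispersion = volume_dispersion,
    holidays = sort(unique(holidays)),
    n_surgery_types = n_surgery_types,
    surgery_type_popularity = surgery_type_popularity,
    outpatient_fraction = outpatient_fraction,
    n_codes = n_codes,
    code_popularity_exponent = code_popularity_exponent,
    comorbidity_count_law = law,
    comorbidity_los_effect = comorbidity_los_effect,
    comorbidity_effect_codes = comorbidity_effect_codes,
    per_type_los = per_type_los,
    planned_discharge_error_rate = planned_discharge_error_rate,
    admission_class_error_rate = admission_class_error_rate,
    patient_pool_fraction = patient_pool_fraction,
    missingness_rates = missingness_rates,
    n_service_departments = check_count(n_service_departments,
                                        "n_service_departments"),
    los_max = check_count(los_max, "los_max"),
    seed = seed
  ), class = "surgecast_config")
  if (is.null(cfg$per_type_los)) {
    cfg$per_type_los <- default_type_los(cfg)
  } else {
    stopifnot(all(c("surgery_type", "mean_pos_los", "dispersion",
                    "p_same_day") %in% names(per_type_los)),
              nrow(per_type_los) == n_surgery_types)
  }
  cfg
}

#' @export
print.surgecast_config <- function(x, ...) {
  cat(sprintf("<surgecast_config> %d days, %d surgery types, %d codes, seed %d\n",
              x$n_days, x$n_surgery_types, x$n_codes, x$seed))
  cat(sprintf("  daily volume means: weekday %.0f / weekend %.0f / holiday %.0f (%d holidays)\n",
              x$weekday_volume_mean, x$weekend_volume_mean,
              x$holiday_volume_mean, length(x$holidays)))
  cat(sprintf("  outpatient fraction %.3f, comorbidity LOS effect %.2f on top %d codes\n",
              x$outpatient_fraction, x$comorbidity_los_effect,
              x$comorbidity_effect_codes))
  invisible(x)
}

# Eight weekday holidays spread through the year, roughly where US hospital
# holidays fall when day 0 is a Monday.
default_holidays <- function(n_days) {
  h <- c(3L, 66L, 129L, 185L, 248L, 310L, 332L, 359L)
  h[h < n_days]
}

# Zipf popularity over ranks 1..n with exponent a, normalized.
zipf_weights <- function(n, a) {
  w <- (seq_len(n))^(-a)
  w / sum(w)
}

# Per-type LOS law drawn from a fixed stream tied to the config seed: a
# long-tailed spread of mean stays across types, and same-day-discharge
# probabilities calibrated on the logit scale so the popularity-weighted
# same-day rate matches the configured outpatient fraction after accounting
# for the planned-discharge error rate.
default_type_los <- function(cfg) {
  with_seed(cfg$seed + 104729L, {
    nt <- cfg$n_surgery_types
    pop <- zipf_weights(nt, cfg$surgery_type_popularity)
    mean_pos <- 1 + pmin(rlnorm(nt, meanlog = log(0.8), sdlog = 0.9), 25)
    logit <- stats::qlogis(0.85) + stats::rnorm(nt, 0, 1.5)
    eps <- cfg$admission_class_error_rate
    # marginal outpatient-class rate f relates to the same-day rate p0 via
    # f = p0 (1 - eps) + (1 - p0) eps; invert for the target p0
    target <- if (eps < 0.5) {
      (cfg$outpatient_fraction - eps) / (1 - 2 * eps)
    } else {
      cfg$outpatient_fraction
    }
    target <- min(max(target, 1e-4), 1 - 1e-4)
    shift <- stats::uniroot(function(d) {
      sum(pop * stats::plogis(logit + d)) - target
    }, interval = c(-30, 30))$root
    data.frame(
      surgery_type = sprintf("T%03d", seq_len(nt)),
      popularity = pop,
      mean_pos_los = mean_pos,
      dispersion = 1.2,
      p_same_day = stats::plogis(logit + shift),
      stringsAsFactors = FALSE
    )
  })
}

#' Build a day-indexed calendar with a weekly cycle and holiday flags
#'
#' @param n_days number of days.
#' @param day0_weekday weekday (0-6, 0 = Monday) of day 0; subsequent days
#'   cycle modulo 7.
#' @param holidays integer set of holiday day indices, each in `[0, n_days)`.
#'
#' @return a data frame of class `surgecast_calendar` with columns
#'   `day_index`, `weekday`, `is_weekend` (weekday 5 or 6), `is_holiday`.
#' @export
generate_calendar <- function(n_days, day0_weekday = 0L, holidays = integer()) {
  n_days <- check_count(n_days, "n_days")
  day0_weekday <- check_count(day0_weekday, "day0_weekday", min = 0L)
  if (day0_weekday > 6L) stop("`day0_weekday` must be in 0..6", call. = FALSE)
  holidays <- as.integer(holidays)
  if (length(holidays) && (any(holidays < 0L) || any(holidays >= n_days))) {
    stop("holiday day index out of range [0, n_days)", call. = FALSE)
  }
  day_index <- 0:(n_days - 1L)
  cal <- data.frame(
    day_index = day_index,
    weekday = (day0_weekday + day_index) %% 7L,
    stringsAsFactors = FALSE
  )
  cal$is_weekend <- cal$weekday >= 5L
  cal$is_holiday <- cal$day_index %in% holidays
  class(cal) <- c("surgecast_calendar", "data.frame")
  cal
}

# Expected daily case count per calendar regime.
regime_means <- function(cfg, calendar) {
  mu <- ifelse(calendar$is_holiday, cfg$holiday_volume_mean,
               ifelse(calendar$is_weekend, cfg$weekend_volume_mean,
                      cfg$weekday_volume_mean))
  as.numeric(mu)
}

# Mean of a normal clipped to [lo, hi] (closed form).
clipped_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a))
}

# The per-patient comorbidity count is a clipped rounded normal; clipping at
# the minimum inflates the mean, so the latent normal mean is calibrated so
# that the realized mean matches the configured one.
calibrate_count_mean <- function(law) {
  target <- law$mean
  f <- function(mu) clipped_normal_mean(mu, law$sd, law$min, law$max) - target
  if (f(target) <= 0) return(target)
  stats::uniroot(f, lower = target - 6 * law$sd, upper = target)$root
}

# Weighted sampling without replacement of comorbidity codes for each
# patient; exact sequential sampling via R's prob= machinery.
sample_patient_codes <- function(n_patients, counts, weights) {
  nw <- length(weights)
  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    out[[i]] <- sort(sample.int(nw, counts[i], replace = FALSE, prob = weights))
  }
  out
}

#' Generate a synthetic surgical-encounter table with known ground truth
#'
#' Simulates one row per surgical case. Daily case counts follow a
#' negative-binomial law around the weekday/weekend/holiday regime mean;
#' surgery types follow a Zipf case mix; LOS is zero-inflated per type
#' (the zero mass is same-day discharge) with a discretized-gamma positive
#' part whose mean is shifted multiplicatively by a latent comorbidity burden
#' score, so the comorbidity matrix carries real predictive signal. Patients
#' are drawn with replacement from a pool, so repeat patients occur and
#' comorbidity sets are patient-level.
#'
#' @param config a [gen_config()] object.
#'
#' @return a list of class `surgecast_sim` with elements `encounters` (data
#'   frame, one row per case; `comorbidity_codes` is a list column),
#'   `calendar` (see [generate_calendar()]), and `truth` (latent parameters:
#'   the per-type LOS table, regime volume means, code weights, burden
#'   effect, and standardization constants) for parameter-recovery tests.
#' @export
generate_encounters <- function(config) {
  stopifnot(inherits(config, "surgecast_config"))
  cfg <- config
  calendar <- generate_calendar(cfg$n_days, cfg$day0_weekday, cfg$holidays)
  mu <- regime_means(cfg, calendar)

  with_seed(cfg$seed, {
    counts <- daily_count_draw(mu, cfg$volume_dispersion)
    n <- sum(counts)
    if (n == 0L) stop("configuration produced zero cases", call. = FALSE)
    day_index <- rep(calendar$day_index, counts)

    # patient pool with repeat visits; comorbidity sets are per patient
    n_patients <- max(1L, as.integer(round(cfg$patient_pool_fraction * n)))
    patient_of_case <- sample.int(n_patients, n, replace = TRUE)
    used <- sort(unique(patient_of_case))
    law <- cfg$comorbidity_count_law
    mu_m <- calibrate_count_mean(law)
    m <- as.integer(round_half_up(pmin(pmax(
      stats::rnorm(length(used), mu_m, law$sd), law$min), law$max)))
    m <- pmin(pmax(m, as.integer(law$min)), cfg$n_codes)
    code_w <- zipf_weights(cfg$n_codes, cfg$code_popularity_exponent)
    codes_of_patient <- sample_patient_codes(length(used), m, code_w)
    names(codes_of_patient) <- as.character(used)

    pat_key <- match(patient_of_case, used)
    case_codes <- codes_of_patient[pat_key]
    n_comorb <- lengths(case_codes)

    # latent burden: count of effect-carrying codes, z-scored over cases
    ne <- cfg$comorbidity_effect_codes
    burden_raw <- vapply(case_codes, function(cc) sum(cc <= ne), numeric(1))
    b_mu <- mean(burden_raw)
    b_sd <- stats::sd(burden_raw)
    if (!is.finite(b_sd) || b_sd == 0) b_sd <- 1
    burden_z <- (burden_raw - b_mu) / b_sd

    # case mix and per-type LOS law
    tl <- cfg$per_type_los
    type_idx <- sample.int(nrow(tl), n, replace = TRUE, prob = tl$popularity)
    p0 <- tl$p_same_day[type_idx]
    same_day <- stats::runif(n) < p0
    mu_pos <- pmax(0.02, (tl$mean_pos_los[type_idx] - 1) *
                     exp(cfg$comorbidity_los_effect * burden_z))
    los <- integer(n)
    pos <- !same_day
    los[pos] <- 1L + stats::rnbinom(sum(pos), size = tl$dispersion[type_idx][pos],
                                    mu = mu_pos[pos])
    los <- pmin(los, cfg$los_max)

    # plan-time admission class: realized same-day status observed through
    # plan-level noise (unplanned admissions / early discharges)
    class_flip <- stats::runif(n) < cfg$admission_class_error_rate
    admit_class <- ifelse((los == 0L) != class_flip, "outpatient", "inpatient")
    # the same-day-discharge flag is finer-grained advance knowledge, held
    # out of the feature set and used only by the adjusted census scenario
    flip <- stats::runif(n) < cfg$planned_discharge_error_rate
    planned_sdd <- (los == 0L) != flip

    # departments: each surgery type belongs to one department
    dept_of_type <- sprintf("DEPT%02d",
                            1L + (seq_len(nrow(tl)) %% cfg$n_service_departments))
    service_line <- paste0(dept_of_type[type_idx], ":", admit_class)

    # demographics and scheduling attributes
    age <- pmin(pmax(stats::rnorm(n, 57, 18), 0), 100)
    sex <- ifelse(stats::runif(n) < 0.464, "M", "F")
    asa <- sample.int(5L, n, replace = TRUE,
                      prob = c(0.08, 0.32, 0.42, 0.15, 0.03))
    type_dur_median <- with_seed(cfg$seed + 7919L,
                                 stats::rlnorm(nrow(tl), log(55), 0.7))
    duration <- stats::rlnorm(n, log(type_dur_median[type_idx]), 0.35)
    urgency <- sample(c("elective", "same_day_add_on", "urgent", "emergent"),
                      n, replace = TRUE, prob = c(0.80, 0.08, 0.09, 0.03))

    encounters <- data.frame(
      case_id = sprintf("C%06d", seq_len(n)),
      patient_id = sprintf("P%06d", patient_of_case),
      day_index = day_index,
      surgery_type = tl$surgery_type[type_idx],
      service_line = service_line,
      planned_admission_class = admit_class,
      urgency = urgency,
      age_years = age,
      sex = sex,
      asa_ps = asa,
      scheduled_duration_min = duration,
      n_comorbidities = as.integer(n_comorb),
      los_days = los,
      planned_same_day_discharge = planned_sdd,
      stringsAsFactors = FALSE
    )
    encounters$comorbidity_codes <-
      lapply(case_codes, function(cc) sprintf("D%04d", cc))

    # expected LOS per type, folding in the population-average burden
    # multiplier: E[los | type] = (1 - p0) * (1 + (mean_pos - 1) E[exp(b z)])
    burden_factor <- mean(exp(cfg$comorbidity_los_effect * burden_z))
    truth <- list(
      config = cfg,
      per_type_los = transform(tl,
        expected_los = (1 - p_same_day) *
          (1 + (mean_pos_los - 1) * burden_factor)),
      burden_factor = burden_factor,
      regime_means = c(weekday = cfg$weekday_volume_mean,
                       weekend = cfg$weekend_volume_mean,
                       holiday = cfg$holiday_volume_mean),
      holiday_effect = cfg$holiday_volume_mean - cfg$weekday_volume_mean,
      code_weights = code_w,
      comorbidity_los_effect = cfg$comorbidity_los_effect,
      burden_center = b_mu, burden_scale = b_sd
    )
    structure(list(encounters = encounters, calendar = calendar, truth = truth),
              class = "surgecast_sim")
  })
}

daily_count_draw <- function(mu, dispersion) {
  if (is.null(dispersion)) {
    as.integer(round_half_up(mu))
  } else if (is.infinite(dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = dispersion, mu = mu)
  }
}

#' @export
print.surgecast_sim <- function(x, ...) {
  cat(sprintf("<surgecast_sim> %d encounters over %d days (%d patients)\n",
              nrow(x$encounters), nrow(x$calendar),
              length(unique(x$encounters$patient_id))))
  invisible(x)
}

#' Blank fields at random to emulate EHR missingness
#'
#' Independently blanks each targeted field with its configured rate so the
#' imputation rules can be exercised. Only fields with a defined downstream
#' imputation rule may be targeted.
#'
#' @param encounters encounter data frame.
#' @param rates named list/vector of blanking probabilities; allowed names are
#'   `asa_ps`, `scheduled_duration_min`, `los_days`, `surgery_type`.
#' @param seed integer seed making the blanking reproducible.
#'
#' @return the encounter table with `NA`s injected.
#' @export
inject_missingness <- function(encounters, rates, seed = 1L) {
  allowed <- c("asa_ps", "scheduled_duration_min", "los_days", "surgery_type")
  rates <- as.list(rates)
  bad <- setdiff(names(rates), allowed)
  if (length(bad)) {
    stop(sprintf("no imputation rule for field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (f in names(rates)) check_prob(rates[[f]], f)
  with_seed(seed, {
    for (f in names(rates)) {
      r <- rates[[f]]
      if (r <= 0) next
      hit <- stats::runif(nrow(encounters)) < r
      encounters[[f]][hit] <- NA
    }
    encounters
  })
}
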