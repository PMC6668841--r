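#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the study conditions of a single-center adult
#' inpatient cohort restricted to admissions of at least 48 hours: a latent
#' per-admission severity process (mean-reverting around a location-specific
#' baseline plus patient-level frailty) drives both the sparse timestamped
#' observations and the in-hospital mortality outcome. Default constants are
#' calibrated so that large-cohort marginals reproduce the published cohort:
#' 2.5% mortality, ICU admission 25% among deaths vs 5% among survivors,
#' mean age 63 vs 55 years, 47% vs 57% female, median length of stay 9 vs
#' 5 days.
#'
#' @param n_admissions number of admissions to generate (>= 1).
#' @param seed integer seed; the whole cohort is a pure function of the
#'   config, including this seed.
#' @param catalogue a [default_catalogue()] (or compatible) variable table.
#' @param location_probs named probabilities (ward, ed, icu, other), sum 1.
#' @param severity list: `baseline` (named per-location level of the latent
#'   process), `baseline_sd` (s.d. of the patient-level frailty added to the
#'   baseline), `reversion` (per-hour mean-reversion rate), `noise_sd`
#'   (per-hour innovation s.d.), `drift` (per-hour deterministic drift) and
#'   `drift_sd` (s.d. of the per-admission deterioration slope, the
#'   time-ordered component of risk).
#' @param outcome list of logit coefficients: `intercept`, `beta_severity`
#'   (on the 48-hour maximum of the latent trace), `beta_trend` (on the
#'   late-minus-early mean severity difference), `beta_age` (per year,
#'   centered at `age_center`), `beta_female`.
#' @param age list: truncated-normal `mean`, `sd`, `min`, `max` (years).
#' @param female_p,race_black_p marginal probabilities.
#' @param comorbidity_p vector of independent comorbidity-flag probabilities.
#' @param los list of outcome-conditional lognormal parameters
#'   (`died_meanlog`, `died_sdlog`, `alive_meanlog`, `alive_sdlog`) and
#'   `floor_days` (admissions shorter than 48 h are excluded by design, so
#'   length of stay is floored at 2 days).
#' @param marginal_mortality the death-rate the default intercept was
#'   calibrated to; kept in the config for reference and reporting.
#' @param emission per-variable emission table, see [default_emission()].
#' @return A list of class `vistl_cohort_config`.
#' @export
cohort_config <- function(n_admissions = 1000L,
                          seed = 1L,
                          catalogue = default_catalogue("demo"),
                          location_probs = c(ward = 0.309, ed = 0.414,
                                             icu = 0.055, other = 0.222),
                          severity = list(
                            baseline = c(ward = 0.55, ed = 0.609,
                                         icu = 1.283, other = -0.059),
                            baseline_sd = 0.32,
                            reversion = 0.12,
                            noise_sd = 0.10,
                            drift = 0,
                            drift_sd = 0.012),
                          outcome = list(intercept = -8.282,
                                         beta_severity = 3.2,
                                         beta_trend = 2.0,
                                         beta_age = 0.0358,
                                         beta_female = -0.54,
                                         age_center = 55),
                          age = list(mean = 54.36, sd = 19,
                                     min = 18, max = 100),
                          female_p = 0.5675,
                          race_black_p = 0.54,
                          comorbidity_p = c(0.35, 0.25, 0.20, 0.15, 0.10),
                          los = list(died_meanlog = log(9), died_sdlog = 0.90,
                                     alive_meanlog = log(5), alive_sdlog = 0.60,
                                     floor_days = 2),
                          marginal_mortality = 0.025,
                          emission = default_emission(catalogue)) {
  cfg <- list(n_admissions = as.integer(n_admissions), seed = as.integer(seed),
              catalogue = catalogue, location_probs = location_probs,
              severity = severity, outcome = outcome, age = age,
              female_p = female_p, race_black_p = race_black_p,
              comorbidity_p = comorbidity_p, los = los,
              marginal_mortality = marginal_mortality, emission = emission)
  class(cfg) <- "vistl_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) stop("invalid CohortConfig field '", field, "': ", why)
  if (!is.numeric(cfg$n_admissions) || cfg$n_admissions < 1)
    fail("n_admissions", "must be >= 1")
  lp <- cfg$location_probs
  if (!all(admission_locations() %in% names(lp)))
    fail("location_probs", "must be named ward/ed/icu/other")
  if (any(lp < 0 | lp > 1)) fail("location_probs", "probabilities must be in [0,1]")
  if (abs(sum(lp) - 1) > 1e-8) fail("location_probs", "must sum to 1")
  for (p in c("female_p", "race_black_p", "marginal_mortality")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(p, "must be in [0,1]")
  }
  if (any(cfg$comorbidity_p < 0 | cfg$comorbidity_p > 1))
    fail("comorbidity_p", "probabilities must be in [0,1]")
  if (!all(admission_locations() %in% names(cfg$severity$baseline)))
    fail("severity$baseline", "must be named ward/ed/icu/other")
  if (cfg$severity$noise_sd < 0) fail("severity$noise_sd", "must be >= 0")
  if (cfg$severity$reversion < 0 || cfg$severity$reversion > 1)
    fail("severity$reversion", "must be in [0,1]")
  if (cfg$age$min >= cfg$age$max) fail("age", "min must be < max")
  if (cfg$los$floor_days < 2)
    fail("los$floor_days", "cohort includes only admissions of >= 48 h")
  validate_catalogue(cfg$catalogue)
  miss <- setdiff(cfg$catalogue$name[!cfg$catalogue$group %in% static_groups()],
                  cfg$emission$variable)
  if (length(miss))
    fail("emission", paste("no emission parameters for:",
                           paste(miss, collapse = ", ")))
  invisible(cfg)
}

#' @export
print.vistl_cohort_config <- function(x, ...) {
  cat("<vistl_cohort_config>\n",
      " n_admissions: ", x$n_admissions, ", seed: ", x$seed, "\n",
      " catalogue: ", x$catalogue$preset[1], " (", nrow(x$catalogue),
      " variables)\n",
      " calibrated marginal mortality: ", 100 * x$marginal_mortality, "%\n",
      sep = "")
  invisible(x)
}

admission_locations <- function() c("ward", "ed", "icu", "other")

#' Default per-variable emission parameters
#'
#' One row per non-static catalogue variable. Continuous variables are
#' emitted as `normal + sign(direction) * link * severity + N(0, noise_sd)`
#' clipped to the plausible range (bidirectional variables draw the sign once
#' per admission); binary variables as Bernoulli with
#' `logit p = bin_base + bin_link * severity`. Observation times follow a
#' Poisson process with `rate_per_hour * (1 + rate_sev * mean severity)`.
#' Ordinal consciousness channels are banded from the latent severity:
#' `model = "avpu"` maps noisy severity through three thresholds to AVPU
#' 0-3, `model = "gcs"` through three thresholds to GCS 15/13/10/6.
#'
#' A `link` (or `bin_link`) of zero designates a pure-noise channel carrying
#' no outcome signal; see [signal_variables()].
#'
#' @param catalogue a catalogue from [default_catalogue()].
#' @return data.frame with columns `variable`, `model`, `rate_per_hour`,
#'   `rate_sev`, `link`, `noise_sd`, `bin_base`, `bin_link`.
#' @export
default_emission <- function(catalogue = default_catalogue("demo")) {
  e <- function(variable, model, rate, link = 0, noise = 0,
                bin_base = 0, bin_link = 0, rate_sev = 0) {
    data.frame(variable = variable, model = model, rate_per_hour = rate,
               rate_sev = rate_sev, link = link, noise_sd = noise,
               bin_base = bin_base, bin_link = bin_link,
               stringsAsFactors = FALSE)
  }
  base <- list(
    e("heart_rate",             "linear", 1,    16, 11),
    e("resp_rate",              "linear", 1,   4.5,  3.5),
    e("systolic_bp",            "linear", 1,    15, 16),
    e("mean_arterial_pressure", "linear", 1,     5, 10),
    e("temperature",            "linear", 1,   0.8, 0.45),
    e("spo2",                   "linear", 1,   3.5,  2.8),
    e("avpu",                   "avpu",   0.5,   1,  0.30),
    e("pao2_fio2_ratio", "linear", 1/6,  30, 50),
    e("platelets",       "linear", 1/6,  18, 40),
    e("bilirubin",       "linear", 1/6, 0.4, 0.4),
    e("creatinine",      "linear", 1/6, 0.25, 0.25),
    e("lactate",         "linear", 1/6, 3.0, 0.5),
    e("wbc",             "linear", 1/6,   6, 2.5),
    e("hemoglobin",      "linear", 1/6, 2.0, 1.2),
    e("sodium",          "linear", 1/6,   0, 3),
    e("potassium",       "linear", 1/6, 0.5, 0.4),
    e("bicarbonate",     "linear", 1/6,   6, 2.5),
    e("med_vasopressor", "binary", 1/6, bin_base = -5.5, bin_link = 2.0, rate_sev = 0.3),
    e("med_antibiotic",  "binary", 1/6, bin_base = -1.5, bin_link = 1.8, rate_sev = 0.3),
    e("med_opioid",      "binary", 1/6, bin_base = -1.2, bin_link = 0.8, rate_sev = 0.3),
    e("med_diuretic",    "binary", 1/8, bin_base = -2.0, bin_link = 1.0, rate_sev = 0.3),
    e("mechanical_ventilation", "binary", 1/4, bin_base = -5.0, bin_link = 3.2, rate_sev = 0.3),
    e("supplemental_oxygen",    "binary", 1/4, bin_base = -2.5, bin_link = 2.5, rate_sev = 0.3),
    e("central_line",           "binary", 1/8, bin_base = -4.0, bin_link = 2.2, rate_sev = 0.3),
    e("telemetry_monitor",      "binary", 1/8, bin_base = -1.5, bin_link = 0),
    e("gcs",              "gcs",    1/4,   1, 0.30),
    e("morse_fall_score", "linear", 1/4,  35, 12),
    e("braden_score",     "linear", 1/4, 6.0, 2.0),
    e("pain_score",       "linear", 1/4,   0, 2),
    e("urine_output",     "linear", 1/4,  40, 15),
    e("chest_xray", "binary", 1/12, bin_base = -1.5, bin_link = 2.0, rate_sev = 0.3),
    e("ekg",        "binary", 1/12, bin_base = -1.2, bin_link = 0)
  )
  em <- do.call(rbind, base)
  extra <- setdiff(catalogue$name[!catalogue$group %in% static_groups()],
                   em$variable)
  if (length(extra)) {
    pad <- do.call(rbind, lapply(seq_along(extra), function(i) {
      nm <- extra[i]
      if (startsWith(nm, "lab_ch_")) {
        e(nm, "linear", 1/24, link = if (i %% 3 == 0) 0 else 7, noise = 10)
      } else {
        e(nm, "binary", 1/24, bin_base = -3,
          bin_link = if (i %% 3 == 0) 0 else 0.8)
      }
    }))
    em <- rbind(em, pad)
  }
  em[em$variable %in% catalogue$name, , drop = FALSE]
}

#' Which catalogue rows carry outcome signal, by construction
#'
#' Signal rows are the emitted variables whose severity link is nonzero,
#' plus the static rows whose admission-level field actually enters the
#' outcome under this config: age and sex when their logit coefficients are
#' nonzero, the location indicators when the location baselines differ. The
#' complement — zero-link channels, race, comorbidity count — is noise with
#' respect to the outcome, which is what the Grad-CAM localization and
#' differential-image checks lean on.
#'
#' @param config a [cohort_config()].
#' @return logical vector along the catalogue rows.
#' @export
signal_variables <- function(config) {
  cat <- config$catalogue
  em <- config$emission
  link <- ifelse(em$model == "binary", em$bin_link, em$link)
  static_signal <- character()
  if (config$outcome$beta_age != 0) static_signal <- c(static_signal, "age_years")
  if (config$outcome$beta_female != 0) static_signal <- c(static_signal, "sex_female")
  if (diff(range(config$severity$baseline)) > 0) {
    static_signal <- c(static_signal, paste0("loc_", admission_locations()))
  }
  cat$name %in% c(em$variable[link != 0], static_signal)
}

# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulate the latent severity process
#'
#' A discrete-time mean-reverting (Ornstein-Uhlenbeck-type) walk around a
#' location baseline plus a per-admission frailty drawn once:
#' `s[t+1] = s[t] + reversion * (mu_i - s[t]) + drift + noise_sd * z`,
#' started at the stationary distribution. ICU baselines exceed ED/ward,
#' which exceed procedural/"other" areas.
#'
#' @param config a [cohort_config()].
#' @param location one of ward/ed/icu/other (recycled to length `n`).
#' @param n_hours trace length, >= 48.
#' @param n number of independent trajectories.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return numeric matrix `n` x `n_hours` (single trajectory as 1-row matrix).
#' @export
simulate_severity <- function(config, location, n_hours = 48L, n = 1L,
                              seed = NULL) {
  if (n_hours < 48) stop("n_hours must be >= 48 (cohort is conditioned on a 48 h stay)")
  location <- match.arg(location, admission_locations(), several.ok = TRUE)
  location <- rep_len(location, n)
  run <- function() severity_matrix(config, location, n_hours)
  if (is.null(seed)) run() else with_seed(seed, run())
}

severity_matrix <- function(config, locations, n_hours = 48L) {
  sv <- config$severity
  n <- length(locations)
  mu <- sv$baseline[locations] + rnorm(n, 0, sv$baseline_sd)
  # per-admission deterioration/improvement slope (per hour); the walk
  # reverts towards the drifting target mu + slope * t
  slope <- sv$drift + rnorm(n, 0, sv$drift_sd %||% 0)
  th <- sv$reversion
  stat_sd <- if (th > 0) sv$noise_sd / sqrt(1 - (1 - th)^2) else sv$noise_sd
  S <- matrix(0, n, n_hours)
  S[, 1] <- mu + rnorm(n, 0, stat_sd)
  if (n_hours > 1) {
    z <- matrix(rnorm(n * (n_hours - 1), 0, sv$noise_sd), n, n_hours - 1)
    for (t in seq_len(n_hours - 1)) {
      S[, t + 1] <- S[, t] + th * (mu + slope * t - S[, t]) + z[, t]
    }
  }
  unname(S)
}

# late-minus-early mean severity: the time-ordered component of risk
severity_trend <- function(S) {
  H <- ncol(S)
  half <- H %/% 2
  rowMeans(S[, (half + 1):H, drop = FALSE]) -
    rowMeans(S[, 1:half, drop = FALSE])
}

#' Emit sparse observations from a severity trace
#'
#' @param trace numeric severity vector (length >= 48) for one admission.
#' @param catalogue variable catalogue.
#' @param config a [cohort_config()] supplying the emission table.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return data.frame with columns `variable`, `time_h`, `value`.
#' @export
emit_observations <- function(trace, catalogue = config$catalogue, config,
                              seed = NULL) {
  if (length(trace) < 48) stop("severity trace must cover >= 48 hours")
  run <- function() {
    obs <- emit_observations_cohort(
      config, S = matrix(trace, nrow = 1), ids = "a1",
      catalogue = catalogue)
    obs[, c("variable", "time_h", "value")]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Vectorized emission for a whole cohort. S is n x H severity, ids length n.
emit_observations_cohort <- function(config, S, ids, catalogue = config$catalogue) {
  em <- config$emission
  H <- ncol(S)
  n <- nrow(S)
  emitted <- catalogue$name[!catalogue$group %in% static_groups()]
  miss <- setdiff(emitted, em$variable)
  if (length(miss)) {
    stop("variable(s) without emission parameters: ", paste(miss, collapse = ", "))
  }
  mean_sev <- pmax(0, rowMeans(S))
  dir_sign <- c(higher_abnormal = 1, lower_abnormal = -1,
                bidirectional = NA_real_, none = 0)
  pieces <- vector("list", length(emitted))
  for (k in seq_along(emitted)) {
    nm <- emitted[k]
    p <- em[em$variable == nm, ]
    ci <- which(catalogue$name == nm)
    rate_i <- p$rate_per_hour * (1 + p$rate_sev * mean_sev)
    counts <- rpois(n, rate_i * H)
    if (catalogue$group[ci] == "vitals") counts <- counts + 1L  # ensure an obs in [0,1)
    total <- sum(counts)
    if (total == 0L) next
    adm <- rep.int(seq_len(n), counts)
    t_h <- runif(total, 0, H)
    if (catalogue$group[ci] == "vitals") {
      # the guaranteed observation lands in the first hour
      first <- c(0L, cumsum(counts))[seq_len(n)][counts > 0] + 1L
      t_h[first] <- runif(sum(counts > 0), 0, 1)
    }
    sev <- S[cbind(adm, pmin(H, floor(t_h) + 1L))]
    val <- switch(p$model,
      linear = {
        sgn <- dir_sign[[catalogue$direction[ci]]]
        if (is.na(sgn)) sgn <- (sample(c(-1, 1), n, replace = TRUE))[adm]
        x <- catalogue$normal[ci] + sgn * p$link * pmax(0, sev) +
          rnorm(total, 0, p$noise_sd)
        pmin(pmax(x, catalogue$low[ci]), catalogue$high[ci])
      },
      binary = {
        rbinom(total, 1L, plogis(p$bin_base + p$bin_link * pmax(0, sev)))
      },
      avpu = {
        sn <- p$link * sev + rnorm(total, 0, p$noise_sd)
        as.numeric((sn > 1.45) + (sn > 2.0) + (sn > 2.6))
      },
      gcs = {
        sn <- p$link * sev + rnorm(total, 0, p$noise_sd)
        pmax(3, 15 - 2 * (sn > 1.5) - 3 * (sn > 2.1) - 4 * (sn > 2.7))
      },
      stop("unknown emission model: ", p$model))
    pieces[[k]] <- data.table::data.table(
      id = ids[adm], variable = nm, time_h = t_h, value = as.numeric(val))
  }
  obs <- data.table::rbindlist(pieces)
  if (!nrow(obs)) {
    return(data.frame(id = character(), variable = character(),
                      time_h = numeric(), value = numeric()))
  }
  data.table::setorder(obs, id, variable, time_h)
  as.data.frame(obs)
}

#' Generate a synthetic cohort
#'
#' Draws admission-level demographics, a latent severity trace per
#' admission, the mortality outcome from a logit on the 48-hour maximum
#' severity plus age and sex, an outcome-conditional lognormal length of
#' stay (floored at 2 days), and the sparse observation stream. The default
#' configuration is calibrated so that large-cohort marginals match the
#' published study cohort; everything is a deterministic function of the
#' config (including its seed).
#'
#' @param config a [cohort_config()].
#' @return A list of class `vistl_cohort`: `admissions` (data.frame),
#'   `observations` (long data.frame), `severity` (n x 48 latent matrix,
#'   kept for testing), `catalogue`, `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_admissions = 200, seed = 1))
#' mean(coh$admissions$outcome == "died")
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_admissions
  with_seed(config$seed, {
    ids <- sprintf("a%06d", seq_len(n))
    loc <- sample(names(config$location_probs), n, replace = TRUE,
                  prob = config$location_probs)
    ag <- config$age
    age <- qnorm(runif(n, pnorm(ag$min, ag$mean, ag$sd),
                       pnorm(ag$max, ag$mean, ag$sd)), ag$mean, ag$sd)
    female <- rbinom(n, 1L, config$female_p)
    race_black <- rbinom(n, 1L, config$race_black_p)
    cm <- sapply(config$comorbidity_p, function(p) rbinom(n, 1L, p))
    cm <- matrix(cm, nrow = n)
    colnames(cm) <- sprintf("cm_%d", seq_along(config$comorbidity_p))

    S <- severity_matrix(config, loc, 48L)
    max48 <- apply(S, 1, max)
    oc <- config$outcome
    eta <- oc$intercept + oc$beta_severity * max48 +
      (oc$beta_trend %||% 0) * severity_trend(S) +
      oc$beta_age * (age - oc$age_center) + oc$beta_female * female
    died <- rbinom(n, 1L, plogis(eta))

    ls <- config$los
    los <- ifelse(died == 1L,
                  rlnorm(n, ls$died_meanlog, ls$died_sdlog),
                  rlnorm(n, ls$alive_meanlog, ls$alive_sdlog))
    los <- pmax(ls$floor_days, los)

    admissions <- data.frame(
      id = ids, age = age, female = female, race_black = race_black,
      admission_location = loc,
      outcome = ifelse(died == 1L, "died", "alive"),
      los_days = los, stringsAsFactors = FALSE)
    admissions <- cbind(admissions, as.data.frame(cm))

    observations <- emit_observations_cohort(config, S, ids)

    structure(list(admissions = admissions, observations = observations,
                   severity = S, catalogue = config$catalogue,
                   config = config),
              class = "vistl_cohort")
  })
}

#' @export
print.vistl_cohort <- function(x, ...) {
  cat("<vistl_cohort> ", nrow(x$admissions), " admissions, ",
      nrow(x$observations), " observations, ",
      sum(x$admissions$outcome == "died"), " deaths (",
      round(100 * mean(x$admissions$outcome == "died"), 2), "%)\n", sep = "")
  invisible(x)
}

#' Extract one admission as a self-contained record
#'
#' @param cohort a `vistl_cohort`.
#' @param id admission id.
#' @return list with fields `id`, `age`, `female`, `race_black`,
#'   `admission_location`, `comorbidity_flags`, `observations` (data.frame),
#'   `outcome`, `los_days`, `latent_trace` (if the cohort kept it).
#' @export
admission_record <- function(cohort, id) {
  i <- match(id, cohort$admissions$id)
  if (is.na(i)) stop("unknown admission id: ", id)
  a <- cohort$admissions[i, ]
  cmcols <- grep("^cm_", names(a), value = TRUE)
  list(id = a$id, age = a$age, female = a$female, race_black = a$race_black,
       admission_location = a$admission_location,
       comorbidity_flags = as.integer(a[cmcols]),
       observations = cohort$observations[cohort$observations$id == id,
                                          c("variable", "time_h", "value")],
       outcome = a$outcome, los_days = a$los_days,
       latent_trace = if (!is.null(cohort$severity)) cohort$severity[i, ] else NULL)
}
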