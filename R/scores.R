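#' Early-warning score banding tables
#'
#' The MEWS and SOFA component bandings ship as CSV fixtures
#' (`inst/extdata/mews_bands.csv`, `sofa_bands.csv`) rather than code, so
#' they are auditable and swappable if a site uses variant bands. Bands are
#' half-open intervals `[low, high)`; an empty bound is unbounded. The SOFA
#' cardiovascular rows additionally key on the vasopressor flag (the
#' simulator emits a flag without dose, so the dose-graded rows collapse to
#' 3 without and 4 with concurrent hypotension).
#'
#' @param which `"mews"` or `"sofa"`.
#' @return data.frame of band rows.
#' @export
score_bands <- function(which = c("mews", "sofa")) {
  which <- match.arg(which)
  cached <- .vistl_cache[[paste0(which, "_bands")]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", paste0(which, "_bands.csv"),
                      package = "vistl", mustWork = TRUE)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  b$low[is.na(b$low)] <- -Inf
  b$high[is.na(b$high)] <- Inf
  .vistl_cache[[paste0(which, "_bands")]] <- b
  b
}

.vistl_cache <- new.env(parent = emptyenv())

# Band lookup: value vector -> points, for one component's rows
band_points <- function(x, rows) {
  o <- order(rows$low)
  lows <- rows$low[o]
  lows[1] <- -Inf
  rows$points[o][findInterval(x, lows)]
}

#' Modified Early Warning Score at one time point
#'
#' Sum of five banded components (systolic blood pressure, heart rate,
#' respiratory rate, temperature, AVPU consciousness), each 0-3 except
#' temperature (0-2); total range 0-14. Vectorized: each panel field may be
#' a vector.
#'
#' @param panel list/data.frame with `systolic_bp` (mmHg), `heart_rate`
#'   (/min), `resp_rate` (/min), `temperature` (degC), `avpu` (0-3 numeric
#'   or "alert"/"voice"/"pain"/"unresponsive").
#' @return integer vector of MEWS totals.
#' @export
mews_at_hour <- function(panel) {
  need <- c("systolic_bp", "heart_rate", "resp_rate", "temperature", "avpu")
  miss <- need[vapply(need, function(f) is.null(panel[[f]]) ||
                        anyNA(panel[[f]]), logical(1))]
  if (length(miss)) stop("MEWS panel missing/NA field(s): ",
                         paste(miss, collapse = ", "))
  avpu <- panel$avpu
  if (is.character(avpu) || is.factor(avpu)) {
    avpu <- c(alert = 0, voice = 1, pain = 2, unresponsive = 3)[as.character(avpu)]
    if (anyNA(avpu)) stop("unknown AVPU level")
  }
  b <- score_bands("mews")
  total <- band_points(panel$systolic_bp, b[b$component == "systolic_bp", ]) +
    band_points(panel$heart_rate,  b[b$component == "heart_rate", ]) +
    band_points(panel$resp_rate,   b[b$component == "resp_rate", ]) +
    band_points(panel$temperature, b[b$component == "temperature", ]) +
    band_points(avpu,              b[b$component == "avpu", ])
  as.integer(total)
}

#' Sequential Organ Failure Assessment score at one time point
#'
#' Sum of six organ components (respiration, coagulation, liver,
#' cardiovascular, central nervous system, renal), each 0-4; total 0-24.
#' The cardiovascular component keys on the vasopressor flag and mean
#' arterial pressure. The renal component uses creatinine; when
#' `urine_output_24h` is supplied (non-`NA`) the renal score is the worse of
#' the creatinine and urine bands.
#'
#' @param panel list/data.frame with `pao2_fio2_ratio` (mmHg), `platelets`
#'   (10^3/uL), `bilirubin` (mg/dL), `mean_arterial_pressure` (mmHg),
#'   `vasopressor` (0/1), `gcs` (3-15), `creatinine` (mg/dL), optional
#'   `urine_output_24h` (mL).
#' @return integer vector of SOFA totals.
#' @export
sofa_at_hour <- function(panel) {
  need <- c("pao2_fio2_ratio", "platelets", "bilirubin",
            "mean_arterial_pressure", "vasopressor", "gcs", "creatinine")
  miss <- need[vapply(need, function(f) is.null(panel[[f]]) ||
                        anyNA(panel[[f]]), logical(1))]
  if (length(miss)) stop("SOFA panel missing/NA field(s): ",
                         paste(miss, collapse = ", "))
  if (any(panel$gcs < 3 | panel$gcs > 15)) stop("gcs out of range [3, 15]")
  b <- score_bands("sofa")
  comp <- function(nm, x) band_points(x, b[b$component == nm, ])
  vaso <- as.integer(panel$vasopressor > 0)
  cardio_rows <- b[b$component == "cardiovascular", ]
  cardio <- ifelse(vaso == 1L,
                   band_points(panel$mean_arterial_pressure,
                               cardio_rows[cardio_rows$vaso == 1, ]),
                   band_points(panel$mean_arterial_pressure,
                               cardio_rows[cardio_rows$vaso == 0, ]))
  renal <- comp("renal", panel$creatinine)
  if (!is.null(panel$urine_output_24h)) {
    uo <- panel$urine_output_24h
    ok <- !is.na(uo)
    if (any(ok)) {
      renal_u <- comp("renal_urine", uo[ok])
      renal[ok] <- pmax(renal[ok], renal_u)
    }
  }
  total <- comp("respiration", panel$pao2_fio2_ratio) +
    comp("coagulation", panel$platelets) +
    comp("liver", panel$bilirubin) +
    cardio +
    comp("cns", panel$gcs) +
    renal
  as.integer(total)
}

# catalogue row -> panel field maps for the native-unit grid
mews_panel_vars <- function() {
  c(systolic_bp = "systolic_bp", heart_rate = "heart_rate",
    resp_rate = "resp_rate", temperature = "temperature", avpu = "avpu")
}
sofa_panel_vars <- function() {
  c(pao2_fio2_ratio = "pao2_fio2_ratio", platelets = "platelets",
    bilirubin = "bilirubin", mean_arterial_pressure = "mean_arterial_pressure",
    vasopressor = "med_vasopressor", gcs = "gcs", creatinine = "creatinine")
}

score_grid_hourly <- function(values, which, include_urine = FALSE) {
  vars <- if (which == "mews") mews_panel_vars() else sofa_panel_vars()
  miss <- setdiff(unname(vars), rownames(values))
  if (length(miss)) stop("grid lacks score input row(s): ",
                         paste(miss, collapse = ", "))
  panel <- lapply(vars, function(v) values[v, ])
  if (which == "mews") return(mews_at_hour(panel))
  H <- ncol(values)
  panel$urine_output_24h <- rep(NA_real_, H)
  if (include_urine && "urine_output" %in% rownames(values) && H >= 24) {
    # 24-h urine only defined from hour 24 on: trailing-rate x 24
    panel$urine_output_24h[24:H] <- values["urine_output", 24:H] * 24
  }
  sofa_at_hour(panel)
}

#' Hourly score trajectory and 48-hour maximum for one admission
#'
#' Builds the complete native-unit hourly grid (blocking, carry-forward,
#' location-median imputation), scores every hour, and returns the hourly
#' vector with its maximum — the paper-style "highest score within the
#' first 48 hours" comparator.
#'
#' @param admission an admission record ([admission_record()]).
#' @param which `"mews"` or `"sofa"`.
#' @param imputation_stats training-split [fit_imputation_stats()].
#' @param catalogue variable catalogue.
#' @param include_urine include the 24-h urine band in the SOFA renal
#'   component from hour 24 on (off by default: the hourly grid carries a
#'   rate, not a daily total).
#' @return list with `hourly` (integer vector), `max48`, `which`.
#' @export
max_score_48h <- function(admission, which = c("mews", "sofa"),
                          imputation_stats, catalogue,
                          include_urine = FALSE) {
  which <- match.arg(which)
  grid <- native_grid(admission, catalogue, imputation_stats)
  hourly <- score_grid_hourly(grid$values, which, include_urine)
  list(hourly = hourly, max48 = max(hourly), which = toupper(which))
}

#' Maximum 48-hour MEWS and SOFA for every admission in a cohort
#'
#' Batch version of [max_score_48h()] running on the vectorized native-unit
#' image stack.
#'
#' @param cohort a `vistl_cohort`.
#' @param ids admissions to score (default all).
#' @param imputation_stats training-split imputation stats.
#' @param include_urine see [max_score_48h()].
#' @return data.frame with `id`, `mews_max48`, `sofa_max48`.
#' @export
score_cohort <- function(cohort, ids = cohort$admissions$id,
                         imputation_stats, include_urine = FALSE) {
  stack <- encode_cohort(cohort, ids, imputation_stats, normalizer = NULL)
  V <- dim(stack$pixels)[1]; H <- dim(stack$pixels)[2]; N <- dim(stack$pixels)[3]
  flat <- matrix(stack$pixels, nrow = V)        # V x (H*N)
  rownames(flat) <- stack$row_labels
  mews <- matrix(score_grid_hourly(flat, "mews"), H, N)
  if (include_urine) {
    # the 24-h urine window is per-admission, so score per slice
    sofa <- vapply(seq_len(N), function(n) {
      sl <- stack$pixels[, , n]
      rownames(sl) <- stack$row_labels
      score_grid_hourly(sl, "sofa", TRUE)
    }, integer(H))
    sofa <- matrix(sofa, H, N)
  } else {
    sofa <- matrix(score_grid_hourly(flat, "sofa"), H, N)
  }
  data.frame(id = ids,
             mews_max48 = apply(mews, 2, max),
             sofa_max48 = apply(sofa, 2, max),
             stringsAsFactors = FALSE)
}
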