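#' Variable catalogues for visual timelines
#'
#' A catalogue is the ordered list of clinical variables that forms the
#' vertical axis of every visual timeline. Each variable carries its group
#' (vitals, labs, medications, interventions, nurse_exam, diagnostic_tests,
#' clinical_characteristics, location), its kind (continuous or binary), the
#' direction in which it becomes clinically abnormal (used by the "custom"
#' normalization), a plausible range in native units, and a clinically normal
#' reference value used by the synthetic generator and as a last-resort
#' imputation midpoint.
#'
#' The list order is the "standard ordering": variables arranged by group,
#' with no further ordering inside a group.
#'
#' @param preset `"demo"` (40 clinically named variables, every group
#'   represented) or `"full"` (the demo variables padded with generic
#'   numbered lab and medication channels to exactly 156 rows, matching the
#'   published feature-matrix height).
#' @return A `data.frame` of class `vistl_catalogue` with columns `name`,
#'   `group`, `kind`, `direction`, `low`, `high`, `normal`, `units`.
#' @examples
#' cat <- default_catalogue("demo")
#' nrow(default_catalogue("full"))  # 156
#' @export
default_catalogue <- function(preset = c("demo", "full")) {
  if (length(preset) == 1L && !preset %in% c("demo", "full")) {
    stop("unknown catalogue preset: '", preset, "' (use 'demo' or 'full')")
  }
  preset <- match.arg(preset)

  v <- function(name, group, kind, direction, low = NA_real_, high = NA_real_,
                normal = NA_real_, units = "") {
    data.frame(name = name, group = group, kind = kind, direction = direction,
               low = low, high = high, normal = normal, units = units,
               stringsAsFactors = FALSE)
  }

  rows <- list(
    ## vitals ---------------------------------------------------------------
    v("heart_rate",            "vitals", "continuous", "bidirectional",   20, 220,  75, "/min"),
    v("resp_rate",             "vitals", "continuous", "higher_abnormal",  4,  60,  14, "/min"),
    v("systolic_bp",           "vitals", "continuous", "lower_abnormal",  40, 260, 120, "mmHg"),
    v("mean_arterial_pressure","vitals", "continuous", "lower_abnormal",  30, 180,  85, "mmHg"),
    v("temperature",           "vitals", "continuous", "bidirectional",   32,  42,  37, "degC"),
    v("spo2",                  "vitals", "continuous", "lower_abnormal",  50, 100,  98, "%"),
    v("avpu",                  "vitals", "continuous", "higher_abnormal",  0,   3,   0, "AVPU level"),
    ## labs -----------------------------------------------------------------
    v("pao2_fio2_ratio", "labs", "continuous", "lower_abnormal",   40,  600, 450, "mmHg"),
    v("platelets",       "labs", "continuous", "lower_abnormal",    5, 1000, 250, "10^3/uL"),
    v("bilirubin",       "labs", "continuous", "higher_abnormal", 0.1,   30, 0.7, "mg/dL"),
    v("creatinine",      "labs", "continuous", "higher_abnormal", 0.2,   15, 0.9, "mg/dL"),
    v("lactate",         "labs", "continuous", "higher_abnormal", 0.3,   20, 1.0, "mmol/L"),
    v("wbc",             "labs", "continuous", "bidirectional",   0.1,   80,   8, "10^3/uL"),
    v("hemoglobin",      "labs", "continuous", "lower_abnormal",    3,   20,13.5, "g/dL"),
    v("sodium",          "labs", "continuous", "bidirectional",   110,  170, 140, "mmol/L"),
    v("potassium",       "labs", "continuous", "bidirectional",   1.5,    9,   4, "mmol/L"),
    v("bicarbonate",     "labs", "continuous", "lower_abnormal",    5,   45,  24, "mmol/L"),
    ## medications (binary: presence of an order in that hour) ---------------
    v("med_vasopressor", "medications", "binary", "none"),
    v("med_antibiotic",  "medications", "binary", "none"),
    v("med_opioid",      "medications", "binary", "none"),
    v("med_diuretic",    "medications", "binary", "none"),
    ## interventions ----------------------------------------------------------
    v("mechanical_ventilation", "interventions", "binary", "none"),
    v("supplemental_oxygen",    "interventions", "binary", "none"),
    v("central_line",           "interventions", "binary", "none"),
    v("telemetry_monitor",      "interventions", "binary", "none"),
    ## nurse examinations -----------------------------------------------------
    v("gcs",              "nurse_exam", "continuous", "lower_abnormal",   3,  15, 15, "points"),
    v("morse_fall_score", "nurse_exam", "continuous", "higher_abnormal",  0, 125, 25, "points"),
    v("braden_score",     "nurse_exam", "continuous", "lower_abnormal",   6,  23, 20, "points"),
    v("pain_score",       "nurse_exam", "continuous", "higher_abnormal",  0,  10,  1, "points"),
    v("urine_output",     "nurse_exam", "continuous", "lower_abnormal",   0, 200, 80, "mL/h"),
    ## diagnostic tests -------------------------------------------------------
    v("chest_xray", "diagnostic_tests", "binary", "none"),
    v("ekg",        "diagnostic_tests", "binary", "none"),
    ## clinical characteristics (static, rendered as constant rows) -----------
    v("age_years",         "clinical_characteristics", "continuous", "higher_abnormal", 18, 100, 55, "years"),
    v("sex_female",        "clinical_characteristics", "binary", "none"),
    v("race_black",        "clinical_characteristics", "binary", "none"),
    v("comorbidity_count", "clinical_characteristics", "continuous", "higher_abnormal", 0, 10, 0, "count"),
    ## location (one-hot, static) ---------------------------------------------
    v("loc_ward", "location", "binary", "none"),
    v("loc_ed",   "location", "binary", "none"),
    v("loc_icu",  "location", "binary", "none"),
    v("loc_other","location", "binary", "none")
  )
  cat <- do.call(rbind, rows)

  if (preset == "full") {
    # Pad to 156 rows with generic numbered channels, inserted inside their
    # group blocks so the catalogue stays grouped (standard ordering).
    n_pad <- 156L - nrow(cat)
    n_lab <- ceiling(n_pad / 2)
    n_med <- n_pad - n_lab
    pad_lab <- do.call(rbind, lapply(seq_len(n_lab), function(i) {
      v(sprintf("lab_ch_%02d", i), "labs", "continuous",
        if (i %% 2 == 0) "higher_abnormal" else "lower_abnormal",
        0, 100, 50, "arb")
    }))
    pad_med <- do.call(rbind, lapply(seq_len(n_med), function(i) {
      v(sprintf("med_ch_%02d", i), "medications", "binary", "none")
    }))
    cat <- rbind(cat, pad_lab, pad_med)
    grp_order <- variable_groups()
    cat <- cat[order(match(cat$group, grp_order)), , drop = FALSE]
  }

  rownames(cat) <- NULL
  cat$preset <- preset
  class(cat) <- c("vistl_catalogue", "data.frame")
  validate_catalogue(cat)
  cat
}

#' The eight variable groups, in standard display order
#' @return Character vector of group names.
#' @export
variable_groups <- function() {
  c("vitals", "labs", "medications", "interventions", "nurse_exam",
    "diagnostic_tests", "clinical_characteristics", "location")
}

validate_catalogue <- function(cat) {
  stopifnot(is.data.frame(cat),
            all(c("name", "group", "kind", "direction", "low", "high",
                  "normal") %in% names(cat)))
  if (anyDuplicated(cat$name)) {
    stop("catalogue variable names must be unique; duplicated: ",
         paste(unique(cat$name[duplicated(cat$name)]), collapse = ", "))
  }
  if (!all(cat$group %in% variable_groups())) {
    stop("unknown variable group(s): ",
         paste(setdiff(cat$group, variable_groups()), collapse = ", "))
  }
  cont <- cat$kind == "continuous"
  if (any(cont & (is.na(cat$low) | is.na(cat$high) | cat$low >= cat$high))) {
    stop("continuous variables need plausible_range low < high")
  }
  if (any(cont & cat$direction == "none")) {
    stop("continuous variables need a direction (not 'none')")
  }
  if (any(!cont & cat$direction != "none")) {
    stop("binary variables must have direction 'none'")
  }
  invisible(cat)
}

# Static groups are rendered from admission-level fields, never observed.
static_groups <- function() c("clinical_characteristics", "location")

catalogue_index <- function(cat, names) {
  idx <- match(names, cat$name)
  if (anyNA(idx)) {
    stop("variable(s) not in catalogue: ",
         paste(unique(names[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Serialize / load a catalogue as YAML
#'
#' @param cat a `vistl_catalogue`
#' @param path file path
#' @return `read_catalogue_yaml` returns a `vistl_catalogue`.
#' @export
write_catalogue_yaml <- function(cat, path) {
  validate_catalogue(cat)
  recs <- lapply(seq_len(nrow(cat)), function(i) {
    r <- as.list(cat[i, setdiff(names(cat), "preset"), drop = FALSE])
    lapply(r, function(x) if (is.na(x)) NULL else x)
  })
  yaml::write_yaml(list(preset = cat$preset[1], variables = recs), path)
  invisible(path)
}

#' @rdname write_catalogue_yaml
#' @export
read_catalogue_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cat <- data.table::rbindlist(lapply(obj$variables, function(r) {
    data.frame(name = r$name, group = r$group, kind = r$kind,
               direction = r$direction,
               low = if (is.null(r$low)) NA_real_ else as.numeric(r$low),
               high = if (is.null(r$high)) NA_real_ else as.numeric(r$high),
               normal = if (is.null(r$normal)) NA_real_ else as.numeric(r$normal),
               units = if (is.null(r$units)) "" else r$units,
               stringsAsFactors = FALSE)
  }))
  cat <- as.data.frame(cat)
  cat$preset <- obj$preset %||% "demo"
  class(cat) <- c("vistl_catalogue", "data.frame")
  validate_catalogue(cat)
  cat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
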