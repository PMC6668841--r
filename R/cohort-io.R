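#' Write / read a cohort as a pair of CSV files
#'
#' `admissions.csv` holds one row per admission (id, age, female, race_black,
#' admission_location, outcome, los_days, plus comorbidity flag columns);
#' `observations.csv` is long format (id, variable, time_h, value). The round
#' trip is lossless to the written float precision (15 significant digits).
#' The latent severity matrix is a test-only field and is not serialized.
#'
#' @param cohort a `vistl_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort_csv` returns `dir` invisibly; `read_cohort_csv`
#'   returns a `vistl_cohort` (without `severity` or `config`).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adm_path <- file.path(dir, "admissions.csv")
  obs_path <- file.path(dir, "observations.csv")
  data.table::fwrite(cohort$admissions, adm_path)
  data.table::fwrite(cohort$observations, obs_path)
  write_catalogue_yaml(cohort$catalogue, file.path(dir, "catalogue.yaml"))
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @param catalogue catalogue used to validate variable names; if `NULL`,
#'   `catalogue.yaml` in `dir` is loaded.
#' @export
read_cohort_csv <- function(dir, catalogue = NULL) {
  adm_path <- file.path(dir, "admissions.csv")
  obs_path <- file.path(dir, "observations.csv")
  for (p in c(adm_path, obs_path)) {
    if (!file.exists(p)) stop("missing cohort file: ", p)
  }
  if (is.null(catalogue)) {
    cy <- file.path(dir, "catalogue.yaml")
    if (!file.exists(cy)) stop("no catalogue given and no catalogue.yaml in ", dir)
    catalogue <- read_catalogue_yaml(cy)
  }
  adm <- as.data.frame(data.table::fread(adm_path))
  obs <- as.data.frame(data.table::fread(obs_path))

  need_adm <- c("id", "age", "female", "race_black", "admission_location",
                "outcome", "los_days")
  if (!all(need_adm %in% names(adm))) {
    stop("admissions.csv lacks column(s): ",
         paste(setdiff(need_adm, names(adm)), collapse = ", "))
  }
  bad <- which(!adm$outcome %in% c("died", "alive"))
  if (length(bad)) stop("admissions.csv row ", bad[1], ": bad outcome '",
                        adm$outcome[bad[1]], "'")
  bad <- which(!adm$admission_location %in% admission_locations())
  if (length(bad)) stop("admissions.csv row ", bad[1], ": bad location '",
                        adm$admission_location[bad[1]], "'")
  bad <- which(adm$los_days < 2)
  if (length(bad)) stop("admissions.csv row ", bad[1],
                        ": los_days < 2 (cohort requires >= 48 h stays)")

  need_obs <- c("id", "variable", "time_h", "value")
  if (!all(need_obs %in% names(obs))) {
    stop("observations.csv lacks column(s): ",
         paste(setdiff(need_obs, names(obs)), collapse = ", "))
  }
  bad <- which(obs$time_h < 0)
  if (length(bad)) stop("observations.csv row ", bad[1], ": negative time_h")
  bad <- which(!obs$variable %in% catalogue$name)
  if (length(bad)) stop("observations.csv row ", bad[1],
                        ": unknown variable '", obs$variable[bad[1]], "'")
  bad <- which(!obs$id %in% adm$id)
  if (length(bad)) stop("observations.csv row ", bad[1],
                        ": unknown admission id '", obs$id[bad[1]], "'")
  bad <- which(!is.finite(obs$value))
  if (length(bad)) stop("observations.csv row ", bad[1], ": non-finite value")

  structure(list(admissions = adm, observations = obs, severity = NULL,
                 catalogue = catalogue, config = NULL),
            class = "vistl_cohort")
}
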