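#' Block sparse observations into an hourly grid
#'
#' Hour bins are 0-based and half-open: bin `h` covers times in `[h, h+1)`.
#' Cell `(v, h)` holds the latest observation of variable `v` inside bin `h`
#' if there is one, otherwise the most recent earlier value carried forward
#' (LOCF), otherwise missing (`NA`). When two observations share a bin the
#' later timestamp wins; exact timestamp ties resolve to the later input row.
#'
#' @param observations data.frame with columns `variable`, `time_h`, `value`.
#' @param catalogue the variable catalogue (defines the row order).
#' @param n_hours number of hourly bins (48 for the standard timeline).
#' @param admission_location carried on the grid for location-specific
#'   imputation downstream.
#' @return A `vistl_hourly_grid`: list with `values` (V x n_hours matrix in
#'   native units, `NA` = missing), `observed_mask` (TRUE where an in-bin
#'   observation landed, before carry-forward), `catalogue`,
#'   `admission_location`, `n_dropped` (observations at `time_h >= n_hours`,
#'   dropped with a warning).
#' @export
block_hourly <- function(observations, catalogue, n_hours = 48L,
                         admission_location = NA_character_) {
  validate_catalogue(catalogue)
  V <- nrow(catalogue)
  vals <- matrix(NA_real_, V, n_hours, dimnames = list(catalogue$name, NULL))
  in_hour <- matrix(FALSE, V, n_hours)
  n_dropped <- 0L
  if (nrow(observations)) {
    if (any(observations$time_h < 0)) stop("observation with negative time_h")
    vi <- catalogue_index(catalogue, observations$variable)
    late <- observations$time_h >= n_hours
    n_dropped <- sum(late)
    if (n_dropped) {
      warning(n_dropped, " observation(s) at or beyond hour ", n_hours,
              " dropped")
    }
    obs <- observations[!late, , drop = FALSE]
    vi <- vi[!late]
    if (nrow(obs)) {
      hour <- as.integer(floor(obs$time_h))
      # later timestamp wins; ties resolve to later input order
      o <- order(vi, hour, obs$time_h, seq_along(vi))
      vi <- vi[o]; hour <- hour[o]; val <- obs$value[o]
      keep <- !duplicated(cbind(vi, hour)[rev(seq_along(vi)), , drop = FALSE])
      keep <- rev(keep)
      vals[cbind(vi[keep], hour[keep] + 1L)] <- val[keep]
      in_hour[cbind(vi[keep], hour[keep] + 1L)] <- TRUE
    }
  }
  # carry forward along the time axis
  for (h in seq_len(n_hours)[-1]) {
    na <- is.na(vals[, h])
    vals[na, h] <- vals[na, h - 1L]
  }
  structure(list(values = vals, observed_mask = !is.na(vals),
                 in_hour_mask = in_hour, catalogue = catalogue,
                 admission_location = admission_location,
                 n_dropped = n_dropped),
            class = "vistl_hourly_grid")
}

#' Fit location-specific imputation medians on a training cohort
#'
#' For every continuous variable, the median of all observed values is
#' computed per admission location, with the variable's global median as
#' fallback for locations never observed, and the plausible-range midpoint
#' as final fallback for variables never observed anywhere. Binary variables
#' impute 0 (absence). Static clinical-characteristic and location rows are
#' rendered from admission fields, so their fallbacks are only reached for
#' grids built without that information.
#'
#' @param cohort a `vistl_cohort` restricted to the training split (see
#'   [split_cohort()]).
#' @param fitted_on free-text id of the split the stats come from; stored
#'   and checked downstream to keep validation data out of fitting.
#' @return A `vistl_imputation_stats` object.
#' @export
fit_imputation_stats <- function(cohort, fitted_on = "training") {
  if (!nrow(cohort$admissions)) stop("training cohort is empty")
  cat <- cohort$catalogue
  locs <- admission_locations()
  obs <- data.table::as.data.table(cohort$observations)
  adm <- data.table::as.data.table(
    cohort$admissions[, c("id", "admission_location")])
  obs <- merge(obs, adm, by = "id")
  med_loc <- matrix(NA_real_, nrow(cat), length(locs),
                    dimnames = list(cat$name, locs))
  if (nrow(obs)) {
    agg <- obs[, list(med = stats::median(value)),
               by = c("variable", "admission_location")]
    med_loc[cbind(match(agg$variable, cat$name),
                  match(agg$admission_location, locs))] <- agg$med
    glob <- obs[, list(med = stats::median(value)), by = "variable"]
    global <- stats::setNames(rep(NA_real_, nrow(cat)), cat$name)
    global[glob$variable] <- glob$med
  } else {
    global <- stats::setNames(rep(NA_real_, nrow(cat)), cat$name)
  }
  midpoint <- ifelse(cat$kind == "binary", 0, (cat$low + cat$high) / 2)
  structure(list(median_by_location = med_loc, global_median = global,
                 midpoint = stats::setNames(midpoint, cat$name),
                 binary = stats::setNames(cat$kind == "binary", cat$name),
                 fitted_on = fitted_on,
                 fitted_ids = cohort$admissions$id),
            class = "vistl_imputation_stats")
}

#' Fill the remaining missing cells of an hourly grid
#'
#' Applied after carry-forward: cells still missing get the admission
#' location's median for that variable, then the global median, then the
#' plausible-range midpoint (binary variables get 0). Observed cells are
#' untouched and the observation mask is preserved for audit.
#'
#' @param grid a `vistl_hourly_grid`.
#' @param stats a `vistl_imputation_stats`.
#' @return A complete `vistl_hourly_grid` (no `NA` cells).
#' @export
impute_missing <- function(grid, stats) {
  cat <- grid$catalogue
  miss <- setdiff(cat$name, rownames(stats$median_by_location))
  if (length(miss)) {
    stop("imputation stats lack variable(s): ", paste(miss, collapse = ", "))
  }
  fill <- imputation_fill_values(stats, cat, grid$admission_location)
  vals <- grid$values
  na <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(na)) vals[na] <- fill[na[, 1L]]
  grid$values <- vals
  grid
}

# Resolve the per-variable fill value for one admission location
imputation_fill_values <- function(stats, cat, location) {
  fill <- stats$midpoint[cat$name]
  fill[stats$binary[cat$name]] <- 0
  g <- stats$global_median[cat$name]
  fill[!is.na(g)] <- g[!is.na(g)]
  if (!is.na(location) && location %in% colnames(stats$median_by_location)) {
    m <- stats$median_by_location[cat$name, location]
    fill[!is.na(m)] <- m[!is.na(m)]
  }
  unname(fill)
}

# Render the static clinical-characteristic and location rows from the
# admission-level fields, in native units.
static_row_values <- function(cat, admission) {
  vals <- rep(NA_real_, nrow(cat))
  set_if <- function(name, value) {
    i <- match(name, cat$name)
    if (!is.na(i)) vals[i] <<- value
  }
  set_if("age_years", admission$age)
  set_if("sex_female", admission$female)
  set_if("race_black", admission$race_black)
  cm <- if (!is.null(admission$comorbidity_flags)) {
    sum(admission$comorbidity_flags)
  } else {
    sum(unlist(admission[grep("^cm_", names(admission))]))
  }
  set_if("comorbidity_count", cm)
  for (l in admission_locations()) {
    set_if(paste0("loc_", l),
           as.numeric(identical(admission$admission_location, l)))
  }
  vals
}

#' Build the complete native-unit hourly grid for one admission
#'
#' Composition of [block_hourly()], carry-forward, [impute_missing()], and
#' rendering of the static rows (age, sex, race, comorbidity count, location
#' one-hot) as constant values across all hours. This is the representation
#' the MEWS/SOFA scorers consume; normalization happens afterwards.
#'
#' @inheritParams encode_admission
#' @return A complete `vistl_hourly_grid` in native units.
#' @export
native_grid <- function(admission, catalogue, imputation_stats,
                        n_hours = 48L) {
  grid <- block_hourly(admission$observations, catalogue, n_hours,
                       admission$admission_location)
  grid <- impute_missing(grid, imputation_stats)
  sv <- static_row_values(catalogue, admission)
  stat_rows <- which(!is.na(sv))
  if (length(stat_rows)) {
    grid$values[stat_rows, ] <- matrix(sv[stat_rows], length(stat_rows),
                                       n_hours)
  }
  grid
}
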