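# Shared fixtures, built lazily and memoised for the session.
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# A small default cohort used across encoder / score / model tests.
small_cohort <- function(n = 400, seed = 7) {
  memo(paste0("cohort_", n, "_", seed),
       generate_cohort(cohort_config(n_admissions = n, seed = seed)))
}

small_split <- function(coh = small_cohort(), seed = 7) {
  memo(paste0("split_", nrow(coh$admissions), "_", seed),
       make_split(coh$admissions$id, seed))
}

small_stats <- function(coh = small_cohort(), split = small_split()) {
  memo("stats_small",
       fit_imputation_stats(split_cohort(coh, split$train_ids), "train"))
}

# hand-built admission record for precise encoder checks
toy_admission <- function(observations, location = "ward", age = 60,
                          female = 1, race = 0) {
  list(id = "toy1", age = age, female = female, race_black = race,
       admission_location = location, comorbidity_flags = c(1L, 0L),
       observations = observations, outcome = "alive", los_days = 4)
}

obs_df <- function(variable, time_h, value) {
  data.frame(variable = variable, time_h = time_h, value = value,
             stringsAsFactors = FALSE)
}

# scalar brute-force reference for hourly blocking + LOCF of one variable
locf_reference <- function(times, values, n_hours = 48) {
  out <- rep(NA_real_, n_hours)
  for (h in seq_len(n_hours) - 1L) {
    sel <- which(times < h + 1)
    if (length(sel)) {
      # latest time wins; ties at identical time -> later input row
      best <- sel[order(times[sel], sel)][length(sel)]
      out[h + 1L] <- values[best]
    }
  }
  out
}
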