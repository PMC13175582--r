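# Cohort filters and 4-hour trajectory construction.
#
# The cohort rule set: suspected sepsis means an antibiotic administration
# and a microbial culture within 24 hours of each other; stays shorter than
# 12 hours are excluded; data past the cohort-level 95th percentile of stay
# length is removed; and timesteps at or after a comfort-measures-only order
# are censored.

#' Cohort configuration
#'
#' @param suspicion_window_hours maximum antibiotic-culture gap defining
#'   suspected sepsis (default 24)
#' @param min_stay_hours minimum ICU stay, inclusive (default 12)
#' @param truncation_percentile cohort-level stay-length percentile beyond
#'   which data is removed (default 95)
#' @param bin_hours width of a timestep bin (default 4)
#' @param split_fraction fraction of patients assigned to the training split
#' @param split_seed seed of the patient-level split
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(suspicion_window_hours = 24, min_stay_hours = 12,
                          truncation_percentile = 95, bin_hours = 4,
                          split_fraction = 0.5, split_seed = 1L) {
  cfg <- structure(list(suspicion_window_hours = suspicion_window_hours,
                        min_stay_hours = min_stay_hours,
                        truncation_percentile = truncation_percentile,
                        bin_hours = bin_hours,
                        split_fraction = split_fraction,
                        split_seed = as.integer(split_seed)),
                   class = "cohort_config")
  for (f in c("suspicion_window_hours", "min_stay_hours", "bin_hours"))
    if (!is_num1(cfg[[f]]) || cfg[[f]] <= 0)
      config_error("invalid configuration field '%s': must be positive", f)
  if (!is_num1(cfg$truncation_percentile) || cfg$truncation_percentile <= 0 ||
      cfg$truncation_percentile > 100)
    config_error("invalid configuration field 'truncation_percentile': must be in (0, 100]")
  if (!is_num1(cfg$split_fraction) || cfg$split_fraction <= 0 ||
      cfg$split_fraction >= 1)
    config_error("invalid configuration field 'split_fraction': must be in (0, 1)")
  cfg
}

#' Read a cohort from the CSV schema
#'
#' Inverse of [write_cohort()]. The same reader accepts any extract reshaped
#' to the documented schema (`patients.csv`, `icustays.csv`, `events.csv`,
#' `treatments.csv`, with hours measured from ICU admission).
#'
#' @param directory cohort directory
#' @return list of `patient_record`
#' @export
read_cohort <- function(directory) {
  need <- c("patients.csv", "icustays.csv", "events.csv", "treatments.csv")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing))
    io_error("cohort directory '%s' is missing %s", directory,
             paste(missing, collapse = ", "))
  pats <- fread(file.path(directory, "patients.csv"),
                colClasses = list(character = "patient_id"))
  stays <- fread(file.path(directory, "icustays.csv"),
                 colClasses = list(character = c("stay_id", "patient_id"),
                                   numeric = c("intime", "outtime", "death_time"),
                                   integer = "death_flag"))
  events <- fread(file.path(directory, "events.csv"),
                  colClasses = list(character = c("patient_id", "feature_name"),
                                    numeric = c("time_hours", "value")))
  treatments <- fread(file.path(directory, "treatments.csv"),
                      colClasses = list(character = c("patient_id", "treatment"),
                                        numeric = c("time_hours", "amount")))
  if (!nrow(pats)) return(list())
  demo_cols <- setdiff(names(pats), "patient_id")
  lapply(seq_len(nrow(pats)), function(i) {
    pid <- pats$patient_id[i]
    st <- stays[stays$patient_id == pid][1]
    ev <- events[events$patient_id == pid, c("time_hours", "feature_name", "value")]
    tr <- treatments[treatments$patient_id == pid, c("time_hours", "treatment", "amount")]
    setorder(ev, time_hours, feature_name)
    setorder(tr, time_hours, treatment)
    cmo <- tr$time_hours[tr$treatment == "cmo"]
    patient_record(
      patient_id = pid,
      demographics = stats::setNames(as.numeric(pats[i, demo_cols, with = FALSE]),
                                     demo_cols),
      icu_intime = st$intime, icu_outtime = st$outtime,
      death_flag = st$death_flag == 1,
      death_time = as.numeric(st$death_time),
      events = ev, treatments = tr,
      cmo_time = if (length(cmo)) min(cmo) else NA_real_,
      antibiotic_times = tr$time_hours[tr$treatment == "antibiotic"],
      culture_times = tr$time_hours[tr$treatment == "culture"])
  })
}

#' Sepsis suspicion time
#'
#' Earliest time `t = min(a, c)` over antibiotic times `a` and culture times
#' `c` with `|a - c| <= suspicion_window_hours`; `NA` when no pair qualifies.
#'
#' @param record a `patient_record`
#' @param config a [cohort_config()]
#' @return hours, or `NA_real_`
#' @export
suspicion_time <- function(record, config = cohort_config()) {
  a <- record$antibiotic_times
  c_ <- record$culture_times
  if (!length(a) || !length(c_)) return(NA_real_)
  gaps <- abs(outer(a, c_, `-`)) <= config$suspicion_window_hours
  if (!any(gaps)) return(NA_real_)
  starts <- outer(a, c_, pmin)
  min(starts[gaps])
}

#' Cohort eligibility
#'
#' A record is eligible when a suspicion time exists and the ICU stay lasted
#' at least `min_stay_hours` (inclusive).
#'
#' @inheritParams suspicion_time
#' @return logical
#' @export
eligible <- function(record, config = cohort_config()) {
  !is.na(suspicion_time(record, config)) &&
    (record$icu_outtime - record$icu_intime) >= config$min_stay_hours
}

#' Cohort-level stay-length truncation cutoff
#'
#' The `truncation_percentile`-th percentile (linear interpolation between
#' order statistics) of eligible patients' stay lengths. All trajectory
#' building uses this single cohort-level cutoff.
#'
#' @param records list of `patient_record`
#' @param config a [cohort_config()]
#' @return hours
#' @export
stay_length_cutoff <- function(records, config = cohort_config()) {
  keep <- vapply(records, eligible, logical(1), config = config)
  if (!any(keep)) domain_error("no eligible records: cannot compute stay-length cutoff")
  stays <- vapply(records[keep], function(r) r$icu_outtime - r$icu_intime,
                  numeric(1))
  unname(stats::quantile(stays, config$truncation_percentile / 100, type = 7))
}

# Which measured features are forward-filled labs (vs within-bin-averaged
# vitals). Unknown feature names default to vital-style aggregation.
lab_feature_names <- function() {
  cat_feat <- feature_catalog()
  cat_feat$name[cat_feat$kind == "lab"]
}

# per-feature cohort medians used for missing-at-start imputation
cohort_feature_medians <- function(records, feature_names) {
  ev <- rbindlist(lapply(records, function(r) r$events))
  med <- stats::setNames(rep(NA_real_, length(feature_names)), feature_names)
  if (nrow(ev)) {
    m <- ev[, list(med = stats::median(value)), by = "feature_name"]
    med[m$feature_name] <- m$med
  }
  med[is.na(med)] <- 0
  med
}

#' Build a binned trajectory for one eligible patient
#'
#' Bins are half-open `[i * bin_hours, (i + 1) * bin_hours)` from ICU
#' admission; an event exactly on a boundary belongs to the later bin.
#' Vitals are averaged within bin and carried forward when a bin has no
#' observation; labs carry their most recent value; either carries a
#' cohort-level median before the first observation. Every carried value is
#' marked in the imputed-flag matrix. Fluids are summed per bin; vasopressor
#' and diuretic activity are per-bin flags. States are dropped from the
#' first bin whose start reaches the CMO order and from any bin whose start
#' reaches the cohort cutoff.
#'
#' Labels: `vaso_at_12h` at bin `b` is the vasopressor flag of the bin
#' starting 12 h after bin `b`'s start, `NA` when the admission (alive or
#' dead) ends before that bin exists; `died_in_admission` is the admission's
#' death flag at every state.
#'
#' @param record an eligible `patient_record`
#' @param cutoff cohort-level stay-length cutoff from [stay_length_cutoff()]
#' @param config a [cohort_config()]
#' @param feature_names measured feature order (defaults to the sorted
#'   features present in this record)
#' @param cohort_medians named vector of per-feature medians for
#'   missing-at-start imputation
#' @return an object of class `trajectory`
#' @export
build_trajectory <- function(record, cutoff, config = cohort_config(),
                             feature_names = NULL, cohort_medians = NULL) {
  if (!eligible(record, config))
    domain_error("patient %s is not eligible for the cohort", record$patient_id)
  bw <- config$bin_hours
  stay_len <- record$icu_outtime - record$icu_intime
  n_full <- max(1L, ceiling(stay_len / bw))
  if (is.null(feature_names))
    feature_names <- sort(unique(record$events$feature_name))
  if (is.null(cohort_medians))
    cohort_medians <- cohort_feature_medians(list(record), feature_names)
  labs <- intersect(feature_names, lab_feature_names())

  feats <- matrix(NA_real_, n_full, length(feature_names),
                  dimnames = list(NULL, feature_names))
  imputed <- matrix(TRUE, n_full, length(feature_names),
                    dimnames = list(NULL, feature_names))
  ev <- record$events
  ev_bin <- if (nrow(ev)) as.integer(floor(ev$time_hours / bw)) else integer(0)
  for (f in feature_names) {
    sel <- which(ev$feature_name == f & ev_bin < n_full)
    last <- cohort_medians[[f]]
    for (b in seq_len(n_full)) {
      in_bin <- sel[ev_bin[sel] == b - 1L]
      if (length(in_bin)) {
        if (f %in% labs) {
          # most recent observation within the bin
          last <- ev$value[in_bin[which.max(ev$time_hours[in_bin])]]
        } else {
          last <- mean(ev$value[in_bin])
        }
        imputed[b, f] <- FALSE
      }
      feats[b, f] <- last
    }
  }

  tr <- record$treatments
  tr_bin <- if (nrow(tr)) as.integer(floor(tr$time_hours / bw)) else integer(0)
  fluid_ml <- vapply(seq_len(n_full) - 1L, function(b)
    sum(tr$amount[tr$treatment == "fluid_ml" & tr_bin == b]), numeric(1))
  vaso_active <- vapply(seq_len(n_full) - 1L, function(b)
    any(tr$treatment == "vasopressor_rate" & tr_bin == b), logical(1))
  diuretic_given <- vapply(seq_len(n_full) - 1L, function(b)
    any(tr$treatment == "diuretic_mg" & tr_bin == b), logical(1))

  horizon <- as.integer(round(12 / bw))
  vaso_at_12h <- rep(NA, n_full)
  ok <- seq_len(n_full) + horizon <= n_full
  vaso_at_12h[ok] <- vaso_active[which(ok) + horizon]

  demo <- record$demographics
  all_names <- c(names(demo), feature_names)
  feats <- cbind(matrix(rep(as.numeric(demo), each = n_full), n_full,
                        dimnames = list(NULL, names(demo))), feats)
  imputed <- cbind(matrix(FALSE, n_full, length(demo),
                          dimnames = list(NULL, names(demo))), imputed)

  # censoring: percentile cutoff and comfort-measures-only order
  starts <- (seq_len(n_full) - 1L) * bw
  keep <- starts < cutoff
  if (!is.na(record$cmo_time)) keep <- keep & starts < record$cmo_time
  keep_idx <- which(keep)
  if (!length(keep_idx))
    domain_error("patient %s has no uncensored states", record$patient_id)

  structure(list(
    patient_id = record$patient_id,
    bin_index = keep_idx - 1L,
    features = feats[keep_idx, , drop = FALSE],
    imputed = imputed[keep_idx, , drop = FALSE],
    actions = data.table(fluid_ml = fluid_ml[keep_idx],
                         vaso_active = vaso_active[keep_idx],
                         diuretic_given = diuretic_given[keep_idx]),
    labels = data.table(vaso_at_12h = vaso_at_12h[keep_idx],
                        died_in_admission = rep(record$death_flag,
                                                length(keep_idx))),
    truncated_at_cmo = !is.na(record$cmo_time) &&
      any(starts >= record$cmo_time),
    truncated_at_percentile = any(starts >= cutoff),
    feature_names = all_names), class = "trajectory")
}

#' @export
format.trajectory <- function(x, ...) {
  sprintf("<trajectory %s: %d states x %d features%s%s>",
          x$patient_id, length(x$bin_index), ncol(x$features),
          if (x$truncated_at_cmo) ", CMO-censored" else "",
          if (x$truncated_at_percentile) ", percentile-truncated" else "")
}

#' @export
print.trajectory <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Build trajectories for a whole cohort
#'
#' Applies the eligibility filters, computes the single cohort-level
#' stay-length cutoff and the imputation medians over the eligible records,
#' and builds one trajectory per eligible patient with a shared feature
#' schema.
#'
#' @param records list of `patient_record`
#' @param config a [cohort_config()]
#' @return an object of class `trajectory_set`: list with `trajectories`,
#'   `cutoff`, `medians`, `feature_names` (the shared state-vector order)
#' @export
build_trajectories <- function(records, config = cohort_config()) {
  keep <- vapply(records, eligible, logical(1), config = config)
  if (!any(keep)) domain_error("no eligible records in cohort")
  records <- records[keep]
  measured <- sort(unique(unlist(lapply(records, function(r)
    unique(r$events$feature_name)))))
  cutoff <- stay_length_cutoff(records, config)
  medians <- cohort_feature_medians(records, measured)
  # a CMO order in the first bin censors every state; such patients
  # contribute nothing to the trajectory set
  fully_censored <- vapply(records, function(r)
    !is.na(r$cmo_time) && r$cmo_time <= 0, logical(1))
  records <- records[!fully_censored]
  if (!length(records)) domain_error("every eligible record is fully censored")
  trajs <- lapply(records, build_trajectory, cutoff = cutoff, config = config,
                  feature_names = measured, cohort_medians = medians)
  names(trajs) <- vapply(trajs, `[[`, character(1), "patient_id")
  structure(list(trajectories = trajs, cutoff = cutoff, medians = medians,
                 feature_names = trajs[[1]]$feature_names, config = config),
            class = "trajectory_set")
}

#' @export
format.trajectory_set <- function(x, ...) {
  sprintf("<trajectory_set: %d patients, %d states, cutoff %.1f h>",
          length(x$trajectories),
          sum(vapply(x$trajectories, function(t) length(t$bin_index), integer(1))),
          x$cutoff)
}

#' @export
print.trajectory_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Patient-level train/evaluation split
#'
#' Disjoint, exhaustive split with `floor(split_fraction * n)` training
#' patients, deterministic given `split_seed`.
#'
#' @param records list of `patient_record` (or a `trajectory_set`)
#' @param config a [cohort_config()]
#' @return list with `train` and `eval` character vectors of patient ids
#' @export
split_cohort <- function(records, config = cohort_config()) {
  ids <- if (inherits(records, "trajectory_set"))
    names(records$trajectories)
  else vapply(records, `[[`, character(1), "patient_id")
  if (length(ids) < 2) domain_error("need at least 2 patients to split")
  shuffled <- with_seed(config$split_seed, sample(ids))
  n_train <- floor(config$split_fraction * length(ids))
  list(train = sort(shuffled[seq_len(n_train)]),
       eval = sort(shuffled[-seq_len(n_train)]))
}

# --- tabular views and persistence ------------------------------------------

state_input_names <- function(ts) c(ts$feature_names, "fluid_ml",
                                    "vaso_active", "diuretic_given")

#' Tabular views of a trajectory set
#'
#' `states_table()` returns one row per state: identifiers, the fixed-order
#' feature vector, imputation flags (`imp_<feature>` for measured features)
#' and the in-bin actions. `labels_table()` returns the per-state outcome
#' labels.
#'
#' @param ts a `trajectory_set`
#' @return a data.table
#' @export
states_table <- function(ts) {
  rbindlist(lapply(ts$trajectories, function(tr) {
    dt <- data.table(patient_id = tr$patient_id, bin_index = tr$bin_index)
    dt <- cbind(dt, as.data.table(tr$features))
    imp <- as.data.table(tr$imputed)
    setnames(imp, paste0("imp_", names(imp)))
    cbind(dt, imp, tr$actions)
  }))
}

#' @rdname states_table
#' @export
labels_table <- function(ts) {
  rbindlist(lapply(ts$trajectories, function(tr)
    data.table(patient_id = tr$patient_id, bin_index = tr$bin_index,
               tr$labels)))
}

#' Write / read trajectories as a two-file set
#'
#' `states.csv` holds one row per state (feature order documented in the
#' sidecar `schema.json`), `labels.csv` the outcome labels.
#'
#' @param ts a `trajectory_set`
#' @param directory output directory
#' @return the directory, invisibly
#' @export
write_trajectories <- function(ts, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) io_error("cannot create '%s'", directory)
  fwrite(states_table(ts), file.path(directory, "states.csv"))
  fwrite(labels_table(ts), file.path(directory, "labels.csv"))
  schema <- list(feature_names = ts$feature_names,
                 input_names = state_input_names(ts),
                 bin_hours = ts$config$bin_hours,
                 cutoff_hours = ts$cutoff,
                 medians = as.list(ts$medians))
  writeLines(jsonlite::toJSON(schema, auto_unbox = TRUE, digits = 12, pretty = TRUE),
             file.path(directory, "schema.json"))
  invisible(directory)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(directory) {
  states <- fread(file.path(directory, "states.csv"),
                  colClasses = list(character = "patient_id"))
  labels <- fread(file.path(directory, "labels.csv"),
                  colClasses = list(character = "patient_id"))
  schema <- jsonlite::fromJSON(file.path(directory, "schema.json"))
  trajs <- lapply(split(seq_len(nrow(states)), states$patient_id), function(ix) {
    st <- states[ix][order(bin_index)]
    lb <- labels[labels$patient_id == st$patient_id[1]][order(bin_index)]
    fn <- schema$feature_names
    imp <- as.matrix(st[, paste0("imp_", fn), with = FALSE])
    colnames(imp) <- fn
    structure(list(
      patient_id = st$patient_id[1],
      bin_index = st$bin_index,
      features = as.matrix(st[, fn, with = FALSE]),
      imputed = imp,
      actions = st[, c("fluid_ml", "vaso_active", "diuretic_given"), with = FALSE],
      labels = lb[, c("vaso_at_12h", "died_in_admission"), with = FALSE],
      truncated_at_cmo = NA, truncated_at_percentile = NA,
      feature_names = fn), class = "trajectory")
  })
  structure(list(trajectories = trajs[order(names(trajs))],
                 cutoff = schema$cutoff_hours,
                 medians = unlist(schema$medians),
                 feature_names = schema$feature_names,
                 config = cohort_config(bin_hours = schema$bin_hours)),
            class = "trajectory_set")
}

#' Per-feature cohort statistics for z-scoring
#'
#' Mean and standard deviation of every state-vector input (features plus
#' in-bin actions), computed over the states of the given patients — by
#' convention the training split only.
#'
#' @param ts a `trajectory_set`
#' @param patient_ids patients to include (default: all)
#' @return an object of class `cohort_stats` with `mean` and `sd` named
#'   vectors; zero-variance inputs keep `sd = 0` and are flagged in
#'   `zero_sd`
#' @export
cohort_stats <- function(ts, patient_ids = NULL) {
  st <- states_table(ts)
  if (!is.null(patient_ids)) st <- st[st$patient_id %in% patient_ids]
  if (!nrow(st)) domain_error("no states selected for cohort statistics")
  cols <- state_input_names(ts)
  x <- as.matrix(st[, cols, with = FALSE]) * 1.0
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[is.na(sd_)] <- 0
  structure(list(mean = mu, sd = sd_, zero_sd = names(mu)[sd_ == 0],
                 input_names = cols, feature_names = ts$feature_names,
                 n_states = nrow(st)),
            class = "cohort_stats")
}
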