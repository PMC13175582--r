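# Fixture builders shared across the suite. Everything is generated in code;
# expensive shared objects (a small simulated cohort and its engine) are
# built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

empty_events <- function() data.table::data.table(
  time_hours = numeric(0), feature_name = character(0), value = numeric(0))
empty_treatments <- function() data.table::data.table(
  time_hours = numeric(0), treatment = character(0), amount = numeric(0))

events_of <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(time_hours = r[[1]], feature_name = r[[2]],
                           value = r[[3]])))
}

treatments_of <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(time_hours = r[[1]], treatment = r[[2]],
                           amount = r[[3]])))
}

make_record <- function(patient_id = "X1", stay = 48, abx = 1, cult = 2,
                        death = FALSE, death_time = NA_real_, cmo = NA_real_,
                        events = NULL, treatments = NULL,
                        demo = c(age = 60, sex = 1, dx_chf = 0, dx_ckd = 0)) {
  tr <- treatments %||% empty_treatments()
  # suspicion/CMO markers live in the treatments file of the CSV schema
  extra <- data.table::rbindlist(c(
    lapply(abx, function(t) data.table::data.table(
      time_hours = t, treatment = "antibiotic", amount = 1)),
    lapply(cult, function(t) data.table::data.table(
      time_hours = t, treatment = "culture", amount = 1)),
    if (!is.na(cmo)) list(data.table::data.table(
      time_hours = cmo, treatment = "cmo", amount = 1))))
  tr <- data.table::rbindlist(list(tr, extra))
  data.table::setorder(tr, time_hours, treatment)
  patient_record(patient_id, demo, 0, stay, death, death_time,
                 events = events %||% empty_events(),
                 treatments = tr,
                 cmo_time = cmo, antibiotic_times = abx,
                 culture_times = cult)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A hand-built trajectory whose observed plan at bin 0 is (vol, prs) under
# the default 3-bin window, with explicit outcome labels at bin 0.
make_traj <- function(pid, vol = "none", prs = "maintain", died = FALSE,
                      vaso12 = NA, n_bins = 4L,
                      features = NULL, imputed = NULL,
                      feature_names = c("age", "sex", "hr")) {
  fluid <- rep(0, n_bins); diur <- rep(FALSE, n_bins); va <- rep(FALSE, n_bins)
  if (vol == "give_fluids") fluid[2] <- 500
  if (vol == "give_diuretics") diur[2] <- TRUE
  if (prs == "increase_or_start") va[min(4, n_bins)] <- TRUE
  if (prs == "decrease_or_stop") va[1] <- TRUE
  if (is.null(features)) {
    features <- matrix(0, n_bins, length(feature_names),
                       dimnames = list(NULL, feature_names))
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(features), ncol(features),
                      dimnames = dimnames(features))
  }
  structure(list(
    patient_id = pid,
    bin_index = seq_len(n_bins) - 1L,
    features = features,
    imputed = imputed,
    actions = data.table::data.table(fluid_ml = fluid, vaso_active = va,
                                     diuretic_given = diur),
    labels = data.table::data.table(
      vaso_at_12h = c(vaso12, rep(NA, n_bins - 1)),
      died_in_admission = rep(died, n_bins)),
    truncated_at_cmo = FALSE, truncated_at_percentile = FALSE,
    feature_names = colnames(features)), class = "trajectory")
}

# A neighbor pool: one single-state-queried trajectory per neighbor, each
# realizing the requested observed plan and labels at bin 0.
make_neighbor_fixture <- function(vol, prs, died = rep(FALSE, length(vol)),
                                  vaso12 = rep(NA, length(vol))) {
  n <- length(vol)
  trajs <- lapply(seq_len(n), function(i)
    make_traj(sprintf("N%04d", i), vol[i], prs[i], died = died[i],
              vaso12 = vaso12[i]))
  names(trajs) <- vapply(trajs, `[[`, character(1), "patient_id")
  ns <- structure(list(
    query = list(patient_id = "QUERY", bin_index = 0L),
    neighbors = data.table::data.table(
      patient_id = names(trajs), bin_index = 0L,
      distance = seq_len(n) * 1e-3),
    k_actual = n, metric = "euclidean"), class = "neighbor_set")
  list(trajs = trajs, neighbors = ns)
}

# small shared cohort + engine, simulated once per run
demo_pipeline <- function() {
  if (!is.null(fixture_cache$demo)) return(fixture_cache$demo)
  sim <- simulate_cohort(sim_config(n_patients = 40, mean_stay_hours = 48,
                                    seed = 42))
  ts <- build_trajectories(sim$records)
  split <- split_cohort(ts)
  stats <- cohort_stats(ts, split$train)
  emb <- embed_cohort(ts, stats = stats)
  engine <- cue_engine(ts, stats, emb, eval_ids = split$eval)
  demo <- list(sim = sim, ts = ts, split = split, stats = stats,
               emb = emb, engine = engine)
  fixture_cache$demo <- demo
  demo
}

# a query state of the demo engine with a full 100-neighbor pool
demo_query <- function() {
  d <- demo_pipeline()
  ev <- d$emb[d$emb$patient_id %in% d$split$eval]
  ev[which.max(ev$bin_index == 0)]
}

# independent brute-force k-NN used as the retrieval oracle
brute_force_knn <- function(E, ids, bins, q, k, exclude_pid = NULL) {
  d <- apply(E, 1, function(r) sqrt(sum((r - q)^2)))
  keep <- if (is.null(exclude_pid)) rep(TRUE, nrow(E)) else ids != exclude_pid
  ord <- order(d, ids, bins)
  ord <- ord[keep[ord]]
  ord[seq_len(min(k, length(ord)))]
}

# independent two-sided Fisher p-value by full enumeration of the
# hypergeometric distribution (sum of all tables no more probable than the
# observed one, with the standard floating-point guard)
enum_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- function(x) lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  pobs <- exp(logp(a))
  sum(probs[probs <= pobs * (1 + 1e-7)])
}
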