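# The eight intelligent reasoning cues computed from a query state and its
# nearest-neighbor pool:
#   R1/R2 consistent / unusual case features
#   R3    neighbor risk score (low / moderate / high)
#   R4    plan-conditional risk difference (two-sided Fisher exact test)
#   R5    peer action frequencies (with the 10-of-100 support gate)
#   R6    consensus peer action (strictly more than 60% of neighbors)
#   R7    plan mention (emitted by the interface layer)
#   R8    recommended plan, by peer actions or by risk scores

#' Cue configuration
#'
#' @param max_features maximum entries in the R1/R2 feature cues
#' @param consensus_threshold consensus requires the modal action in strictly
#'   more than this fraction of neighbors (default 0.60)
#' @param min_support minimum neighbors on a plan before its conditional
#'   risk or a recommendation is shown (default 10)
#' @param alpha significance level of the plan-conditional risk test
#' @param risk_band_edges boundaries of the low / moderate / high risk bands
#' @param plan_window_bins bins after the current one over which a
#'   neighbor's observed plan is read (default 3, i.e. 12 hours)
#' @return an object of class `cue_config`
#' @export
cue_config <- function(max_features = 3L, consensus_threshold = 0.60,
                       min_support = 10L, alpha = 0.05,
                       risk_band_edges = c(1 / 3, 2 / 3),
                       plan_window_bins = 3L) {
  cfg <- structure(list(max_features = as.integer(max_features),
                        consensus_threshold = consensus_threshold,
                        min_support = as.integer(min_support),
                        alpha = alpha,
                        risk_band_edges = risk_band_edges,
                        plan_window_bins = as.integer(plan_window_bins)),
                   class = "cue_config")
  if (!is_num1(cfg$consensus_threshold) || cfg$consensus_threshold <= 0 ||
      cfg$consensus_threshold >= 1)
    config_error("invalid configuration field 'consensus_threshold': must be in (0, 1)")
  if (!is_num1(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    config_error("invalid configuration field 'alpha': must be in (0, 1)")
  if (length(cfg$risk_band_edges) != 2 ||
      !(cfg$risk_band_edges[1] < cfg$risk_band_edges[2]) ||
      cfg$risk_band_edges[1] <= 0 || cfg$risk_band_edges[2] >= 1)
    config_error("invalid configuration field 'risk_band_edges': need two increasing values in (0, 1)")
  if (!is_count(cfg$min_support) || !is_count(cfg$max_features) ||
      !is_count(cfg$plan_window_bins))
    config_error("invalid configuration field: max_features, min_support and plan_window_bins must be positive integers")
  cfg
}

outcome_kinds <- function() c("vasopressor_at_12h", "mortality_in_admission")

resolve_trajs <- function(trajectories) {
  if (inherits(trajectories, "trajectory_set")) trajectories$trajectories
  else trajectories
}

get_trajectory <- function(trajectories, patient_id) {
  trajs <- resolve_trajs(trajectories)
  tr <- trajs[[patient_id]]
  if (is.null(tr)) domain_error("no trajectory for patient %s", patient_id)
  tr
}

#' Look up one state of a trajectory set
#'
#' @param trajectories a `trajectory_set` or named list of `trajectory`
#' @param patient_id patient identifier
#' @param bin_index bin index of the state
#' @return list with `features`, `imputed` (named vectors), `actions`,
#'   `labels` for that state
#' @export
get_state <- function(trajectories, patient_id, bin_index) {
  tr <- get_trajectory(trajectories, patient_id)
  i <- match(bin_index, tr$bin_index)
  if (is.na(i))
    domain_error("patient %s has no state at bin %d", patient_id, bin_index)
  list(patient_id = patient_id, bin_index = bin_index,
       features = tr$features[i, ], imputed = tr$imputed[i, ],
       actions = as.list(tr$actions[i]), labels = as.list(tr$labels[i]))
}

# --- observed plans ---------------------------------------------------------

#' Discretize a neighbor's observed treatment plan
#'
#' The volume action is read from fluid/diuretic activity over the
#' `plan_window_bins` bins after `bin_index`: any fluid and no diuretic is
#' `give_fluids`, any diuretic is `give_diuretics`, neither is `none`
#' (simultaneous fluid and diuretic counts as `give_fluids`). The pressor
#' action compares vasopressor activity at the window end against the
#' current bin: off-to-on is `increase_or_start`, on-to-off is
#' `decrease_or_stop`, otherwise `maintain`. A window reaching past the end
#' of the trajectory is computed on the available bins and flagged
#' `partial`.
#'
#' @param traj a `trajectory`
#' @param bin_index the decision bin
#' @param config a [cue_config()]
#' @return a `treatment_plan` with attribute `partial`
#' @export
observed_plan <- function(traj, bin_index, config = cue_config()) {
  i <- match(bin_index, traj$bin_index)
  if (is.na(i))
    domain_error("trajectory %s has no bin %d", traj$patient_id, bin_index)
  n <- length(traj$bin_index)
  W <- config$plan_window_bins
  win <- (i + 1):(i + W)
  partial <- (i + W) > n
  win <- win[win <= n]
  any_fluid <- length(win) > 0 && any(traj$actions$fluid_ml[win] > 0)
  any_diur <- length(win) > 0 && any(traj$actions$diuretic_given[win])
  vol <- if (any_fluid) "give_fluids"
         else if (any_diur) "give_diuretics"
         else "none"
  end_i <- if (length(win)) max(win) else i
  now_on <- isTRUE(traj$actions$vaso_active[i])
  end_on <- isTRUE(traj$actions$vaso_active[end_i])
  prs <- if (!now_on && end_on) "increase_or_start"
         else if (now_on && !end_on) "decrease_or_stop"
         else "maintain"
  plan <- treatment_plan(vol, prs)
  attr(plan, "partial") <- partial
  attr(plan, "simultaneous_volume") <- any_fluid && any_diur
  plan
}

#' Observed plans of every state in a trajectory set
#'
#' Applies [observed_plan()] to every state; used to tally peer actions and
#' (via `plans_cache`, attached by [cue_engine()]) to avoid recomputing
#' window plans per query.
#'
#' @param ts a `trajectory_set` or named list of `trajectory`
#' @param config a [cue_config()]
#' @return data.table `(patient_id, bin_index, volume_action,
#'   pressor_action, partial)`
#' @export
observed_plans_table <- function(ts, config = cue_config()) {
  trajs <- resolve_trajs(ts)
  W <- config$plan_window_bins
  out <- rbindlist(lapply(trajs, function(tr) {
    n <- length(tr$bin_index)
    fl <- tr$actions$fluid_ml > 0
    di <- tr$actions$diuretic_given
    va <- tr$actions$vaso_active
    vol <- character(n); prs <- character(n); partial <- logical(n)
    for (i in seq_len(n)) {
      win <- if (i < n) (i + 1):min(i + W, n) else integer(0)
      anyf <- any(fl[win]); anyd <- any(di[win])
      vol[i] <- if (anyf) "give_fluids" else if (anyd) "give_diuretics" else "none"
      endi <- if (length(win)) max(win) else i
      prs[i] <- if (!va[i] && va[endi]) "increase_or_start"
                else if (va[i] && !va[endi]) "decrease_or_stop"
                else "maintain"
      partial[i] <- (i + W) > n
    }
    data.table(patient_id = tr$patient_id, bin_index = tr$bin_index,
               volume_action = vol, pressor_action = prs, partial = partial)
  }))
  data.table::setkeyv(out, c("patient_id", "bin_index"))
  out
}

# observed plans of every neighbor, as a data.table (in neighbor order)
neighbor_plans <- function(neighbors, trajectories, config = cue_config()) {
  cache <- if (is.list(trajectories)) trajectories$plans_cache else NULL
  if (!is.null(cache) && cache$window == config$plan_window_bins) {
    tab <- cache$table[data.table(patient_id = neighbors$neighbors$patient_id,
                                  bin_index = neighbors$neighbors$bin_index)]
    return(tab)
  }
  trajs <- resolve_trajs(trajectories)
  rbindlist(lapply(seq_len(nrow(neighbors$neighbors)), function(j) {
    nb <- neighbors$neighbors[j]
    pl <- observed_plan(trajs[[nb$patient_id]], nb$bin_index, config)
    data.table(patient_id = nb$patient_id, bin_index = nb$bin_index,
               volume_action = pl$volume_action,
               pressor_action = pl$pressor_action,
               partial = attr(pl, "partial"))
  }))
}

neighbor_labels <- function(neighbors, outcome_kind, trajectories) {
  outcome_kind <- match.arg(outcome_kind, outcome_kinds())
  col <- if (outcome_kind == "vasopressor_at_12h") "vaso_at_12h"
         else "died_in_admission"
  cache <- if (is.list(trajectories)) trajectories$labels_cache else NULL
  if (!is.null(cache)) {
    tab <- cache[data.table(patient_id = neighbors$neighbors$patient_id,
                            bin_index = neighbors$neighbors$bin_index)]
    return(as.logical(tab[[col]]))
  }
  trajs <- resolve_trajs(trajectories)
  vapply(seq_len(nrow(neighbors$neighbors)), function(j) {
    nb <- neighbors$neighbors[j]
    tr <- trajs[[nb$patient_id]]
    i <- match(nb$bin_index, tr$bin_index)
    v <- tr$labels[[col]][i]
    if (is.na(v)) NA else as.logical(v)
  }, logical(1))
}

#' Attach plan/label lookup caches to a trajectory set
#'
#' Precomputes the observed-plan table and the keyed label table so cue
#' computation over many queries avoids per-neighbor lookups. Used by
#' [cue_engine()]; harmless (and helpful) for direct cue calls too.
#'
#' @param ts a `trajectory_set`
#' @param config a [cue_config()]
#' @return the `trajectory_set` with `plans_cache` and `labels_cache`
#' @export
cache_cue_lookups <- function(ts, config = cue_config()) {
  ts$plans_cache <- list(window = config$plan_window_bins,
                         table = observed_plans_table(ts, config))
  lt <- labels_table(ts)
  data.table::setkeyv(lt, c("patient_id", "bin_index"))
  ts$labels_cache <- lt
  ts
}

# --- R1 / R2: case features -------------------------------------------------

#' Per-feature discrepancy between a query state and its neighbors
#'
#' For each measured feature `f`, the discrepancy is
#' `d_f = |z(query_f) - mean z(neighbors_f)|` with z-scores from the cohort
#' training statistics; the neighbor dispersion `s_f` is the SD of the
#' neighbors' z-values. Zero-variance cohort features are excluded.
#'
#' @param query a state from [get_state()]
#' @param neighbors a `neighbor_set`
#' @param trajectories a `trajectory_set` or named list of `trajectory`
#' @param cohort_stats training-split [cohort_stats()]
#' @param features which features to score (default: all measured,
#'   non-demographic features)
#' @return data.table `(feature, query_z, neighbor_mean_z, dispersion,
#'   discrepancy, query_imputed, all_neighbors_imputed)`
#' @export
feature_discrepancy <- function(query, neighbors, trajectories, cohort_stats,
                                features = NULL) {
  if (!nrow(neighbors$neighbors)) domain_error("empty neighbor set")
  trajs <- resolve_trajs(trajectories)
  if (is.null(features))
    features <- setdiff(cohort_stats$feature_names, demographic_features())
  features <- setdiff(features, cohort_stats$zero_sd)
  if (!length(features)) return(data.table(feature = character(0)))
  mu <- cohort_stats$mean[features]
  sd_ <- cohort_stats$sd[features]
  nb <- neighbors$neighbors
  Z <- matrix(NA_real_, nrow(nb), length(features))
  Imp <- matrix(NA, nrow(nb), length(features))
  for (j in seq_len(nrow(nb))) {
    tr <- trajs[[nb$patient_id[j]]]
    i <- match(nb$bin_index[j], tr$bin_index)
    Z[j, ] <- (tr$features[i, features] - mu) / sd_
    Imp[j, ] <- tr$imputed[i, features]
  }
  qz <- (query$features[features] - mu) / sd_
  data.table(feature = features,
             query_z = unname(qz),
             neighbor_mean_z = colMeans(Z),
             dispersion = apply(Z, 2, stats::sd),
             discrepancy = abs(unname(qz) - colMeans(Z)),
             query_imputed = unname(query$imputed[features]),
             all_neighbors_imputed = apply(Imp, 2, all))
}

feature_cue <- function(kind, entries, max_features) {
  structure(list(kind = kind,
                 entries = utils::head(entries, max_features)),
            class = "feature_cue")
}

#' Most consistent / most unusual features of a case (R1 / R2)
#'
#' R1 selects up to `max_features` features with the smallest discrepancy
#' among features whose neighbor dispersion is below the median dispersion
#' (agreement *and* tightness); R2 selects the largest discrepancies. Both
#' skip features whose query value is imputed or that are imputed in every
#' neighbor, and break ties by feature name.
#'
#' @inheritParams feature_discrepancy
#' @param config a [cue_config()]
#' @return an object of class `feature_cue` (possibly with zero entries)
#' @export
consistent_features <- function(query, neighbors, trajectories, cohort_stats,
                                config = cue_config()) {
  d <- feature_discrepancy(query, neighbors, trajectories, cohort_stats)
  d <- d[!d$query_imputed & !d$all_neighbors_imputed]
  if (!nrow(d)) return(feature_cue("consistent", d, config$max_features))
  tight <- d[d$dispersion < stats::median(d$dispersion)]
  setorder(tight, discrepancy, feature)
  feature_cue("consistent", tight, config$max_features)
}

#' @rdname consistent_features
#' @export
unusual_features <- function(query, neighbors, trajectories, cohort_stats,
                             config = cue_config()) {
  d <- feature_discrepancy(query, neighbors, trajectories, cohort_stats)
  d <- d[!d$query_imputed & !d$all_neighbors_imputed]
  if (nrow(d)) d <- d[order(-d$discrepancy, d$feature)]
  feature_cue("unusual", d, config$max_features)
}

# --- R3: neighbor risk score ------------------------------------------------

#' Neighbor-based risk score (R3)
#'
#' The probability of the outcome among the neighbors with a defined label:
#' `positives / n_defined`. The level is `low` below the lower band edge,
#' `high` above the upper edge, otherwise `moderate`.
#'
#' @param neighbors a `neighbor_set`
#' @param outcome_kind `"vasopressor_at_12h"` or `"mortality_in_admission"`
#' @param trajectories a `trajectory_set` or named list of `trajectory`
#' @param config a [cue_config()]
#' @return an object of class `risk_cue`
#' @export
risk_score <- function(neighbors, outcome_kind, trajectories,
                       config = cue_config()) {
  lab <- neighbor_labels(neighbors, outcome_kind, trajectories)
  n_def <- sum(!is.na(lab))
  if (n_def == 0)
    domain_error("risk undefined: no neighbor has a defined %s label", outcome_kind)
  p <- sum(lab, na.rm = TRUE) / n_def
  e <- config$risk_band_edges
  level <- if (p < e[1]) "low" else if (p > e[2]) "high" else "moderate"
  structure(list(outcome_kind = match.arg(outcome_kind, outcome_kinds()),
                 probability = p, n_defined = n_def,
                 n_positive = sum(lab, na.rm = TRUE), level = level),
            class = "risk_cue")
}

# --- R4: plan-conditional risk difference -----------------------------------

# Core computation on an explicit partition; exercised directly by the
# partition-swap property.
plan_risk_from_partition <- function(is_plan, labels, config) {
  n_plan <- sum(is_plan)
  n_rest <- sum(!is_plan)
  def <- !is.na(labels)
  pos_plan <- sum(labels[is_plan & def])
  def_plan <- sum(is_plan & def)
  pos_rest <- sum(labels[!is_plan & def])
  def_rest <- sum(!is_plan & def)
  risk_plan <- if (def_plan > 0) pos_plan / def_plan else NA_real_
  risk_rest <- if (def_rest > 0) pos_rest / def_rest else NA_real_
  p_value <- NA_real_
  if (def_plan > 0 && def_rest > 0) {
    tab <- matrix(c(pos_plan, def_plan - pos_plan,
                    pos_rest, def_rest - pos_rest), 2, byrow = TRUE)
    p_value <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  sufficient <- n_plan >= config$min_support
  significant <- sufficient && !is.na(p_value) && p_value < config$alpha
  if (!sufficient) {
    # below the support gate neither the conditional risk nor the test is shown
    risk_plan <- NA_real_
    p_value <- NA_real_
  }
  list(risk_plan = risk_plan, risk_rest = risk_rest,
       n_plan = n_plan, n_rest = n_rest,
       n_plan_defined = def_plan, n_rest_defined = def_rest,
       p_value = p_value, significant = significant,
       sufficient_support = sufficient)
}

#' Plan-conditional risk difference (R4)
#'
#' Partitions the neighbors into those whose observed plan equals `plan`
#' and the rest, computes the outcome risk in each partition, and tests the
#' 2x2 outcome table with a two-sided Fisher exact test. A plan taken by
#' fewer than `min_support` neighbors fails the support gate: its
#' conditional risk and p-value are reported undefined and the difference
#' can never be flagged significant.
#'
#' @inheritParams risk_score
#' @param plan a [treatment_plan()]
#' @return an object of class `plan_risk` (fields `plan`, `risk_plan`,
#'   `risk_rest`, `n_plan`, `n_rest`, `p_value`, `significant`,
#'   `sufficient_support`)
#' @export
plan_conditional_risk <- function(neighbors, plan, outcome_kind, trajectories,
                                  config = cue_config()) {
  if (!nrow(neighbors$neighbors)) domain_error("empty neighbor set")
  plans <- neighbor_plans(neighbors, trajectories, config)
  is_plan <- plans$volume_action == plan$volume_action &
    plans$pressor_action == plan$pressor_action
  labels <- neighbor_labels(neighbors, outcome_kind, trajectories)
  out <- plan_risk_from_partition(is_plan, labels, config)
  out$plan <- plan
  out$outcome_kind <- match.arg(outcome_kind, outcome_kinds())
  class(out) <- "plan_risk"
  out
}

# --- R5 / R6: peer actions --------------------------------------------------

#' Peer action frequencies within one category (R5)
#'
#' Counts each action of the category (`volume` or `pressor`) over the
#' neighbors' observed plans; frequencies are counts divided by `k_actual`.
#'
#' @inheritParams risk_score
#' @param category `"volume"` or `"pressor"`
#' @return an object of class `action_frequency`
#' @export
action_frequencies <- function(neighbors, category, trajectories,
                               config = cue_config()) {
  category <- match.arg(category, c("volume", "pressor"))
  if (!nrow(neighbors$neighbors)) domain_error("empty neighbor set")
  plans <- neighbor_plans(neighbors, trajectories, config)
  acts <- if (category == "volume") volume_actions() else pressor_actions()
  col <- if (category == "volume") "volume_action" else "pressor_action"
  counts <- vapply(acts, function(a) sum(plans[[col]] == a), integer(1))
  structure(list(category = category, counts = counts,
                 frequencies = counts / neighbors$k_actual,
                 k_actual = neighbors$k_actual),
            class = "action_frequency")
}

#' Consensus peer action (R6)
#'
#' The modal action of a category reaches consensus only when its frequency
#' strictly exceeds `consensus_threshold`; a tie for the mode never does
#' (no single plan is consistently taken).
#'
#' @param freq an [action_frequencies()] result
#' @param config a [cue_config()]
#' @return an object of class `consensus_action`
#' @export
consensus <- function(freq, config = cue_config()) {
  f <- freq$frequencies
  top <- max(f)
  modal <- sort(names(f)[f == top])
  tie <- length(modal) > 1
  structure(list(category = freq$category,
                 modal_action = modal[1],
                 modal_frequency = unname(top),
                 tie = tie,
                 consensus = !tie && top > config$consensus_threshold),
            class = "consensus_action")
}

# --- R8: recommendation -----------------------------------------------------

#' Recommended plan (R8)
#'
#' `mode = "by_peer"` composes the modal action of each category (the
#' actions most commonly taken by peers; ties broken alphabetically).
#' `mode = "by_risk"` returns the plan whose conditional risk is
#' significantly different and lowest among sufficiently supported plans
#' with risk below the rest; absent when no plan qualifies.
#'
#' @inheritParams risk_score
#' @param mode `"by_peer"` or `"by_risk"`
#' @return an object of class `recommendation`; `plan` is `NULL` when no
#'   plan qualifies
#' @export
recommend <- function(neighbors, mode, outcome_kind = "mortality_in_admission",
                      trajectories = NULL, config = cue_config()) {
  mode <- match.arg(mode, c("by_peer", "by_risk"))
  if (mode == "by_peer") {
    fv <- action_frequencies(neighbors, "volume", trajectories, config)
    fp <- action_frequencies(neighbors, "pressor", trajectories, config)
    cv <- consensus(fv, config)
    cp <- consensus(fp, config)
    plan <- treatment_plan(cv$modal_action, cp$modal_action)
    return(structure(list(mode = mode, plan = plan,
                          basis = list(volume = cv, pressor = cp)),
                     class = "recommendation"))
  }
  g <- plan_grid()
  cands <- list()
  for (i in seq_len(nrow(g))) {
    pl <- treatment_plan(g$volume_action[i], g$pressor_action[i])
    pr <- plan_conditional_risk(neighbors, pl, outcome_kind, trajectories,
                                config)
    if (pr$sufficient_support && pr$significant &&
        !is.na(pr$risk_plan) && !is.na(pr$risk_rest) &&
        pr$risk_plan < pr$risk_rest)
      cands[[length(cands) + 1]] <- pr
  }
  if (!length(cands))
    return(structure(list(mode = mode, plan = NULL, basis = NULL),
                     class = "recommendation"))
  risks <- vapply(cands, `[[`, numeric(1), "risk_plan")
  keys <- vapply(cands, function(x) plan_key(x$plan), character(1))
  best <- order(risks, keys)[1]
  structure(list(mode = mode, plan = cands[[best]]$plan,
                 basis = cands[[best]]),
            class = "recommendation")
}

# --- JSON serialization -----------------------------------------------------

CUE_SCHEMA_VERSION <- "1"

cue_envelope <- function(cue_code, payload) {
  list(cue_code = cue_code, version = CUE_SCHEMA_VERSION,
       inputs_digest = fnv1a_hex(payload), payload = payload)
}

#' Serialize a cue to its versioned JSON object
#'
#' Every cue becomes a list with `cue_code` (`R1`..`R8`, including the
#' suffixed variants `R3-L/M/H`, `R4-Y/N`, `R5-Y/N`, `R6-Y/N`), a schema
#' `version`, an `inputs_digest` and the cue `payload`.
#'
#' @param x a cue object
#' @param ... unused, or `focal_count` for `action_frequency` (attaches the
#'   R5-Y/N support suffix for a focal plan)
#' @return a list ready for [jsonlite::toJSON()]
#' @export
cue_json <- function(x, ...) UseMethod("cue_json")

#' @export
cue_json.feature_cue <- function(x, ...) {
  code <- if (x$kind == "consistent") "R1" else "R2"
  cue_envelope(code, list(kind = x$kind, entries = x$entries))
}

#' @export
cue_json.risk_cue <- function(x, ...) {
  suffix <- c(low = "L", moderate = "M", high = "H")[x$level]
  cue_envelope(paste0("R3-", suffix),
               list(outcome_kind = x$outcome_kind,
                    probability = x$probability, n_defined = x$n_defined,
                    level = x$level))
}

#' @export
cue_json.plan_risk <- function(x, ...) {
  cue_envelope(paste0("R4-", if (x$significant) "Y" else "N"),
               list(plan = unclass(x$plan), outcome_kind = x$outcome_kind,
                    risk_plan = x$risk_plan, risk_rest = x$risk_rest,
                    n_plan = x$n_plan, n_rest = x$n_rest,
                    p_value = x$p_value, significant = x$significant,
                    sufficient_support = x$sufficient_support))
}

#' @export
cue_json.action_frequency <- function(x, ..., focal_count = NULL,
                                      min_support = NULL) {
  code <- "R5"
  if (!is.null(focal_count) && !is.null(min_support))
    code <- paste0("R5-", if (focal_count >= min_support) "Y" else "N")
  cue_envelope(code, list(category = x$category,
                          counts = as.list(x$counts),
                          frequencies = as.list(x$frequencies),
                          k_actual = x$k_actual))
}

#' @export
cue_json.consensus_action <- function(x, ...) {
  cue_envelope(paste0("R6-", if (x$consensus) "Y" else "N"),
               list(category = x$category, modal_action = x$modal_action,
                    modal_frequency = x$modal_frequency, tie = x$tie,
                    consensus = x$consensus))
}

#' @export
cue_json.recommendation <- function(x, ...) {
  cue_envelope("R8", list(mode = x$mode,
                          plan = if (is.null(x$plan)) NULL else unclass(x$plan),
                          has_plan = !is.null(x$plan)))
}

plan_mention_json <- function(plan) {
  cue_envelope("R7", list(plan = if (is.null(plan)) NULL else unclass(plan)))
}
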