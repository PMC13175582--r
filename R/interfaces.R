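# Assembly of the seven decision-support interface payloads from cues.
#
# Interface -> cue composition:
#   case_features                {R1, R2}
#   treatment_risk               {R3}   (vasopressor use at +12 h)
#   mortality_risk               {R3}   (death within the admission)
#   interactive_treatment_risk   {R7, R3, R4, R5} (+R8 when inferable)
#   interactive_mortality_risk   {R7, R3, R4, R5} (+R8 when inferable)
#   prior_clinician_actions      {R7, R5, R6} (+implicit R8, outcome-free)
#   treatment_recommendation     {R7, R8}

#' @rdname build_payload
#' @export
interface_names <- function() {
  c("case_features", "treatment_risk", "mortality_risk",
    "interactive_treatment_risk", "interactive_mortality_risk",
    "prior_clinician_actions", "treatment_recommendation")
}

#' @rdname build_payload
#' @return `interface_cue_map()`: per interface, the `required` cue codes
#'   every payload must contain and the `optional` codes it may contain.
#' @export
interface_cue_map <- function() {
  list(
    case_features = list(required = c("R1", "R2"), optional = character(0)),
    treatment_risk = list(required = "R3", optional = character(0)),
    mortality_risk = list(required = "R3", optional = character(0)),
    interactive_treatment_risk = list(required = c("R7", "R3", "R4", "R5"),
                                      optional = "R8"),
    interactive_mortality_risk = list(required = c("R7", "R3", "R4", "R5"),
                                      optional = "R8"),
    prior_clinician_actions = list(required = c("R7", "R5", "R6"),
                                   optional = character(0)),
    treatment_recommendation = list(required = c("R7", "R8"),
                                    optional = character(0)))
}

#' Bundle the fitted pipeline into a cue engine
#'
#' Holds everything the interface layer needs: trajectories (with labels),
#' the embedding table and its exact-retrieval index, training-split
#' statistics, and the cue/neighbor configurations.
#'
#' @param ts a `trajectory_set` (the full cohort, so neighbor states can be
#'   drawn from the training split)
#' @param stats training-split [cohort_stats()]
#' @param embeddings cohort embedding table ([embed_cohort()])
#' @param cue_cfg a [cue_config()]
#' @param nq_cfg a [neighbor_query_config()]
#' @param eval_ids patient ids allowed as query states (default: all)
#' @return an object of class `cue_engine`
#' @export
cue_engine <- function(ts, stats, embeddings, cue_cfg = cue_config(),
                       nq_cfg = neighbor_query_config(), eval_ids = NULL) {
  if (inherits(ts, "trajectory_set")) ts <- cache_cue_lookups(ts, cue_cfg)
  structure(list(ts = ts, stats = stats, embeddings = as.data.table(embeddings),
                 index = build_index(embeddings), cue_cfg = cue_cfg,
                 nq_cfg = nq_cfg, eval_ids = eval_ids),
            class = "cue_engine")
}

#' @export
format.cue_engine <- function(x, ...) {
  sprintf("<cue_engine: %d states indexed (%s), k=%d>",
          nrow(x$embeddings), x$index$source, x$nq_cfg$k)
}

#' @export
print.cue_engine <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

engine_query <- function(engine, patient_id, bin_index) {
  if (!is.null(engine$eval_ids) && !(patient_id %in% engine$eval_ids))
    usage_error("patient %s is not in the evaluation split", patient_id)
  # compute the row selection outside `[` so the bare argument names cannot
  # be captured by the table's identically named columns
  sel <- which(engine$embeddings$patient_id == patient_id &
                 engine$embeddings$bin_index == bin_index)
  row <- engine$embeddings[sel]
  if (!nrow(row))
    usage_error("no embedded state for patient %s at bin %s", patient_id,
                bin_index)
  row[1]
}

conditional_risk_json <- function(pr, edges) {
  # conditional R3: suffix only when the conditional risk is defined
  if (is.na(pr$risk_plan)) {
    cue_envelope("R3", list(outcome_kind = pr$outcome_kind,
                            conditional_on = unclass(pr$plan),
                            probability = NULL, n_defined = pr$n_plan_defined,
                            level = NULL))
  } else {
    level <- if (pr$risk_plan < edges[1]) "low"
             else if (pr$risk_plan > edges[2]) "high" else "moderate"
    cue_envelope(paste0("R3-", c(low = "L", moderate = "M", high = "H")[level]),
                 list(outcome_kind = pr$outcome_kind,
                      conditional_on = unclass(pr$plan),
                      probability = pr$risk_plan,
                      n_defined = pr$n_plan_defined, level = level))
  }
}

#' Build one interface payload
#'
#' Computes the query state's neighbor set and assembles exactly the cue
#' set mapped to `interface_name`. Interactive interfaces require a
#' `selected_plan` and mark `no_recommendation` when the plan fails the
#' support gate; `prior_clinician_actions` contains no outcome-derived
#' numbers.
#'
#' @param engine a [cue_engine()]
#' @param interface_name one of [interface_names()]
#' @param patient_id,bin_index the query state
#' @param selected_plan a [treatment_plan()] (interactive interfaces only)
#' @return an object of class `interface_payload`
#' @export
build_payload <- function(engine, interface_name, patient_id, bin_index,
                          selected_plan = NULL) {
  if (!interface_name %in% interface_names())
    usage_error("unknown interface name '%s'", interface_name)
  interactive <- interface_name %in% c("interactive_treatment_risk",
                                       "interactive_mortality_risk")
  if (interactive && is.null(selected_plan))
    usage_error("interface '%s' requires a selected treatment plan",
                interface_name)
  query <- engine_query(engine, patient_id, bin_index)
  nbs <- nearest_states(engine$index, query, engine$nq_cfg)
  cfg <- engine$cue_cfg
  ts <- engine$ts
  outcome <- if (grepl("treatment", interface_name)) "vasopressor_at_12h"
             else "mortality_in_admission"
  cues <- list()
  extra <- list()

  if (interface_name == "case_features") {
    qs <- get_state(ts, patient_id, bin_index)
    cues <- list(
      cue_json(consistent_features(qs, nbs, ts, engine$stats, cfg)),
      cue_json(unusual_features(qs, nbs, ts, engine$stats, cfg)))
  } else if (interface_name %in% c("treatment_risk", "mortality_risk")) {
    cues <- list(cue_json(risk_score(nbs, outcome, ts, cfg)))
  } else if (interactive) {
    pr <- plan_conditional_risk(nbs, selected_plan, outcome, ts, cfg)
    fv <- action_frequencies(nbs, "volume", ts, cfg)
    fp <- action_frequencies(nbs, "pressor", ts, cfg)
    cues <- list(
      plan_mention_json(selected_plan),
      conditional_risk_json(pr, cfg$risk_band_edges),
      cue_json(pr),
      cue_json(fv, focal_count = unname(fv$counts[selected_plan$volume_action]),
               min_support = cfg$min_support),
      cue_json(fp, focal_count = unname(fp$counts[selected_plan$pressor_action]),
               min_support = cfg$min_support))
    extra$plan_support <- list(n_plan = pr$n_plan,
                               sufficient = pr$sufficient_support)
    extra$no_recommendation <- !pr$sufficient_support
    if (pr$significant && !is.na(pr$risk_plan) && !is.na(pr$risk_rest) &&
        pr$risk_plan < pr$risk_rest) {
      rec <- structure(list(mode = "by_risk", plan = selected_plan,
                            basis = pr), class = "recommendation")
      cues[[length(cues) + 1]] <- cue_json(rec)
    }
  } else if (interface_name == "prior_clinician_actions") {
    fv <- action_frequencies(nbs, "volume", ts, cfg)
    fp <- action_frequencies(nbs, "pressor", ts, cfg)
    cv <- consensus(fv, cfg)
    cp <- consensus(fp, cfg)
    cues <- list(plan_mention_json(NULL),
                 cue_json(fv), cue_json(fp), cue_json(cv), cue_json(cp))
    # the modal actions "could be considered a recommendation": emitted as a
    # derived field, not a cue, and flagged implicit
    extra$modal_plan <- list(volume_action = cv$modal_action,
                             pressor_action = cp$modal_action,
                             implicit = TRUE)
  } else if (interface_name == "treatment_recommendation") {
    rec <- recommend(nbs, "by_risk", outcome_kind = "mortality_in_admission",
                     trajectories = ts, config = cfg)
    cues <- list(plan_mention_json(rec$plan), cue_json(rec))
    extra$no_recommendation <- is.null(rec$plan)
  }

  structure(c(list(interface_name = interface_name,
                   patient_id = patient_id,
                   bin_index = bin_index,
                   selected_plan = if (is.null(selected_plan)) NULL
                                   else unclass(selected_plan),
                   k_actual = nbs$k_actual,
                   cues = cues),
              extra),
            class = "interface_payload")
}

#' Validate and serialize an interface payload
#'
#' `validate_payload()` checks the structural contract: known interface
#' name, required identifier fields, exact cue composition per the
#' interface map, and (for `prior_clinician_actions`) the absence of any
#' outcome-derived cue.
#'
#' @param payload an `interface_payload` (or a list parsed from its JSON)
#' @return `TRUE` invisibly; otherwise a schema error
#' @export
validate_payload <- function(payload) {
  need <- c("interface_name", "patient_id", "bin_index", "cues")
  missing <- need[!need %in% names(payload)]
  if (length(missing))
    schema_error("payload is missing fields: %s", paste(missing, collapse = ", "))
  nm <- payload$interface_name
  map <- interface_cue_map()[[nm]]
  if (is.null(map)) schema_error("unknown interface name '%s'", nm)
  codes <- vapply(payload$cues, `[[`, character(1), "cue_code")
  prefixes <- sub("-.*$", "", codes)
  if (!all(prefixes %in% c(map$required, map$optional)) ||
      !all(map$required %in% prefixes))
    schema_error("interface '%s' has cue set {%s}, expected {%s}%s", nm,
                 paste(sort(unique(prefixes)), collapse = ", "),
                 paste(map$required, collapse = ", "),
                 if (length(map$optional))
                   sprintf(" (+optional %s)", paste(map$optional, collapse = ", "))
                 else "")
  for (cue in payload$cues) {
    if (!all(c("cue_code", "version", "inputs_digest", "payload") %in%
             names(cue)))
      schema_error("cue object missing envelope fields in interface '%s'", nm)
  }
  if (nm == "prior_clinician_actions" && any(prefixes %in% c("R3", "R4")))
    schema_error("prior_clinician_actions must not contain outcome cues")
  invisible(TRUE)
}

#' @rdname validate_payload
#' @export
payload_json <- function(payload) {
  canonical_json(unclass(payload))
}

#' @export
format.interface_payload <- function(x, ...) {
  sprintf("<interface_payload %s for %s/bin %s: %d cues>",
          x$interface_name, x$patient_id, x$bin_index, length(x$cues))
}

#' @export
print.interface_payload <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
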