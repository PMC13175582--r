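# Exact nearest-neighbor retrieval over state embeddings.
#
# The cue statistics are computed over only 100 neighbors, so retrieval is
# exact by contract: the index must answer every query identically to a
# brute-force scan, with deterministic lexicographic tie-breaking.

#' Neighbor query configuration
#'
#' @param k number of neighbors (default 100)
#' @param metric `euclidean` or `cosine`
#' @param exclude_same_patient drop all states of the query's own patient
#'   (default `TRUE`), so a patient's own history cannot dominate their cues
#' @return an object of class `neighbor_query_config`
#' @export
neighbor_query_config <- function(k = 100L, metric = "euclidean",
                                  exclude_same_patient = TRUE) {
  metric <- match.arg(metric, c("euclidean", "cosine"))
  cfg <- structure(list(k = as.integer(k), metric = metric,
                        exclude_same_patient = isTRUE(exclude_same_patient)),
                   class = "neighbor_query_config")
  if (!is_count(cfg$k))
    config_error("invalid configuration field 'k': must be a positive integer")
  cfg
}

#' Build a neighbor index over cohort embeddings
#'
#' @param embeddings embeddings data.table from [embed_cohort()] (columns
#'   `patient_id`, `bin_index`, `e1..ed`; one homogeneous `source`)
#' @return an object of class `neighbor_index`
#' @export
build_index <- function(embeddings) {
  if (!nrow(embeddings)) schema_error("cannot index an empty embedding set")
  src <- attr(embeddings, "source", exact = TRUE)
  if ("source" %in% names(embeddings)) {
    u <- unique(embeddings$source)
    if (length(u) > 1)
      schema_error("mixed embedding sources in one index: %s",
                   paste(u, collapse = ", "))
    src <- u
  }
  ecols <- grep("^e[0-9]+$", names(embeddings), value = TRUE)
  if (!length(ecols)) schema_error("no embedding columns (e1..ed) found")
  dt <- as.data.table(embeddings)
  setorder(dt, patient_id, bin_index)
  E <- as.matrix(dt[, ecols, with = FALSE])
  structure(list(E = E, patient_id = dt$patient_id, bin_index = dt$bin_index,
                 dim = ncol(E), source = src %||% "unknown",
                 sqnorm = rowSums(E^2)),
            class = "neighbor_index")
}

#' @export
format.neighbor_index <- function(x, ...) {
  sprintf("<neighbor_index: %d states, dim %d, source %s>",
          nrow(x$E), x$dim, x$source)
}

#' @export
print.neighbor_index <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Exact k-nearest states for a query embedding
#'
#' Returns the `k_actual = min(k, available)` exact nearest states under the
#' configured metric, after excluding the query state itself (and, by
#' default, every state of the query's patient). Distance ties are broken
#' by `(patient_id, bin_index)` lexicographic order.
#'
#' @param index a `neighbor_index`
#' @param query one embedding row (data.table/list with `patient_id`,
#'   `bin_index`, `e1..ed`)
#' @param config a [neighbor_query_config()]
#' @return an object of class `neighbor_set`: `query` reference,
#'   `neighbors` data.table `(patient_id, bin_index, distance)` with
#'   non-decreasing distances, and `k_actual`
#' @export
nearest_states <- function(index, query, config = neighbor_query_config()) {
  qlist <- if (is.data.frame(query)) as.list(query[1, ]) else as.list(query)
  q <- suppressWarnings(as.numeric(unlist(
    qlist[paste0("e", seq_len(index$dim))])))
  if (length(q) != index$dim || anyNA(q))
    schema_error("query dimension does not match the index (dim %d)", index$dim)
  if (config$metric == "euclidean") {
    # plain coordinate-wise differences: unlike the expanded-square trick,
    # this keeps exactly tied distances exactly tied, so the lexicographic
    # tie rule sees them
    diff <- index$E - matrix(q, nrow(index$E), index$dim, byrow = TRUE)
    dist <- sqrt(rowSums(diff * diff))
  } else {
    qn <- sqrt(sum(q^2))
    en <- sqrt(index$sqnorm)
    denom <- en * qn
    sim <- ifelse(denom > 0, as.numeric(index$E %*% q) / denom, 0)
    dist <- 1 - sim
  }
  qpid <- as.character(query[["patient_id"]])
  qbin <- as.integer(query[["bin_index"]])
  drop <- if (config$exclude_same_patient) index$patient_id == qpid
          else index$patient_id == qpid & index$bin_index == qbin
  keep <- which(!drop)
  if (!length(keep))
    domain_error("no candidate neighbors remain after exclusions")
  ord <- keep[order(dist[keep], index$patient_id[keep], index$bin_index[keep])]
  k_actual <- min(config$k, length(ord))
  sel <- ord[seq_len(k_actual)]
  structure(list(
    query = list(patient_id = qpid, bin_index = qbin),
    neighbors = data.table(patient_id = index$patient_id[sel],
                           bin_index = index$bin_index[sel],
                           distance = dist[sel]),
    k_actual = k_actual,
    metric = config$metric), class = "neighbor_set")
}

#' @export
format.neighbor_set <- function(x, ...) {
  sprintf("<neighbor_set for %s/bin %s: k=%d, d in [%.3g, %.3g]>",
          x$query$patient_id, x$query$bin_index, x$k_actual,
          if (x$k_actual) min(x$neighbors$distance) else NA,
          if (x$k_actual) max(x$neighbors$distance) else NA)
}

#' @export
print.neighbor_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Serialize a neighbor set to JSON
#'
#' @param ns a `neighbor_set`
#' @return a JSON string
#' @export
neighbor_set_json <- function(ns) {
  canonical_json(list(query = ns$query, metric = ns$metric,
                      k_actual = ns$k_actual,
                      neighbors = ns$neighbors))
}
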