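#' Discrete treatment plans
#'
#' A treatment plan discretizes the sepsis management decision into two
#' orthogonal categories: the volume action (IV fluid bolus, nothing, or
#' diuresis) and the vasopressor action (increase/start, maintain, or
#' decrease/stop). The 3 x 3 grid enumerates all plans.
#'
#' @param volume_action one of `volume_actions()`
#' @param pressor_action one of `pressor_actions()`
#' @return an object of class `treatment_plan`
#' @examples
#' treatment_plan("give_fluids", "maintain")
#' @export
treatment_plan <- function(volume_action, pressor_action) {
  volume_action <- match.arg(volume_action, volume_actions())
  pressor_action <- match.arg(pressor_action, pressor_actions())
  structure(list(volume_action = volume_action,
                 pressor_action = pressor_action),
            class = "treatment_plan")
}

#' @rdname treatment_plan
#' @export
volume_actions <- function() c("give_fluids", "none", "give_diuretics")

#' @rdname treatment_plan
#' @export
pressor_actions <- function() c("increase_or_start", "maintain", "decrease_or_stop")

.plan_cache <- new.env(parent = emptyenv())

#' @rdname treatment_plan
#' @return `plan_grid()`: a data.frame with one row per plan in the 3 x 3 grid.
#' @export
plan_grid <- function() {
  if (is.null(.plan_cache$grid)) {
    g <- expand.grid(volume_action = volume_actions(),
                     pressor_action = pressor_actions(),
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$volume_action, g$pressor_action), , drop = FALSE]
    rownames(g) <- NULL
    .plan_cache$grid <- g
  }
  .plan_cache$grid
}

plan_key <- function(plan) paste(plan$volume_action, plan$pressor_action, sep = "|")

plan_from_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  treatment_plan(parts[1], parts[2])
}

#' @export
format.treatment_plan <- function(x, ...) {
  sprintf("<plan volume=%s pressor=%s>", x$volume_action, x$pressor_action)
}

#' @export
print.treatment_plan <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

plan_equal <- function(a, b) {
  a$volume_action == b$volume_action && a$pressor_action == b$pressor_action
}
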