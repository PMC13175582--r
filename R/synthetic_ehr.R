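# Synthetic sepsis cohort generator.
#
# One latent severity per patient evolves as a bounded AR(1) on [0, 1].
# Vitals and labs are linear-Gaussian emissions of severity; a softmax
# clinician policy picks one discrete treatment plan per 4-hour bin; death
# follows a per-bin logistic hazard in severity plus the configured additive
# plan effect. All plan-conditional outcome probabilities are computed in
# closed form (dynamic programming over a discretized severity grid), so
# downstream estimators can be checked against known truth.

BIN_HOURS <- 4

#' Simulation configuration
#'
#' Defines the synthetic cohort generating process. Defaults describe a
#' mixed-acuity ICU cohort: ~4-day mean stay, moderate measurement noise,
#' and treatment effects of a plausible magnitude on in-admission mortality.
#'
#' @param n_patients number of patients to simulate
#' @param mean_stay_hours mean planned ICU stay (gamma-distributed, shape 2)
#' @param severity_drift additive per-bin drift of the latent severity
#' @param action_effects data.frame with columns `volume_action`,
#'   `pressor_action`, `mortality`: additive log-odds shift of the per-bin
#'   death hazard for each plan in the 3 x 3 grid (all 9 cells required)
#' @param policy_temperature softmax temperature of the simulated clinician
#'   policy; lower values concentrate peers on the severity-appropriate plan
#'   (yielding consensus), higher values approach a uniform (unconfounded)
#'   policy
#' @param measurement_noise_sd emission noise, in units of each feature's
#'   population SD
#' @param missingness_rate probability that a scheduled vital measurement is
#'   skipped in a bin (labs are additionally sparser by a factor of ~0.35)
#' @param cmo_hazard per-bin probability of a comfort-measures-only order
#' @param suspicion_fraction fraction of patients given an antibiotic+culture
#'   pair within the 24 h suspicion window
#' @param outcome_base_logodds intercept of the per-bin death hazard
#' @param outcome_severity_logodds slope of the hazard in latent severity
#' @param seed integer seed; identical configs reproduce cohorts exactly
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_patients = 200,
                       mean_stay_hours = 96,
                       severity_drift = 0,
                       action_effects = default_action_effects(),
                       policy_temperature = 0.7,
                       measurement_noise_sd = 0.6,
                       missingness_rate = 0.3,
                       cmo_hazard = 0.01,
                       suspicion_fraction = 0.9,
                       outcome_base_logodds = -5.3,
                       outcome_severity_logodds = 2.2,
                       seed = 1L) {
  cfg <- structure(list(
    n_patients = n_patients, mean_stay_hours = mean_stay_hours,
    severity_drift = severity_drift, action_effects = action_effects,
    policy_temperature = policy_temperature,
    measurement_noise_sd = measurement_noise_sd,
    missingness_rate = missingness_rate, cmo_hazard = cmo_hazard,
    suspicion_fraction = suspicion_fraction,
    outcome_base_logodds = outcome_base_logodds,
    outcome_severity_logodds = outcome_severity_logodds,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_patients))
    config_error("invalid configuration field 'n_patients': must be a positive integer")
  if (!is_num1(cfg$mean_stay_hours) || cfg$mean_stay_hours <= 0)
    config_error("invalid configuration field 'mean_stay_hours': must be a positive real")
  if (!is_num1(cfg$severity_drift))
    config_error("invalid configuration field 'severity_drift': must be a real number")
  if (!is_num1(cfg$policy_temperature) || cfg$policy_temperature <= 0)
    config_error("invalid configuration field 'policy_temperature': must be positive")
  if (!is_num1(cfg$measurement_noise_sd) || cfg$measurement_noise_sd <= 0)
    config_error("invalid configuration field 'measurement_noise_sd': must be positive")
  for (f in c("missingness_rate", "cmo_hazard", "suspicion_fraction"))
    if (!is_prob(cfg[[f]]))
      config_error("invalid configuration field '%s': must lie in [0, 1]", f)
  if (!is_num1(cfg$seed))
    config_error("invalid configuration field 'seed': must be an integer")
  ae <- cfg$action_effects
  if (!is.data.frame(ae) ||
      !all(c("volume_action", "pressor_action", "mortality") %in% names(ae)))
    config_error(paste0("invalid configuration field 'action_effects': need a ",
                        "data.frame with volume_action, pressor_action, mortality"))
  grid <- plan_grid()
  have <- paste(ae$volume_action, ae$pressor_action)
  want <- paste(grid$volume_action, grid$pressor_action)
  if (anyDuplicated(have) || !setequal(have, want))
    config_error(paste0("invalid configuration field 'action_effects': must ",
                        "cover each cell of the 3 x 3 plan grid exactly once"))
  if (!is.numeric(ae$mortality) || anyNA(ae$mortality))
    config_error("invalid configuration field 'action_effects': mortality shifts must be numeric")
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_action_effects <- function() {
  g <- plan_grid()
  vol <- c(give_fluids = -0.3, none = 0, give_diuretics = -0.1)
  prs <- c(increase_or_start = -0.3, maintain = 0, decrease_or_stop = 0.2)
  g$mortality <- unname(vol[g$volume_action] + prs[g$pressor_action])
  g
}

#' @rdname sim_config
#' @param outcome outcome name for `zero_action_effects()` compatibility
#' @export
zero_action_effects <- function(outcome = "mortality") {
  g <- plan_grid()
  g$mortality <- 0
  g
}

# --- feature catalogue ------------------------------------------------------

# 8 vitals (dense, aggregated per bin) + 8 labs (sparse, forward-filled).
# slope is the shift, in population SDs, from severity 0 to severity 1.
feature_catalog <- function() {
  data.frame(
    name = c("heart_rate", "sbp", "dbp", "resp_rate", "temp_c", "spo2",
             "map_bp", "gcs",
             "lactate", "creatinine", "wbc", "platelets", "bilirubin",
             "bun", "sodium", "hemoglobin"),
    kind = rep(c("vital", "lab"), each = 8),
    mu = c(85, 115, 65, 19, 37.2, 96, 80, 13,
           2.2, 1.4, 11, 220, 1.1, 25, 139, 10.5),
    sd = c(15, 18, 12, 5, 0.7, 2.5, 12, 2.5,
           1.4, 0.9, 4.5, 80, 0.8, 12, 4, 1.8),
    slope = c(1.2, -1.0, -0.8, 1.0, 0.6, -0.8, -1.1, -1.2,
              1.3, 0.9, 0.8, -0.7, 0.6, 0.8, 0.3, -0.4),
    stringsAsFactors = FALSE)
}

demographic_features <- function() c("age", "sex", "dx_chf", "dx_ckd")

# --- latent process, policy and hazard --------------------------------------

SEV_REVERSION <- 0.15
SEV_MEAN <- 0.5
SEV_NOISE_SD <- 0.08

severity_step <- function(s, drift, eps) {
  pmin(1, pmax(0, s + SEV_REVERSION * (SEV_MEAN - s) + drift + eps))
}

vol_score <- c(give_fluids = 1, none = 0, give_diuretics = -1)
prs_score <- c(increase_or_start = 1, maintain = 0, decrease_or_stop = -1)

# Softmax policy over the plan grid: utilities penalize the squared mismatch
# between each action's intensity score and a severity-derived target.
# `on` is the pressor status entering the bin; it nudges the pressor target
# toward the status quo (treatment inertia).
policy_probs <- function(s, on, temperature) {
  g <- plan_grid()
  vt <- 2 * s - 1
  pt <- pmin(1, pmax(-1, 2 * s - 1 + ifelse(on, 0.3, -0.3)))
  u <- -(vol_score[g$volume_action] - vt)^2 - (prs_score[g$pressor_action] - pt)^2
  e <- exp((u - max(u)) / temperature)
  unname(e / sum(e))
}

hazard_prob <- function(cfg, s, effect) {
  stats::plogis(cfg$outcome_base_logodds + cfg$outcome_severity_logodds * s + effect)
}

# effect vector aligned with plan_grid() row order
effects_vector <- function(cfg) {
  ae <- cfg$action_effects
  key <- paste(ae$volume_action, ae$pressor_action)
  g <- plan_grid()
  ae$mortality[match(paste(g$volume_action, g$pressor_action), key)]
}

# pressor status after applying a plan's pressor action
pressor_update <- function(on, pressor_action) {
  ifelse(pressor_action == "increase_or_start", TRUE,
         ifelse(pressor_action == "decrease_or_stop", FALSE, on))
}

plan_codes <- function() {
  if (is.null(.plan_cache$codes)) {
    g <- plan_grid()
    vol <- c(give_fluids = "fl", none = "no", give_diuretics = "di")
    prs <- c(increase_or_start = "up", maintain = "mt", decrease_or_stop = "dn")
    g$code <- paste(vol[g$volume_action], prs[g$pressor_action], sep = "_")
    .plan_cache$codes <- g
  }
  .plan_cache$codes
}

# --- closed-form ground truth (grid dynamic programming) --------------------

GT_GRID_N <- 61

# Discretized severity transition kernel with boundary clamping.
severity_kernel <- function(grid, drift) {
  n <- length(grid)
  half <- diff(grid)[1] / 2
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m <- grid[i] + SEV_REVERSION * (SEV_MEAN - grid[i]) + drift
    upper <- stats::pnorm(grid + half, m, SEV_NOISE_SD)
    lower <- stats::pnorm(grid - half, m, SEV_NOISE_SD)
    p <- upper - lower
    p[1] <- upper[1]          # clamp mass below 0 into the first cell
    p[n] <- 1 - lower[n]      # and above 1 into the last
    K[i, ] <- p / sum(p)
  }
  K
}

# Precompute every array needed for closed-form state probabilities:
#   Pdie[r+1, i, on+1]  P(death within r remaining bins | severity node i,
#                         pressor status on, plans drawn from the policy)
#   KP[r+1, i, on+1]    one-step severity-smoothed continuation of Pdie[r]
#   m3[i, on+1]         P(pressor active 3 bins ahead | node i, status on)
make_ground_truth_tables <- function(cfg, max_bins) {
  grid <- seq(0, 1, length.out = GT_GRID_N)
  n <- GT_GRID_N
  K <- severity_kernel(grid, cfg$severity_drift)
  g <- plan_grid()
  eff <- effects_vector(cfg)
  q <- sapply(seq_len(nrow(g)), function(p) hazard_prob(cfg, grid, eff[p]))
  pi_on <- lapply(c(FALSE, TRUE), function(on)
    t(sapply(grid, function(s) policy_probs(s, on, cfg$policy_temperature))))
  onprime <- lapply(c(FALSE, TRUE), function(on)
    pressor_update(on, g$pressor_action))  # logical vec over plans

  Pdie <- array(0, dim = c(max_bins + 1, n, 2))
  KP <- array(0, dim = c(max_bins + 1, n, 2))
  for (r in seq_len(max_bins)) {
    for (oi in 1:2) KP[r, , oi] <- K %*% Pdie[r, , oi]
    for (oi in 1:2) {
      acc <- numeric(n)
      for (p in seq_len(nrow(g))) {
        cont <- KP[r, , if (onprime[[oi]][p]) 2 else 1]
        acc <- acc + pi_on[[oi]][, p] * (q[, p] + (1 - q[, p]) * cont)
      }
      Pdie[r + 1, , oi] <- acc
    }
  }
  for (oi in 1:2) KP[max_bins + 1, , oi] <- K %*% Pdie[max_bins + 1, , oi]

  # joint (severity, pressor-status) chain for the 12 h pressor outcome
  M <- matrix(0, 2 * n, 2 * n)
  idx <- function(i, oi) (oi - 1) * n + i
  for (oi in 1:2) {
    for (oj in 1:2) {
      sel <- which(ifelse(onprime[[oi]], 2, 1) == oj)
      if (!length(sel)) next
      w <- rowSums(pi_on[[oi]][, sel, drop = FALSE])  # depends on next severity
      M[idx(seq_len(n), oi), idx(seq_len(n), oj)] <-
        M[idx(seq_len(n), oi), idx(seq_len(n), oj)] + K * rep(w, each = n)
    }
  }
  on_ind <- c(rep(0, n), rep(1, n))
  m3v <- M %*% (M %*% (M %*% on_ind))
  m3 <- cbind(m3v[1:n], m3v[(n + 1):(2 * n)])

  list(grid = grid, K = K, q = q, pi_on = pi_on, onprime = onprime,
       Pdie = Pdie, KP = KP, m3 = m3, eff = eff, max_bins = max_bins)
}

# linear interpolation of a grid-valued function at severity s
gt_interp <- function(grid, values, s) {
  n <- length(grid)
  pos <- (s - grid[1]) / (grid[2] - grid[1])
  i <- pmin(n - 1, pmax(1, floor(pos) + 1))
  w <- pmax(0, pmin(1, pos - (i - 1)))
  values[i] * (1 - w) + values[i + 1] * w
}

# All plan-conditional and policy-marginal state probabilities for one state.
# `on_prev` is the pressor status entering the bin; `remaining` counts bins
# from the current one (inclusive) to the planned end of stay.
gt_state_probs <- function(cfg, tab, s, on_prev, remaining) {
  g <- plan_grid()
  oi <- if (on_prev) 2 else 1
  r <- max(remaining, 1)
  pi_s <- policy_probs(s, on_prev, cfg$policy_temperature)
  pm <- numeric(nrow(g)); pv <- numeric(nrow(g)); hz <- numeric(nrow(g))
  for (p in seq_len(nrow(g))) {
    onp <- if (tab$onprime[[oi]][p]) 2 else 1
    hz[p] <- hazard_prob(cfg, s, tab$eff[p])
    cont <- gt_interp(tab$grid, tab$KP[r, , onp], s)
    pm[p] <- hz[p] + (1 - hz[p]) * cont
    pv[p] <- gt_interp(tab$grid, tab$m3[, onp], s)
  }
  list(hazard = hz, p_mort = pm, p_vaso12 = pv,
       p_mort_policy = sum(pi_s * pm), p_vaso12_policy = sum(pi_s * pv),
       policy = pi_s)
}

# --- cohort simulation ------------------------------------------------------

#' Simulate a synthetic sepsis cohort with known ground truth
#'
#' Draws `config$n_patients` ICU stays: irregular vital/lab measurements,
#' per-bin treatment plans from the softmax policy, antibiotic/culture
#' suspicion events, comfort-measures-only orders, and a death/discharge
#' outcome from the logistic per-bin hazard. Identical configurations
#' (including the seed) reproduce the cohort exactly.
#'
#' @param config a [sim_config()]
#' @return a list with `records` (list of `patient_record`) and
#'   `ground_truth` (a `ground_truth` object holding, per state, the latent
#'   severity and the closed-form outcome probabilities under each plan and
#'   under the behaviour policy)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cat_feat <- feature_catalog()
  n_vital <- sum(cat_feat$kind == "vital")
  vital_rows <- which(cat_feat$kind == "vital")
  lab_rows <- which(cat_feat$kind == "lab")

  with_seed(config$seed, {
    planned_hours <- pmin(504, pmax(8, stats::rgamma(
      config$n_patients, shape = 2, scale = config$mean_stay_hours / 2)))
    planned_bins <- ceiling(planned_hours / BIN_HOURS)
    tab <- make_ground_truth_tables(config, max(planned_bins))

    records <- vector("list", config$n_patients)
    gt_rows <- vector("list", config$n_patients)

    for (pi_ in seq_len(config$n_patients)) {
      pid <- sprintf("P%04d", pi_)
      age <- round(stats::runif(1, 35, 92))
      sex <- stats::rbinom(1, 1, 0.5)
      dx_chf <- stats::rbinom(1, 1, 0.25)
      dx_ckd <- stats::rbinom(1, 1, 0.2)

      nb <- planned_bins[pi_]
      s <- stats::runif(1, 0.15, 0.85)
      on_prev <- FALSE
      cmo_time <- NA_real_
      death_time <- NA_real_
      died <- FALSE

      ev_t <- list(); ev_f <- list(); ev_v <- list()
      tr_t <- numeric(0); tr_k <- character(0); tr_a <- numeric(0)
      gt <- vector("list", nb)

      for (t in seq_len(nb) - 1L) {
        if (t > 0) s <- severity_step(s, config$severity_drift,
                                      stats::rnorm(1, 0, SEV_NOISE_SD))
        start <- t * BIN_HOURS
        cmo_active <- !is.na(cmo_time)
        if (!cmo_active && stats::runif(1) < config$cmo_hazard) {
          cmo_time <- start
          cmo_active <- TRUE
          tr_t <- c(tr_t, start); tr_k <- c(tr_k, "cmo"); tr_a <- c(tr_a, 1)
        }

        # ground truth is recorded for every simulated bin, before the plan
        # draw, conditioning on the pressor status entering the bin
        probs <- gt_state_probs(config, tab, s, on_prev, nb - t)

        if (cmo_active) {
          plan_idx <- which(plan_grid()$volume_action == "none" &
                            plan_grid()$pressor_action == "decrease_or_stop")
        } else {
          plan_idx <- sample.int(9L, 1L, prob = probs$policy)
        }
        g <- plan_grid()
        vol <- g$volume_action[plan_idx]
        prs <- g$pressor_action[plan_idx]
        on_now <- pressor_update(on_prev, prs)

        if (!cmo_active) {
          if (vol == "give_fluids") {
            tr_t <- c(tr_t, round(start + stats::runif(1, 0, BIN_HOURS), 3))
            tr_k <- c(tr_k, "fluid_ml")
            tr_a <- c(tr_a, 250 * sample.int(4L, 1L))
          } else if (vol == "give_diuretics") {
            tr_t <- c(tr_t, round(start + stats::runif(1, 0, BIN_HOURS), 3))
            tr_k <- c(tr_k, "diuretic_mg")
            tr_a <- c(tr_a, c(20, 40)[sample.int(2L, 1L)])
          }
        }
        if (on_now) {
          tr_t <- c(tr_t, round(start + stats::runif(1, 0, 0.5), 3))
          tr_k <- c(tr_k, "vasopressor_rate")
          tr_a <- c(tr_a, round(stats::runif(1, 0.05, 0.3), 3))
        }

        # measurements: full admission panel in bin 0, then sparser
        meas_p_vital <- if (t == 0) 0.9 else 1 - config$missingness_rate
        meas_p_lab <- if (t == 0) 0.9 else 0.35 * (1 - config$missingness_rate)
        take <- stats::runif(nrow(cat_feat)) <
          ifelse(cat_feat$kind == "vital", meas_p_vital, meas_p_lab)
        if (any(take)) {
          tt <- round(start + stats::runif(sum(take), 0, BIN_HOURS), 3)
          vv <- round(cat_feat$mu[take] +
                        2 * cat_feat$slope[take] * cat_feat$sd[take] * (s - 0.5) +
                        stats::rnorm(sum(take), 0,
                                     cat_feat$sd[take] * config$measurement_noise_sd), 4)
          ev_t[[t + 1L]] <- tt
          ev_f[[t + 1L]] <- cat_feat$name[take]
          ev_v[[t + 1L]] <- vv
        }

        gt[[t + 1L]] <- c(bin_index = t, severity = round(s, 8),
                          pressor_on_prev = as.integer(on_prev),
                          pressor_on = as.integer(on_now),
                          remaining_bins = nb - t,
                          stats::setNames(round(probs$hazard, 8),
                                          paste0("hazard_", plan_codes()$code)),
                          stats::setNames(round(probs$p_mort, 8),
                                          paste0("pmort_", plan_codes()$code)),
                          stats::setNames(round(probs$p_vaso12, 8),
                                          paste0("pvaso12_", plan_codes()$code)),
                          pmort_policy = round(probs$p_mort_policy, 8),
                          pvaso12_policy = round(probs$p_vaso12_policy, 8),
                          plan_taken = plan_idx)

        # per-bin death draw under the taken plan
        if (stats::runif(1) < probs$hazard[plan_idx]) {
          died <- TRUE
          death_time <- (t + 1) * BIN_HOURS
          on_prev <- on_now
          gt <- gt[seq_len(t + 1L)]
          break
        }
        on_prev <- on_now
      }

      outtime <- if (died) death_time else round(planned_hours[pi_], 3)

      # suspicion events (antibiotic + culture within the 24 h window)
      abx <- numeric(0); cult <- numeric(0)
      u <- stats::runif(1)
      if (u < config$suspicion_fraction) {
        a <- round(stats::runif(1, 0, max(0.5, min(12, outtime - 0.5))), 3)
        cl <- round(pmin(outtime, pmax(0, a + stats::runif(1, -6, 6))), 3)
        abx <- a; cult <- cl
        tr_t <- c(tr_t, a, cl); tr_k <- c(tr_k, "antibiotic", "culture")
        tr_a <- c(tr_a, 1, 1)
      } else if (stats::runif(1) < 0.5 && outtime > 2) {
        a <- 1; abx <- a
        tr_t <- c(tr_t, a); tr_k <- c(tr_k, "antibiotic"); tr_a <- c(tr_a, 1)
        if (outtime > 30) {  # culture too far from the antibiotic to qualify
          cl <- round(min(outtime, a + 30), 3); cult <- cl
          tr_t <- c(tr_t, cl); tr_k <- c(tr_k, "culture"); tr_a <- c(tr_a, 1)
        }
      }

      events <- data.table(time_hours = unlist(ev_t) %||% numeric(0),
                           feature_name = unlist(ev_f) %||% character(0),
                           value = unlist(ev_v) %||% numeric(0))
      keep <- events$time_hours <= outtime
      events <- events[keep]
      setorder(events, time_hours, feature_name)
      treatments <- data.table(time_hours = tr_t, treatment = tr_k, amount = tr_a)
      treatments <- treatments[treatments$time_hours <= outtime]
      setorder(treatments, time_hours, treatment)

      records[[pi_]] <- patient_record(
        patient_id = pid,
        demographics = c(age = age, sex = sex, dx_chf = dx_chf, dx_ckd = dx_ckd),
        icu_intime = 0, icu_outtime = outtime,
        death_flag = died, death_time = if (died) death_time else NA_real_,
        events = events, treatments = treatments,
        cmo_time = cmo_time,
        antibiotic_times = abx, culture_times = cult)

      gtd <- as.data.table(do.call(rbind, gt))
      gtd[, patient_id := pid]
      gt_rows[[pi_]] <- gtd
    }

    gt_states <- rbindlist(gt_rows)
    setcolorder(gt_states, c("patient_id", setdiff(names(gt_states), "patient_id")))
    list(records = records,
         ground_truth = structure(list(states = gt_states, seed = config$seed),
                                  class = "ground_truth"))
  })
}

#' Construct a patient record
#'
#' @param patient_id identifier
#' @param demographics named numeric vector (age, sex, diagnosis flags)
#' @param icu_intime,icu_outtime stay bounds in hours (intime is 0-aligned)
#' @param death_flag logical; did the patient die in this admission
#' @param death_time hours, or `NA`
#' @param events data.table/data.frame with `time_hours`, `feature_name`, `value`
#' @param treatments data.table/data.frame with `time_hours`, `treatment`, `amount`
#' @param cmo_time hours of the comfort-measures-only order, or `NA`
#' @param antibiotic_times,culture_times numeric vectors of event hours
#' @return an object of class `patient_record`
#' @export
patient_record <- function(patient_id, demographics, icu_intime = 0,
                           icu_outtime, death_flag = FALSE,
                           death_time = NA_real_,
                           events = data.table(time_hours = numeric(0),
                                               feature_name = character(0),
                                               value = numeric(0)),
                           treatments = data.table(time_hours = numeric(0),
                                                   treatment = character(0),
                                                   amount = numeric(0)),
                           cmo_time = NA_real_,
                           antibiotic_times = numeric(0),
                           culture_times = numeric(0)) {
  if (icu_outtime < icu_intime)
    domain_error("patient %s: icu_outtime precedes icu_intime", patient_id)
  structure(list(patient_id = as.character(patient_id),
                 demographics = demographics,
                 icu_intime = icu_intime, icu_outtime = icu_outtime,
                 death_flag = isTRUE(death_flag), death_time = death_time,
                 events = as.data.table(events),
                 treatments = as.data.table(treatments),
                 cmo_time = cmo_time,
                 antibiotic_times = as.numeric(antibiotic_times),
                 culture_times = as.numeric(culture_times)),
            class = "patient_record")
}

#' @export
format.patient_record <- function(x, ...) {
  sprintf("<patient %s: stay %.1f h, %d events, %d treatments%s>",
          x$patient_id, x$icu_outtime - x$icu_intime, nrow(x$events),
          nrow(x$treatments), if (x$death_flag) ", died" else "")
}

#' @export
print.patient_record <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# --- CSV round trip ---------------------------------------------------------

#' Write a cohort to the documented CSV schema
#'
#' Emits `patients.csv`, `icustays.csv`, `events.csv`, `treatments.csv` and,
#' when ground truth is supplied, `ground_truth.csv`. Antibiotic, culture and
#' CMO events are rows of `treatments.csv`. Times are hours from ICU
#' admission. The files round-trip losslessly through [read_cohort()].
#'
#' @param records list of `patient_record`
#' @param directory output directory (created if needed)
#' @param ground_truth optional `ground_truth` object
#' @return the directory, invisibly
#' @export
write_cohort <- function(records, directory, ground_truth = NULL) {
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    io_error("cannot create cohort directory '%s'", directory)
  probe <- file.path(directory, ".write_probe")
  if (!isTRUE(tryCatch({ file.create(probe, showWarnings = FALSE) },
                       error = function(e) FALSE)))
    io_error("cohort directory '%s' is not writable", directory)
  unlink(probe)

  demo_names <- if (length(records)) names(records[[1]]$demographics)
                else demographic_features()
  pats <- rbindlist(lapply(records, function(r) {
    as.data.table(c(list(patient_id = r$patient_id), as.list(r$demographics)))
  }))
  if (!nrow(pats))
    pats <- as.data.table(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), length(demo_names))),
      c("patient_id", demo_names)))
  stays <- rbindlist(lapply(records, function(r) data.table(
    stay_id = paste0(r$patient_id, "-1"), patient_id = r$patient_id,
    intime = r$icu_intime, outtime = r$icu_outtime,
    death_flag = as.integer(r$death_flag), death_time = r$death_time)))
  if (!nrow(stays))
    stays <- data.table(stay_id = character(0), patient_id = character(0),
                        intime = numeric(0), outtime = numeric(0),
                        death_flag = integer(0), death_time = numeric(0))
  events <- rbindlist(lapply(records, function(r) {
    if (!nrow(r$events)) return(NULL)
    data.table(patient_id = r$patient_id, r$events)
  }))
  if (is.null(events) || !nrow(events))
    events <- data.table(patient_id = character(0), time_hours = numeric(0),
                         feature_name = character(0), value = numeric(0))
  treatments <- rbindlist(lapply(records, function(r) {
    if (!nrow(r$treatments)) return(NULL)
    data.table(patient_id = r$patient_id, r$treatments)
  }))
  if (is.null(treatments) || !nrow(treatments))
    treatments <- data.table(patient_id = character(0), time_hours = numeric(0),
                             treatment = character(0), amount = numeric(0))

  fwrite(pats, file.path(directory, "patients.csv"))
  fwrite(stays, file.path(directory, "icustays.csv"))
  fwrite(events, file.path(directory, "events.csv"))
  fwrite(treatments, file.path(directory, "treatments.csv"))
  if (!is.null(ground_truth))
    fwrite(ground_truth$states, file.path(directory, "ground_truth.csv"))
  invisible(directory)
}

#' @rdname write_cohort
#' @details `read_ground_truth()` reads `ground_truth.csv` back from a cohort
#'   directory written with a ground-truth object.
#' @export
read_ground_truth <- function(directory) {
  path <- file.path(directory, "ground_truth.csv")
  if (!file.exists(path)) io_error("no ground_truth.csv in '%s'", directory)
  structure(list(states = fread(path), seed = NA_integer_),
            class = "ground_truth")
}
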