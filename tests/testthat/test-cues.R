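# The eight reasoning cues: observed-plan discretization, feature
# discrepancies and R1/R2 selection, neighbor risk scores, the Fisher-exact
# plan-conditional risk with its support gate, peer action frequencies,
# consensus, and both recommendation modes.

test_that("observed plans discretize window activity by the documented rules", {
  # pressor active throughout, no volume activity -> (none, maintain)
  t1 <- make_traj("T1")
  t1$actions$vaso_active <- rep(TRUE, 4)
  p1 <- observed_plan(t1, 0)
  expect_equal(p1$volume_action, "none")
  expect_equal(p1$pressor_action, "maintain")
  # 500 ml fluid in the next bin, no pressor ever -> (give_fluids, maintain)
  p2 <- observed_plan(make_traj("T2", vol = "give_fluids"), 0)
  expect_equal(p2$volume_action, "give_fluids")
  expect_equal(p2$pressor_action, "maintain")
  # diuretic at bin+2, pressor on now but off at the window end
  t3 <- make_traj("T3")
  t3$actions$diuretic_given[3] <- TRUE
  t3$actions$vaso_active[1] <- TRUE
  p3 <- observed_plan(t3, 0)
  expect_equal(p3$volume_action, "give_diuretics")
  expect_equal(p3$pressor_action, "decrease_or_stop")
  expect_false(attr(p3, "partial"))
  # off-to-on across the window
  p4 <- observed_plan(make_traj("T4", prs = "increase_or_start"), 0)
  expect_equal(p4$pressor_action, "increase_or_start")
  # simultaneous fluid and diuretic counts as fluids
  t5 <- make_traj("T5", vol = "give_fluids")
  t5$actions$diuretic_given[3] <- TRUE
  expect_equal(observed_plan(t5, 0)$volume_action, "give_fluids")
  expect_true(attr(observed_plan(t5, 0), "simultaneous_volume"))
  # window past the end of the trajectory is partial, computed on what exists
  t6 <- make_traj("T6", n_bins = 2)
  t6$actions$fluid_ml[2] <- 300
  p6 <- observed_plan(t6, 0)
  expect_true(attr(p6, "partial"))
  expect_equal(p6$volume_action, "give_fluids")
  expect_error(observed_plan(t6, 7), class = "sepsiscues_domain_error")
})

test_that("the vectorized plan table agrees with per-state observed_plan", {
  d <- demo_pipeline()
  tab <- observed_plans_table(d$ts)
  set.seed(3)
  for (i in sample(nrow(tab), 40)) {
    pl <- observed_plan(d$ts$trajectories[[tab$patient_id[i]]],
                        tab$bin_index[i])
    expect_equal(tab$volume_action[i], pl$volume_action)
    expect_equal(tab$pressor_action[i], pl$pressor_action)
    expect_equal(tab$partial[i], attr(pl, "partial"))
  }
})

make_feature_fixture <- function(qvals, nvals, mu, sd_) {
  fn <- names(mu)
  stats_ <- structure(list(
    mean = c(mu, fluid_ml = 0, vaso_active = 0, diuretic_given = 0),
    sd = c(sd_, fluid_ml = 1, vaso_active = 1, diuretic_given = 1),
    zero_sd = names(sd_)[sd_ == 0],
    input_names = c(fn, "fluid_ml", "vaso_active", "diuretic_given"),
    feature_names = fn, n_states = 100), class = "cohort_stats")
  trajs <- lapply(seq_len(nrow(nvals)), function(i) {
    make_traj(sprintf("N%04d", i),
              features = matrix(nvals[i, ], 4, length(fn), byrow = TRUE,
                                dimnames = list(NULL, fn)))
  })
  names(trajs) <- vapply(trajs, `[[`, character(1), "patient_id")
  ns <- structure(list(
    query = list(patient_id = "Q", bin_index = 0L),
    neighbors = data.table::data.table(patient_id = names(trajs),
                                       bin_index = 0L,
                                       distance = seq_along(trajs) * 0.01),
    k_actual = length(trajs), metric = "euclidean"), class = "neighbor_set")
  query <- list(patient_id = "Q", bin_index = 0L, features = qvals,
                imputed = stats::setNames(rep(FALSE, length(fn)), fn))
  list(stats = stats_, trajs = trajs, ns = ns, query = query)
}

test_that("feature discrepancies match independent arithmetic", {
  mu <- c(f1 = 10, f2 = 0, f3 = 100, f4 = 5, f5 = 1)
  sd_ <- c(f1 = 2, f2 = 1, f3 = 20, f4 = 0, f5 = 0.5)
  set.seed(8)
  nvals <- matrix(rnorm(6 * 5, mean = rep(mu, each = 6),
                        sd = rep(pmax(sd_, 0.1), each = 6)), 6, 5)
  colnames(nvals) <- names(mu)
  qvals <- stats::setNames(c(13, -0.5, 80, 5, 1.8), names(mu))
  fx <- make_feature_fixture(qvals, nvals, mu, sd_)
  d <- feature_discrepancy(fx$query, fx$ns, fx$trajs, fx$stats)
  expect_false("f4" %in% d$feature)  # zero-SD feature excluded
  for (f in c("f1", "f2", "f3", "f5")) {
    zq <- (qvals[f] - mu[f]) / sd_[f]
    zn <- (nvals[, f] - mu[f]) / sd_[f]
    row <- d[d$feature == f]
    expect_equal(row$discrepancy, abs(zq - mean(zn)), ignore_attr = TRUE)
    expect_equal(row$dispersion, sd(zn), ignore_attr = TRUE)
  }
  # query on the neighbor mean has zero discrepancy
  qc <- qvals; qc["f1"] <- mean(nvals[, "f1"])
  fx2 <- make_feature_fixture(qc, nvals, mu, sd_)
  d2 <- feature_discrepancy(fx2$query, fx2$ns, fx2$trajs, fx2$stats)
  expect_equal(d2$discrepancy[d2$feature == "f1"], 0)
  # identical neighbors 2 SD from the query give discrepancy exactly 2
  nconst <- matrix(rep(mu[1:5], each = 4), 4, 5,
                   dimnames = list(NULL, names(mu)))
  q3 <- mu; q3["f2"] <- mu["f2"] + 2 * sd_["f2"]
  fx3 <- make_feature_fixture(q3, nconst, mu, sd_)
  d3 <- feature_discrepancy(fx3$query, fx3$ns, fx3$trajs, fx3$stats)
  expect_equal(d3$discrepancy[d3$feature == "f2"], 2)
})

test_that("R1/R2 select extreme discrepancies with the documented rules", {
  mu <- c(f1 = 0, f2 = 0, f3 = 0, f4 = 0, f5 = 0, f6 = 0)
  sd_ <- rep(1, 6); names(sd_) <- names(mu)
  set.seed(9)
  # f1 agrees perfectly and neighbors are tight on it; others scattered
  nvals <- cbind(f1 = rep(0.5, 8), f2 = rnorm(8, 3, 2), f3 = rnorm(8, -2, 2),
                 f4 = rnorm(8, 1.5, 2), f5 = rnorm(8, 4, 2),
                 f6 = rnorm(8, -3, 2))
  qvals <- stats::setNames(c(0.5, 0, 0, 0, 0, 0), names(mu))
  fx <- make_feature_fixture(qvals, nvals, mu, sd_)
  r1 <- consistent_features(fx$query, fx$ns, fx$trajs, fx$stats)
  r2 <- unusual_features(fx$query, fx$ns, fx$trajs, fx$stats)
  expect_equal(r1$entries$feature[1], "f1")
  expect_false("f1" %in% r2$entries$feature)
  expect_lte(nrow(r1$entries), 3)
  expect_equal(nrow(r2$entries), 3)
  # R2 equals the brute-force descending sort of discrepancies
  dd <- feature_discrepancy(fx$query, fx$ns, fx$trajs, fx$stats)
  ord <- dd$feature[order(-dd$discrepancy, dd$feature)]
  expect_identical(r2$entries$feature, ord[1:3])
  # R1 only admits features below the median dispersion, sorted by agreement
  med <- stats::median(dd$dispersion)
  expect_true(all(r1$entries$dispersion < med))
  expect_true(!is.unsorted(r1$entries$discrepancy))
  # with two eligible features, the unusual cue reports both
  fx2 <- make_feature_fixture(qvals[1:2], nvals[, 1:2], mu[1:2], sd_[1:2])
  r2b <- unusual_features(fx2$query, fx2$ns, fx2$trajs, fx2$stats)
  expect_equal(nrow(r2b$entries), 2)
  # imputed query features are never surfaced
  fx3 <- fx
  fx3$query$imputed["f2"] <- TRUE
  r2c <- unusual_features(fx3$query, fx3$ns, fx3$trajs, fx3$stats)
  expect_false("f2" %in% r2c$entries$feature)
})

test_that("risk scores use defined-label denominators and the band edges", {
  fx <- make_neighbor_fixture(rep("none", 100), rep("maintain", 100),
                              died = c(rep(TRUE, 30), rep(FALSE, 70)))
  r <- risk_score(fx$neighbors, "mortality_in_admission", fx$trajs)
  expect_equal(r$probability, 0.30)
  expect_equal(r$level, "low")
  expect_equal(r$n_defined, 100)
  # 50 of 100: the "as likely as not" moderate display case
  fx2 <- make_neighbor_fixture(rep("none", 100), rep("maintain", 100),
                               vaso12 = c(rep(TRUE, 50), rep(FALSE, 50)))
  r2 <- risk_score(fx2$neighbors, "vasopressor_at_12h", fx2$trajs)
  expect_equal(r2$probability, 0.50)
  expect_equal(r2$level, "moderate")
  # 20 undefined labels drop out of the denominator: 40 / 80
  fx3 <- make_neighbor_fixture(rep("none", 100), rep("maintain", 100),
                               vaso12 = c(rep(TRUE, 40), rep(FALSE, 40),
                                          rep(NA, 20)))
  r3 <- risk_score(fx3$neighbors, "vasopressor_at_12h", fx3$trajs)
  expect_equal(r3$probability, 0.50)
  expect_equal(r3$n_defined, 80)
  fx4 <- make_neighbor_fixture(rep("none", 5), rep("maintain", 5),
                               vaso12 = rep(NA, 5))
  expect_error(risk_score(fx4$neighbors, "vasopressor_at_12h", fx4$trajs),
               class = "sepsiscues_domain_error")
})

test_that("band edges classify strictly and follow the configuration", {
  mk <- function(pos, n) make_neighbor_fixture(
    rep("none", n), rep("maintain", n),
    died = c(rep(TRUE, pos), rep(FALSE, n - pos)))
  lv <- function(pos, n, cfg = cue_config())
    risk_score(mk(pos, n)$neighbors, "mortality_in_admission",
               mk(pos, n)$trajs, cfg)$level
  expect_equal(lv(33, 100), "low")       # 0.33 < 1/3
  expect_equal(lv(34, 100), "moderate")
  expect_equal(lv(66, 100), "moderate")  # 0.66 < 2/3
  expect_equal(lv(67, 100), "high")      # 0.67 > 2/3
  cfg <- cue_config(risk_band_edges = c(0.2, 0.8))
  expect_equal(lv(21, 100, cfg), "moderate")
  expect_equal(lv(19, 100, cfg), "low")
})

test_that("plan-conditional risk reproduces the exact hypergeometric test", {
  # 40 on the plan with 5 deaths, 60 others with 30 deaths
  fx <- make_neighbor_fixture(
    c(rep("give_fluids", 40), rep("none", 60)),
    rep("maintain", 100),
    died = c(rep(TRUE, 5), rep(FALSE, 35), rep(TRUE, 30), rep(FALSE, 30)))
  pr <- plan_conditional_risk(fx$neighbors,
                              treatment_plan("give_fluids", "maintain"),
                              "mortality_in_admission", fx$trajs)
  expect_equal(pr$n_plan, 40)
  expect_equal(pr$risk_plan, 5 / 40)
  expect_equal(pr$risk_rest, 30 / 60)
  expect_equal(pr$p_value, enum_fisher_p(5, 35, 30, 30), tolerance = 1e-12)
  expect_true(pr$significant)
  expect_true(pr$sufficient_support)
})

test_that("the support gate hides conditional risk below 10 of 100 neighbors", {
  fx <- make_neighbor_fixture(
    c(rep("give_diuretics", 9), rep("none", 91)),
    rep("maintain", 100),
    died = c(rep(TRUE, 9), rep(FALSE, 45), rep(TRUE, 46)))
  pr <- plan_conditional_risk(fx$neighbors,
                              treatment_plan("give_diuretics", "maintain"),
                              "mortality_in_admission", fx$trajs)
  expect_false(pr$sufficient_support)
  expect_false(pr$significant)
  expect_true(is.na(pr$risk_plan))
  expect_true(is.na(pr$p_value))
  expect_equal(pr$n_plan, 9)
  expect_equal(pr$risk_rest, 46 / 91)
  # exactly 10 passes the gate
  fx10 <- make_neighbor_fixture(
    c(rep("give_diuretics", 10), rep("none", 90)),
    rep("maintain", 100),
    died = rep(c(TRUE, FALSE), 50))
  pr10 <- plan_conditional_risk(fx10$neighbors,
                                treatment_plan("give_diuretics", "maintain"),
                                "mortality_in_admission", fx10$trajs)
  expect_true(pr10$sufficient_support)
  expect_false(is.na(pr10$p_value))
})

test_that("identical partition risks give p = 1 and no flag", {
  fx <- make_neighbor_fixture(
    c(rep("give_fluids", 40), rep("none", 60)),
    rep("maintain", 100),
    died = c(rep(TRUE, 20), rep(FALSE, 20), rep(TRUE, 30), rep(FALSE, 30)))
  pr <- plan_conditional_risk(fx$neighbors,
                              treatment_plan("give_fluids", "maintain"),
                              "mortality_in_admission", fx$trajs)
  expect_equal(pr$p_value, 1)
  expect_false(pr$significant)
  # one-sided partitions leave the p-value undefined
  fx1 <- make_neighbor_fixture(rep("none", 20), rep("maintain", 20),
                               died = rep(c(TRUE, FALSE), 10))
  pr1 <- plan_conditional_risk(fx1$neighbors,
                               treatment_plan("none", "maintain"),
                               "mortality_in_admission", fx1$trajs)
  expect_true(is.na(pr1$p_value))
  expect_false(pr1$significant)
})

test_that("swapping the plan and rest partitions negates the difference, keeps p", {
  set.seed(12)
  for (i in 1:20) {
    is_plan <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
    labels <- sample(c(TRUE, FALSE, NA), 60, replace = TRUE,
                     prob = c(0.3, 0.6, 0.1))
    cfg <- cue_config(min_support = 1)
    a <- sepsiscues:::plan_risk_from_partition(is_plan, labels, cfg)
    b <- sepsiscues:::plan_risk_from_partition(!is_plan, labels, cfg)
    if (!is.na(a$p_value)) {
      expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
      expect_equal(a$risk_plan - a$risk_rest, -(b$risk_plan - b$risk_rest),
                   tolerance = 1e-12)
    }
  }
})

test_that("action frequencies are exact tallies normalized by k_actual", {
  fx <- make_neighbor_fixture(rep("give_fluids", 100), rep("maintain", 100))
  f <- action_frequencies(fx$neighbors, "volume", fx$trajs)
  expect_equal(unname(f$frequencies["give_fluids"]), 1)
  expect_equal(sum(f$frequencies), 1)
  fx2 <- make_neighbor_fixture(
    c(rep("give_fluids", 61), rep("none", 30), rep("give_diuretics", 9)),
    rep("maintain", 100))
  f2 <- action_frequencies(fx2$neighbors, "volume", fx2$trajs)
  expect_equal(unname(f2$frequencies[c("give_fluids", "none",
                                       "give_diuretics")]),
               c(0.61, 0.30, 0.09))
  expect_equal(sum(f2$counts), fx2$neighbors$k_actual)
  set.seed(14)
  for (i in 1:5) {
    vol <- sample(volume_actions(), 50, replace = TRUE)
    prs <- sample(pressor_actions(), 50, replace = TRUE)
    fx3 <- make_neighbor_fixture(vol, prs)
    fv <- action_frequencies(fx3$neighbors, "volume", fx3$trajs)
    fp <- action_frequencies(fx3$neighbors, "pressor", fx3$trajs)
    for (a in volume_actions())
      expect_equal(unname(fv$counts[a]), sum(vol == a))
    for (a in pressor_actions())
      expect_equal(unname(fp$counts[a]), sum(prs == a))
    expect_equal(sum(fv$frequencies), 1, tolerance = 1e-9)
  }
})

test_that("consensus requires strictly more than the threshold and no tie", {
  freq_of <- function(counts) {
    fx <- make_neighbor_fixture(
      rep(volume_actions(), counts), rep("maintain", sum(counts)))
    action_frequencies(fx$neighbors, "volume", fx$trajs)
  }
  c61 <- consensus(freq_of(c(61, 30, 9)))
  expect_true(c61$consensus)
  expect_equal(c61$modal_action, "give_fluids")
  c60 <- consensus(freq_of(c(60, 31, 9)))
  expect_false(c60$consensus)
  expect_equal(c60$modal_frequency, 0.60)
  tie <- consensus(freq_of(c(45, 45, 10)))
  expect_false(tie$consensus)
  expect_true(tie$tie)
  # threshold is configurable
  expect_true(consensus(freq_of(c(55, 36, 9)),
                        cue_config(consensus_threshold = 0.5))$consensus)
})

test_that("by-risk recommendations pick the lone significantly safer plan", {
  fx <- make_neighbor_fixture(
    c(rep("give_fluids", 40), rep("none", 60)),
    c(rep("maintain", 100)),
    died = c(rep(TRUE, 5), rep(FALSE, 35), rep(TRUE, 30), rep(FALSE, 30)))
  rec <- recommend(fx$neighbors, "by_risk", "mortality_in_admission", fx$trajs)
  expect_equal(rec$plan$volume_action, "give_fluids")
  expect_equal(rec$plan$pressor_action, "maintain")
  # without support, no recommendation at all
  fx2 <- make_neighbor_fixture(
    c(rep("give_fluids", 5), rep("none", 4)), rep("maintain", 9),
    died = c(rep(FALSE, 5), rep(TRUE, 4)))
  rec2 <- recommend(fx2$neighbors, "by_risk", "mortality_in_admission",
                    fx2$trajs)
  expect_null(rec2$plan)
})

test_that("by-peer recommendations equal the per-category argmax", {
  set.seed(17)
  for (i in 1:10) {
    vol <- sample(volume_actions(), 40, replace = TRUE)
    prs <- sample(pressor_actions(), 40, replace = TRUE)
    fx <- make_neighbor_fixture(vol, prs)
    rec <- recommend(fx$neighbors, "by_peer", trajectories = fx$trajs)
    best <- function(x, acts) {
      counts <- vapply(acts, function(a) sum(x == a), integer(1))
      sort(names(counts)[counts == max(counts)])[1]  # alphabetical tie-break
    }
    expect_equal(rec$plan$volume_action, best(vol, volume_actions()))
    expect_equal(rec$plan$pressor_action, best(prs, pressor_actions()))
  }
})

test_that("cue JSON envelopes carry the suffixed codes", {
  fx <- make_neighbor_fixture(rep("none", 100), rep("maintain", 100),
                              died = c(rep(TRUE, 80), rep(FALSE, 20)))
  r <- risk_score(fx$neighbors, "mortality_in_admission", fx$trajs)
  expect_equal(cue_json(r)$cue_code, "R3-H")
  pr <- plan_conditional_risk(fx$neighbors, treatment_plan("none", "maintain"),
                              "mortality_in_admission", fx$trajs)
  expect_equal(cue_json(pr)$cue_code, "R4-N")
  f <- action_frequencies(fx$neighbors, "volume", fx$trajs)
  expect_equal(cue_json(f)$cue_code, "R5")
  expect_equal(cue_json(f, focal_count = 100, min_support = 10)$cue_code,
               "R5-Y")
  expect_equal(cue_json(f, focal_count = 9, min_support = 10)$cue_code,
               "R5-N")
  expect_equal(cue_json(consensus(f))$cue_code, "R6-Y")
  env <- cue_json(r)
  expect_setequal(names(env), c("cue_code", "version", "inputs_digest",
                                "payload"))
  expect_match(env$inputs_digest, "^[0-9a-f]{8}$")
})
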