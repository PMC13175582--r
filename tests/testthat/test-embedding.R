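# Denoising autoencoder: corruption contract, analytic gradients, training
# behaviour, causal embeddings, and the z-score baseline.

test_that("mask corruption obeys its limits and is seeded-deterministic", {
  d <- demo_pipeline()
  tr <- d$ts$trajectories[[1]]
  cfg0 <- encoder_config(corruption_rate = 0)
  expect_identical(corrupt(tr, cfg0, seed = 1)$features, tr$features)
  cfg1 <- encoder_config(corruption_rate = 1)
  expect_true(all(is.na(corrupt(tr, cfg1, seed = 1)$features)))
  cfg <- encoder_config(corruption_rate = 0.3)
  c1 <- corrupt(tr, cfg, seed = 9)
  expect_identical(c1$features, corrupt(tr, cfg, seed = 9)$features)
  expect_false(identical(c1$features, corrupt(tr, cfg, seed = 10)$features))
  expect_identical(c1$bin_index, tr$bin_index)
  expect_identical(c1$actions, tr$actions)
  emptied <- make_traj("E")
  emptied$bin_index <- integer(0)
  expect_error(corrupt(emptied, cfg), class = "sepsiscues_domain_error")
})

test_that("the masked fraction concentrates at the corruption rate", {
  big <- make_traj("B", n_bins = 100,
                   features = matrix(rnorm(100 * 100), 100,
                                     dimnames = list(NULL, paste0("f", 1:100))))
  cfg <- encoder_config(corruption_rate = 0.3)
  frac <- mean(is.na(corrupt(big, cfg, seed = 4)$features))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- encoder_config(embed_dim = 4, n_layers = 2, n_heads = 2)
  C <- 5; L <- 3
  p <- sepsiscues:::init_params(C, cfg)
  X <- matrix(rnorm(L * C), L, C)
  Tgt <- matrix(rnorm(L * C), L, C)
  bm <- c(FALSE, TRUE, FALSE, FALSE, TRUE)
  Tgt[, bm] <- rbinom(L * 2, 1, 0.5)
  fwd <- sepsiscues:::encoder_forward(p, X, cfg, keep_cache = TRUE)
  dY <- sepsiscues:::recon_loss_grad(fwd$Y, Tgt, bm)
  g <- sepsiscues:::encoder_backward(p, fwd, dY, cfg)
  lossf <- function(pp)
    sepsiscues:::recon_loss(sepsiscues:::encoder_forward(pp, X, cfg)$Y, Tgt, bm)
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossf(p1) - lossf(p2)) / (2 * eps)
      ana <- g[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training reduces the loss and is seeded-deterministic", {
  d <- demo_pipeline()
  trajs <- d$ts$trajectories[d$split$train]
  cfg <- encoder_config(embed_dim = 8, n_layers = 1, n_heads = 2,
                        epochs = 3, seed = 5)
  m1 <- train_encoder(trajs, cfg, stats = d$stats)
  expect_length(m1$loss_history, 4)  # untrained evaluation + 3 epochs
  expect_lt(utils::tail(m1$loss_history, 1), m1$loss_history[1])
  m2 <- train_encoder(trajs, cfg, stats = d$stats)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
  expect_error(train_encoder(trajs[1], cfg), class = "sepsiscues_domain_error")
  odd <- trajs
  odd[[1]]$feature_names <- rev(odd[[1]]$feature_names)
  expect_error(train_encoder(odd, cfg), class = "sepsiscues_schema_error")
})

test_that("a cohort of identical trajectories is reconstructed almost exactly", {
  base <- make_traj("I1", n_bins = 5,
                    features = matrix(rep(c(1, 4, 2, 8, 5), 3), 5, 3,
                                      dimnames = list(NULL, c("a", "b", "c"))))
  trajs <- lapply(1:4, function(i) { t <- base; t$patient_id <- paste0("I", i); t })
  names(trajs) <- paste0("I", 1:4)
  cfg <- encoder_config(embed_dim = 8, n_layers = 1, n_heads = 2,
                        epochs = 250, learning_rate = 5e-3,
                        corruption_rate = 0.2, seed = 2)
  m <- train_encoder(trajs, cfg)
  ev <- evaluate_encoder(m, trajs, corruption_seed = 77)
  # z-scored features have unit variance; reconstruction error under 1% of it
  expect_lt(ev$mse, 1e-2)
})

test_that("embeddings are causal, deterministic and batch-invariant", {
  d <- demo_pipeline()
  trajs <- d$ts$trajectories[d$split$train]
  cfg <- encoder_config(embed_dim = 8, n_layers = 2, n_heads = 2,
                        epochs = 1, seed = 5)
  m <- train_encoder(trajs, cfg, stats = d$stats)
  long <- trajs[[which.max(vapply(trajs, function(t) length(t$bin_index),
                                  integer(1)))]]
  e_full <- embed_states(m, long)
  # truncating the trajectory after bin i leaves embeddings of bins <= i alone
  cut <- long
  keep <- seq_len(length(long$bin_index) - 2)
  cut$bin_index <- cut$bin_index[keep]
  cut$features <- cut$features[keep, , drop = FALSE]
  cut$imputed <- cut$imputed[keep, , drop = FALSE]
  cut$actions <- cut$actions[keep]
  cut$labels <- cut$labels[keep]
  e_cut <- embed_states(m, cut)
  expect_equal(as.data.frame(e_cut), as.data.frame(e_full[keep]),
               tolerance = 1e-12)
  # identical trajectories embed identically; batch order is irrelevant
  twin <- long; twin$patient_id <- "TWIN"
  e_twin <- embed_states(m, twin)
  expect_equal(e_twin[, -1], e_full[, -1], tolerance = 1e-12)
  both1 <- embed_cohort(list(long, twin), model = m)
  both2 <- embed_cohort(list(twin, long), model = m)
  data.table::setorder(both1, patient_id, bin_index)
  data.table::setorder(both2, patient_id, bin_index)
  expect_equal(as.data.frame(both1), as.data.frame(both2))
  bad <- long; bad$feature_names <- c(bad$feature_names[-1], "zzz")
  expect_error(embed_states(m, bad), class = "sepsiscues_schema_error")
})

test_that("the baseline embedding is the hand-computable z-score vector", {
  stats_ <- structure(list(
    mean = c(a = 10, b = 0, c = 5, fluid_ml = 0, vaso_active = 0,
             diuretic_given = 0),
    sd = c(a = 2, b = 1, c = 0, fluid_ml = 1, vaso_active = 1,
           diuretic_given = 1),
    zero_sd = "c",
    input_names = c("a", "b", "c", "fluid_ml", "vaso_active",
                    "diuretic_given"),
    feature_names = c("a", "b", "c"), n_states = 10),
    class = "cohort_stats")
  tr <- make_traj("Z", n_bins = 2,
                  features = matrix(c(12, 10, -1.5, 0, 7, 7), 2, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
  e <- baseline_embed(tr, stats_)
  expect_equal(unname(as.numeric(e[1, c("e1", "e2", "e3")])),
               c((12 - 10) / 2, -1.5, 0))   # zero-SD feature contributes 0
  expect_equal(unname(as.numeric(e[2, c("e1", "e2", "e3")])), c(0, 0, 0))
  expect_identical(attr(e, "source"), "baseline")
  # two states with equal features sit at distance zero
  tr2 <- make_traj("Z2", n_bins = 2,
                   features = matrix(c(12, 12, -1.5, -1.5, 7, 7), 2, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  e2 <- baseline_embed(tr2, stats_)
  expect_equal(sum((as.numeric(e2[1, -(1:2)]) -
                      as.numeric(e2[2, -(1:2)]))^2), 0)
})

test_that("autoencoder neighborhoods are closer in latent severity than random states", {
  d <- demo_pipeline()
  cfg <- encoder_config(embed_dim = 16, n_layers = 1, n_heads = 2,
                        epochs = 4, seed = 11)
  m <- train_encoder(d$ts$trajectories[d$split$train], cfg, stats = d$stats)
  emb <- embed_cohort(d$ts, model = m)
  idx <- build_index(emb)
  gt <- d$sim$ground_truth$states
  gtk <- paste(gt$patient_id, gt$bin_index)
  sev <- gt$severity[match(paste(emb$patient_id, emb$bin_index), gtk)]
  embk <- paste(emb$patient_id, emb$bin_index)
  # paired comparison of the mean severity gap, repeated over seeds
  seed_wins <- vapply(31:33, function(seed) {
    set.seed(seed)
    qs <- sample(nrow(emb), 100)
    gaps <- vapply(qs, function(i) {
      ns <- nearest_states(idx, emb[i], neighbor_query_config(k = 10))
      nn_sev <- sev[match(paste(ns$neighbors$patient_id,
                                ns$neighbors$bin_index), embk)]
      rnd <- sample(setdiff(seq_len(nrow(emb)), i), 10)
      c(nn = mean(abs(nn_sev - sev[i])), rnd = mean(abs(sev[rnd] - sev[i])))
    }, numeric(2))
    mean(gaps["nn", ]) < mean(gaps["rnd", ])
  }, logical(1))
  expect_true(all(seed_wins))
})

test_that("encoder checkpoints survive the save/load round trip", {
  d <- demo_pipeline()
  cfg <- encoder_config(embed_dim = 8, n_layers = 1, n_heads = 2,
                        epochs = 1, seed = 5)
  m <- train_encoder(d$ts$trajectories[d$split$train], cfg, stats = d$stats)
  dir <- file.path(tempdir(), "ckpt")
  save_encoder(m, dir)
  m2 <- load_encoder(dir)
  tr <- d$ts$trajectories[[1]]
  expect_equal(as.data.frame(embed_states(m2, tr)),
               as.data.frame(embed_states(m, tr)), tolerance = 1e-12)
})
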