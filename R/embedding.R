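# Denoising-autoencoder patient-state embeddings.
#
# The encoder sees each trajectory as a sequence of state vectors (features
# plus in-bin actions), corrupts them, and is trained to reconstruct the
# uncorrupted sequence at every timestep. Attention is causal, so a state's
# embedding depends only on that state and its past — the embedding is
# honest at decision time. A deterministic z-score baseline embedding with
# the same downstream contract is provided as a model-free reference.

#' Encoder configuration
#'
#' @param embed_dim embedding dimension (>= 2, divisible by `n_heads`)
#' @param n_layers number of attention + feed-forward blocks
#' @param n_heads attention heads per block
#' @param corruption_rate per-entry corruption probability in `[0, 1]`
#' @param corruption_kind one of `mask` (sentinel replacement), `gaussian`
#'   (additive noise) or `shuffle-mix` (swap in a value from another
#'   timestep of the same trajectory)
#' @param epochs training epochs
#' @param batch_size trajectories per gradient averaging group
#' @param learning_rate Adam step size
#' @param seed RNG seed for initialization, shuffling and corruption
#' @return an object of class `encoder_config`
#' @export
encoder_config <- function(embed_dim = 32L, n_layers = 2L, n_heads = 4L,
                           corruption_rate = 0.3, corruption_kind = "mask",
                           epochs = 8L, batch_size = 8L,
                           learning_rate = 3e-3, seed = 1L) {
  corruption_kind <- match.arg(corruption_kind,
                               c("mask", "gaussian", "shuffle-mix"))
  cfg <- structure(list(embed_dim = as.integer(embed_dim),
                        n_layers = as.integer(n_layers),
                        n_heads = as.integer(n_heads),
                        corruption_rate = corruption_rate,
                        corruption_kind = corruption_kind,
                        epochs = as.integer(epochs),
                        batch_size = as.integer(batch_size),
                        learning_rate = learning_rate,
                        seed = as.integer(seed)),
                   class = "encoder_config")
  if (!is_count(cfg$embed_dim) || cfg$embed_dim < 2)
    config_error("invalid configuration field 'embed_dim': must be an integer >= 2")
  if (!is_count(cfg$n_layers) || !is_count(cfg$n_heads))
    config_error("invalid configuration field 'n_layers'/'n_heads': must be positive integers")
  if (cfg$embed_dim %% cfg$n_heads != 0)
    config_error("invalid configuration field 'n_heads': must divide embed_dim")
  if (!is_prob(cfg$corruption_rate))
    config_error("invalid configuration field 'corruption_rate': must lie in [0, 1]")
  if (!is_num1(cfg$learning_rate) || cfg$learning_rate <= 0)
    config_error("invalid configuration field 'learning_rate': must be positive")
  cfg
}

#' Corrupt a trajectory for denoising training
#'
#' With `corruption_kind = "mask"` every feature entry is independently
#' replaced by the `NA` sentinel with probability `corruption_rate`;
#' structure (length, ordering, actions, labels) is unchanged. Deterministic
#' given `seed`.
#'
#' @param traj a `trajectory`
#' @param config an [encoder_config()]
#' @param seed RNG seed for this corruption draw
#' @return a corrupted `trajectory`
#' @export
corrupt <- function(traj, config = encoder_config(), seed = 1L) {
  if (!length(traj$bin_index)) domain_error("cannot corrupt an empty trajectory")
  with_seed(seed, {
    Fm <- traj$features
    n <- length(Fm)
    hit <- stats::runif(n) < config$corruption_rate
    if (config$corruption_kind == "mask") {
      Fm[hit] <- NA_real_
    } else if (config$corruption_kind == "gaussian") {
      sds <- apply(traj$features, 2, stats::sd)
      sds[is.na(sds) | sds == 0] <- 1
      noise <- matrix(stats::rnorm(n), nrow(Fm)) *
        matrix(sds, nrow(Fm), ncol(Fm), byrow = TRUE)
      Fm[hit] <- Fm[hit] + config$corruption_rate * noise[hit]
    } else { # shuffle-mix: swap in the same feature from a random timestep
      src <- matrix(sample.int(nrow(Fm), n, replace = TRUE), nrow(Fm))
      col <- matrix(rep(seq_len(ncol(Fm)), each = nrow(Fm)), nrow(Fm))
      Fm[hit] <- traj$features[cbind(src[hit], col[hit])]
    }
    out <- traj
    out$features <- Fm
    out
  })
}

# binary input channels are detected from the training data: every observed
# value in {0, 1}
detect_binary <- function(X) {
  apply(X, 2, function(col) all(col %in% c(0, 1)))
}

# state-vector inputs of one trajectory: features + in-bin actions
traj_inputs <- function(traj) {
  cbind(traj$features,
        fluid_ml = traj$actions$fluid_ml,
        vaso_active = as.numeric(traj$actions$vaso_active),
        diuretic_given = as.numeric(traj$actions$diuretic_given))
}

# z-score continuous channels, keep binary channels on their 0/1 scale, and
# map the NA corruption sentinel to the channel's neutral value
encode_input <- function(traj, stats_, binary_mask) {
  X <- traj_inputs(traj)
  X <- X[, stats_$input_names, drop = FALSE]
  mu <- stats_$mean; sd_ <- stats_$sd
  for (j in seq_len(ncol(X))) {
    if (binary_mask[j]) {
      X[is.na(X[, j]), j] <- 0.5
    } else {
      X[, j] <- if (sd_[j] > 0) (X[, j] - mu[j]) / sd_[j] else 0
      X[is.na(X[, j]), j] <- 0
    }
  }
  X
}

#' Train the denoising autoencoder
#'
#' Minimizes the reconstruction loss of the uncorrupted state sequence from
#' corrupted input: squared error on continuous channels (z-scored with
#' statistics from these trajectories), cross-entropy on binary channels.
#' Deterministic given `config$seed`.
#'
#' @param trajectories list of `trajectory` (>= 2) or a `trajectory_set`;
#'   by convention the training split only
#' @param config an [encoder_config()]
#' @param stats optional [cohort_stats()] to z-score with (defaults to
#'   statistics of `trajectories`)
#' @param verbose message the per-epoch training loss
#' @return an object of class `encoder_model` with the trained parameters,
#'   the normalization statistics and `loss_history` (one mean training
#'   loss per epoch; index 1 is the untrained evaluation)
#' @export
train_encoder <- function(trajectories, config = encoder_config(),
                          stats = NULL, verbose = FALSE) {
  if (inherits(trajectories, "trajectory_set")) {
    ts <- trajectories
    trajectories <- ts$trajectories
  } else ts <- NULL
  if (length(trajectories) < 2)
    domain_error("need at least 2 trajectories to train the encoder")
  schemas <- unique(vapply(trajectories, function(t)
    paste(t$feature_names, collapse = "\r"), character(1)))
  if (length(schemas) != 1)
    schema_error("trajectories carry inconsistent feature schemas")

  if (is.null(stats)) {
    tmp <- structure(list(trajectories = trajectories,
                          feature_names = trajectories[[1]]$feature_names,
                          config = if (!is.null(ts)) ts$config else cohort_config()),
                     class = "trajectory_set")
    stats <- cohort_stats(tmp)
  }
  Xall <- do.call(rbind, lapply(trajectories, traj_inputs))
  binary_mask <- detect_binary(Xall[, stats$input_names, drop = FALSE])

  with_seed(config$seed, {
    params <- init_params(length(stats$input_names), config)
    st <- adam_state(params)
    model <- structure(list(params = params, config = config, stats = stats,
                            binary_mask = binary_mask,
                            loss_history = numeric(0)),
                       class = "encoder_model")
    loss_hist <- evaluate_encoder(model, trajectories,
                                  corruption_seed = config$seed)$loss
    if (config$epochs > 0) {
      for (ep in seq_len(config$epochs)) {
        ord <- sample(length(trajectories))
        ep_loss <- 0
        for (ti in ord) {
          traj <- trajectories[[ti]]
          cseed <- sample.int(.Machine$integer.max, 1)
          ctraj <- corrupt(traj, config, seed = cseed)
          X <- encode_input(ctraj, stats, binary_mask)
          Tgt <- encode_input(traj, stats, binary_mask)
          fwd <- encoder_forward(params, X, config, keep_cache = TRUE)
          ep_loss <- ep_loss + recon_loss(fwd$Y, Tgt, binary_mask)
          dY <- recon_loss_grad(fwd$Y, Tgt, binary_mask)
          g <- encoder_backward(params, fwd, dY, config)
          upd <- adam_update(params, g, st, config$learning_rate)
          params <- upd$params; st <- upd$state
        }
        loss_hist <- c(loss_hist, ep_loss / length(trajectories))
        if (verbose)
          message(sprintf("epoch %d: training loss %.5f", ep,
                          ep_loss / length(trajectories)))
      }
    }
    model$params <- params
    model$loss_history <- loss_hist
    model
  })
}

#' Reconstruction performance of an encoder on held-out trajectories
#'
#' Corrupts each trajectory with a fixed seed, reconstructs, and averages
#' the composite loss and the continuous-channel mean squared error.
#'
#' @param model an `encoder_model`
#' @param trajectories list of `trajectory`
#' @param corruption_seed seed of the evaluation corruption draws
#' @return list with `loss` and `mse`
#' @export
evaluate_encoder <- function(model, trajectories, corruption_seed = 1L) {
  if (inherits(trajectories, "trajectory_set"))
    trajectories <- trajectories$trajectories
  bm <- model$binary_mask
  cont <- !bm
  tot_loss <- 0; tot_se <- 0; n_se <- 0
  for (i in seq_along(trajectories)) {
    traj <- trajectories[[i]]
    ctraj <- corrupt(traj, model$config, seed = corruption_seed + i)
    X <- encode_input(ctraj, model$stats, bm)
    Tgt <- encode_input(traj, model$stats, bm)
    fwd <- encoder_forward(model$params, X, model$config)
    tot_loss <- tot_loss + recon_loss(fwd$Y, Tgt, bm)
    if (any(cont)) {
      d <- fwd$Y[, cont, drop = FALSE] - Tgt[, cont, drop = FALSE]
      tot_se <- tot_se + sum(d^2); n_se <- n_se + length(d)
    }
  }
  list(loss = tot_loss / length(trajectories),
       mse = if (n_se) tot_se / n_se else NA_real_)
}

#' Per-state embeddings from a trained encoder
#'
#' One embedding per state. Attention is causal, so a state's embedding may
#' depend on earlier states of its own trajectory but never on later ones,
#' and never on other trajectories in the batch.
#'
#' @param model an `encoder_model`
#' @param traj a `trajectory`
#' @return data.table `(patient_id, bin_index, e1..ed)` with attribute
#'   `source = "autoencoder"`
#' @export
embed_states <- function(model, traj) {
  if (!identical(traj$feature_names,
                 setdiff(model$stats$input_names,
                         c("fluid_ml", "vaso_active", "diuretic_given"))))
    schema_error("trajectory schema does not match the encoder's")
  X <- encode_input(traj, model$stats, model$binary_mask)
  fwd <- encoder_forward(model$params, X, model$config)
  E <- fwd$E
  colnames(E) <- paste0("e", seq_len(ncol(E)))
  out <- data.table(patient_id = traj$patient_id, bin_index = traj$bin_index)
  out <- cbind(out, as.data.table(E))
  data.table::setattr(out, "source", "autoencoder")
  out
}

#' Model-free baseline embedding
#'
#' The z-scored raw state vector (cohort training statistics); zero-variance
#' inputs contribute a zero coordinate. Deterministic and model-free; shares
#' the downstream contract of [embed_states()], so retrieval and every cue
#' accept either source.
#'
#' @param traj a `trajectory`
#' @param cohort_stats a [cohort_stats()]
#' @return data.table `(patient_id, bin_index, e1..ed)` with attribute
#'   `source = "baseline"`
#' @export
baseline_embed <- function(traj, cohort_stats) {
  X <- traj_inputs(traj)[, cohort_stats$input_names, drop = FALSE]
  mu <- cohort_stats$mean; sd_ <- cohort_stats$sd
  for (j in seq_len(ncol(X)))
    X[, j] <- if (sd_[j] > 0) (X[, j] - mu[j]) / sd_[j] else 0
  colnames(X) <- paste0("e", seq_len(ncol(X)))
  out <- data.table(patient_id = traj$patient_id, bin_index = traj$bin_index)
  out <- cbind(out, as.data.table(X))
  data.table::setattr(out, "source", "baseline")
  out
}

#' Embed every trajectory of a set
#'
#' @param ts a `trajectory_set` or list of `trajectory`
#' @param model an `encoder_model`, or `NULL` with `stats` supplied to use
#'   the baseline embedding
#' @param stats a [cohort_stats()] (baseline source only)
#' @return one embeddings data.table for the whole cohort
#' @export
embed_cohort <- function(ts, model = NULL, stats = NULL) {
  trajs <- if (inherits(ts, "trajectory_set")) ts$trajectories else ts
  if (!is.null(model)) {
    out <- rbindlist(lapply(trajs, embed_states, model = model))
    data.table::setattr(out, "source", "autoencoder")
  } else {
    if (is.null(stats)) domain_error("baseline embedding needs cohort_stats")
    out <- rbindlist(lapply(trajs, baseline_embed, cohort_stats = stats))
    data.table::setattr(out, "source", "baseline")
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' A checkpoint is a directory holding `config.json` (architecture,
#' normalization statistics, loss history) and `weights.csv` (flattened
#' parameters).
#'
#' @param model an `encoder_model`
#' @param directory checkpoint directory
#' @return the directory (save) or the restored `encoder_model` (load)
#' @export
save_encoder <- function(model, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) io_error("cannot create '%s'", directory)
  meta <- list(config = unclass(model$config),
               stats = list(mean = as.list(model$stats$mean),
                            sd = as.list(model$stats$sd),
                            input_names = model$stats$input_names,
                            feature_names = model$stats$feature_names,
                            n_states = model$stats$n_states),
               binary_mask = model$binary_mask,
               loss_history = model$loss_history)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = 12),
             file.path(directory, "config.json"))
  w <- rbindlist(lapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    data.table(param = nm, index = seq_along(p), value = as.numeric(p),
               nrow = if (is.matrix(p)) nrow(p) else NA_integer_,
               ncol = if (is.matrix(p)) ncol(p) else NA_integer_)
  }))
  fwrite(w, file.path(directory, "weights.csv"))
  invisible(directory)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(directory) {
  meta <- jsonlite::fromJSON(file.path(directory, "config.json"))
  w <- fread(file.path(directory, "weights.csv"))
  params <- lapply(split(w, by = "param", sorted = FALSE), function(d) {
    if (!is.na(d$nrow[1])) matrix(d$value, d$nrow[1], d$ncol[1]) else d$value
  })
  cfg <- do.call(encoder_config, meta$config[names(meta$config) != ""])
  stats_ <- structure(list(mean = unlist(meta$stats$mean),
                           sd = unlist(meta$stats$sd),
                           zero_sd = names(unlist(meta$stats$sd))[unlist(meta$stats$sd) == 0],
                           input_names = meta$stats$input_names,
                           feature_names = meta$stats$feature_names,
                           n_states = meta$stats$n_states),
                      class = "cohort_stats")
  structure(list(params = params[unique(w$param)], config = cfg,
                 stats = stats_, binary_mask = meta$binary_mask,
                 loss_history = meta$loss_history),
            class = "encoder_model")
}

#' @export
format.encoder_model <- function(x, ...) {
  sprintf("<encoder_model: dim %d, %d layers, %d heads, %d inputs, %d epochs trained>",
          x$config$embed_dim, x$config$n_layers, x$config$n_heads,
          length(x$stats$input_names), max(0, length(x$loss_history) - 1))
}

#' @export
print.encoder_model <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
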