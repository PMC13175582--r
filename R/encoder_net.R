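# Internal network machinery for the denoising autoencoder: a causal
# (left-to-right) multi-head self-attention encoder with a tanh feed-forward
# block per layer, trained by Adam on analytic gradients. Written directly
# in matrix algebra; the backward pass is verified against finite
# differences in the test suite. No layer normalisation at this scale.

pos_encoding <- function(L, d) {
  pos <- matrix(0, L, d)
  positions <- seq_len(L) - 1
  for (j in seq_len(d)) {
    freq <- 1 / (10000^((2 * floor((j - 1) / 2)) / d))
    pos[, j] <- if (j %% 2 == 1) sin(positions * freq) else cos(positions * freq)
  }
  pos
}

init_params <- function(n_inputs, cfg) {
  d <- cfg$embed_dim
  h <- 2L * d
  sc <- function(nr, nc, scale) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  p <- list(W_in = sc(n_inputs, d, 1 / sqrt(n_inputs)), b_in = numeric(d))
  for (l in seq_len(cfg$n_layers)) {
    p[[paste0("Wq", l)]] <- sc(d, d, 1 / sqrt(d))
    p[[paste0("Wk", l)]] <- sc(d, d, 1 / sqrt(d))
    p[[paste0("Wv", l)]] <- sc(d, d, 1 / sqrt(d))
    p[[paste0("Wo", l)]] <- sc(d, d, 0.5 / sqrt(d))
    p[[paste0("W1", l)]] <- sc(d, h, 1 / sqrt(d))
    p[[paste0("b1", l)]] <- numeric(h)
    p[[paste0("W2", l)]] <- sc(h, d, 0.5 / sqrt(h))
    p[[paste0("b2", l)]] <- numeric(d)
  }
  p$W_out <- sc(d, n_inputs, 1 / sqrt(d))
  p$b_out <- numeric(n_inputs)
  p
}

row_softmax_causal <- function(S) {
  L <- nrow(S)
  A <- matrix(0, L, L)
  for (i in seq_len(L)) {
    s <- S[i, seq_len(i)]
    e <- exp(s - max(s))
    A[i, seq_len(i)] <- e / sum(e)
  }
  A
}

# Forward pass over one sequence (L x C input). Returns output scores,
# per-position embeddings (final hidden states) and, if keep_cache, every
# intermediate needed by the backward pass.
encoder_forward <- function(params, X, cfg, keep_cache = FALSE) {
  L <- nrow(X); d <- cfg$embed_dim
  nh <- cfg$n_heads; dh <- d / nh
  H <- X %*% params$W_in + matrix(params$b_in, L, d, byrow = TRUE) +
    pos_encoding(L, d)
  cache <- list(X = X, H0 = H, layers = vector("list", cfg$n_layers))
  for (l in seq_len(cfg$n_layers)) {
    Hin <- H
    Q <- Hin %*% params[[paste0("Wq", l)]]
    K <- Hin %*% params[[paste0("Wk", l)]]
    V <- Hin %*% params[[paste0("Wv", l)]]
    O <- matrix(0, L, d)
    As <- vector("list", nh)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      A <- row_softmax_causal(S)
      As[[hh]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    Attn <- O %*% params[[paste0("Wo", l)]]
    H1 <- Hin + Attn
    Z <- H1 %*% params[[paste0("W1", l)]] +
      matrix(params[[paste0("b1", l)]], L, 2 * d, byrow = TRUE)
    U <- tanh(Z)
    Fo <- U %*% params[[paste0("W2", l)]] +
      matrix(params[[paste0("b2", l)]], L, d, byrow = TRUE)
    H <- H1 + Fo
    if (keep_cache)
      cache$layers[[l]] <- list(Hin = Hin, Q = Q, K = K, V = V, O = O,
                                As = As, H1 = H1, U = U)
  }
  Y <- H %*% params$W_out + matrix(params$b_out, L, ncol(X), byrow = TRUE)
  list(Y = Y, E = H, cache = if (keep_cache) cache else NULL)
}

# Composite reconstruction loss: squared error on continuous channels,
# logistic cross-entropy on binary channels, averaged over all entries.
recon_loss <- function(Y, Tgt, binary_mask) {
  n <- length(Y)
  cont <- !binary_mask
  l <- 0
  if (any(cont)) l <- l + 0.5 * sum((Y[, cont, drop = FALSE] -
                                       Tgt[, cont, drop = FALSE])^2)
  if (any(binary_mask)) {
    yb <- Y[, binary_mask, drop = FALSE]
    tb <- Tgt[, binary_mask, drop = FALSE]
    # stable log(1 + exp(yb)) - tb * yb
    l <- l + sum(pmax(yb, 0) - tb * yb + log1p(exp(-abs(yb))))
  }
  l / n
}

recon_loss_grad <- function(Y, Tgt, binary_mask) {
  n <- length(Y)
  dY <- matrix(0, nrow(Y), ncol(Y))
  cont <- !binary_mask
  if (any(cont))
    dY[, cont] <- Y[, cont, drop = FALSE] - Tgt[, cont, drop = FALSE]
  if (any(binary_mask))
    dY[, binary_mask] <- stats::plogis(Y[, binary_mask, drop = FALSE]) -
      Tgt[, binary_mask, drop = FALSE]
  dY / n
}

encoder_backward <- function(params, fwd, dY, cfg) {
  cache <- fwd$cache
  L <- nrow(dY); d <- cfg$embed_dim
  nh <- cfg$n_heads; dh <- d / nh
  g <- list()
  Hfinal <- fwd$E
  g$W_out <- t(Hfinal) %*% dY
  g$b_out <- colSums(dY)
  dH <- dY %*% t(params$W_out)
  for (l in rev(seq_len(cfg$n_layers))) {
    cl <- cache$layers[[l]]
    # feed-forward block (residual)
    dFo <- dH
    g[[paste0("W2", l)]] <- t(cl$U) %*% dFo
    g[[paste0("b2", l)]] <- colSums(dFo)
    dU <- dFo %*% t(params[[paste0("W2", l)]])
    dZ <- dU * (1 - cl$U^2)
    g[[paste0("W1", l)]] <- t(cl$H1) %*% dZ
    g[[paste0("b1", l)]] <- colSums(dZ)
    dH1 <- dH + dZ %*% t(params[[paste0("W1", l)]])
    # attention block (residual)
    dAttn <- dH1
    g[[paste0("Wo", l)]] <- t(cl$O) %*% dAttn
    dO <- dAttn %*% t(params[[paste0("Wo", l)]])
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (hh in seq_len(nh)) {
      cols <- ((hh - 1) * dh + 1):(hh * dh)
      A <- cl$As[[hh]]
      dOh <- dO[, cols, drop = FALSE]
      dV[, cols] <- t(A) %*% dOh
      dA <- dOh %*% t(cl$V[, cols, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dS %*% cl$K[, cols, drop = FALSE]) / sqrt(dh)
      dK[, cols] <- (t(dS) %*% cl$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g[[paste0("Wq", l)]] <- t(cl$Hin) %*% dQ
    g[[paste0("Wk", l)]] <- t(cl$Hin) %*% dK
    g[[paste0("Wv", l)]] <- t(cl$Hin) %*% dV
    dH <- dH1 + dQ %*% t(params[[paste0("Wq", l)]]) +
      dK %*% t(params[[paste0("Wk", l)]]) +
      dV %*% t(params[[paste0("Wv", l)]])
  }
  g$W_in <- t(cache$X) %*% dH
  g$b_in <- colSums(dH)
  g
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
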