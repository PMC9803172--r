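BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
CE_CLIP <- 1e-12

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Feature-convolution layer forward pass
#'
#' Extends convolution to tabular features: for every unordered feature pair
#' `i < j` (enumerated lexicographically) the layer computes
#' `phi_ij = alpha_i x_i + beta_j x_j`, one `alpha`/`beta` kernel weight per
#' feature, and returns the original features concatenated with the
#' `C(n, 2)` pair features, so downstream layers see both.
#'
#' @param x Numeric vector of length `n >= 2`.
#' @param alpha,beta Kernel weights, length `n`.
#' @return Numeric vector of length `n + choose(n, 2)`.
#' @export
feature_conv_forward <- function(x, alpha, beta) {
  n <- length(x)
  if (n < 2L) abort_glia("feature convolution needs n >= 2", "glia_shape_mismatch")
  stopifnot(length(alpha) == n, length(beta) == n)
  pr <- pair_index(n)
  c(x, alpha[pr$i] * x[pr$i] + beta[pr$j] * x[pr$j])
}

# lexicographic unordered pairs i < j
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j, P = (n * (n - 1L)) %/% 2L)
}

batch_feature_conv <- function(Xc, alpha, beta, pr) {
  Phi <- sweep(Xc[, pr$i, drop = FALSE], 2L, alpha[pr$i], "*") +
    sweep(Xc[, pr$j, drop = FALSE], 2L, beta[pr$j], "*")
  cbind(Xc, Phi)
}

# batch norm over columns; returns output + cache for backward
bn_forward <- function(A, gamma, shift, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(A)
    xc <- sweep(A, 2L, mu)
    v <- colMeans(xc * xc)                    # biased, as in the BN definition
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2L, invstd, "*")
    new_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu
    new_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
    list(out = sweep(sweep(xhat, 2L, gamma, "*"), 2L, shift, "+"),
         xhat = xhat, invstd = invstd, run_mean = new_mean, run_var = new_var)
  } else {
    invstd <- 1 / sqrt(run_var + BN_EPS)
    xhat <- sweep(sweep(A, 2L, run_mean), 2L, invstd, "*")
    list(out = sweep(sweep(xhat, 2L, gamma, "*"), 2L, shift, "+"),
         xhat = xhat, invstd = invstd, run_mean = run_mean, run_var = run_var)
  }
}

bn_backward <- function(dY, cache, gamma, training) {
  B <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dshift <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  if (training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- sweep(
      dxhat - matrix(s1 / B, B, length(s1), byrow = TRUE) -
        sweep(cache$xhat, 2L, s2 / B, "*"),
      2L, cache$invstd, "*"
    )
  } else {
    dx <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = dx, dgamma = dgamma, dshift = dshift)
}

#' One LSTM cell step
#'
#' The gate equations: `f = sigmoid(W_f x + U_f h + b_f)`,
#' `i = sigmoid(W_i x + U_i h + b_i)`, `o = sigmoid(W_o x + U_o h + b_o)`,
#' `chat = tanh(W_c x + U_c h + b_c)`, `c = f * c_prev + i * chat`,
#' `h = o * tanh(c)`.
#'
#' @param x_t Input vector (length `h_in`).
#' @param h_prev,c_prev Previous hidden / cell state (length `H`).
#' @param w List with `W` (`4H x h_in`), `U` (`4H x H`), `b` (`4H`), rows
#'   stacked in gate order forget, input, output, candidate.
#' @return List `h`, `c`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, w) {
  H <- length(h_prev)
  if (nrow(w$W) != 4L * H || ncol(w$W) != length(x_t) ||
      nrow(w$U) != 4L * H || ncol(w$U) != H || length(w$b) != 4L * H ||
      length(c_prev) != H) {
    abort_glia("LSTM weight shapes inconsistent", "glia_shape_mismatch")
  }
  g <- as.vector(w$W %*% x_t + w$U %*% h_prev + w$b)
  f <- sigmoid(g[seq_len(H)])
  i <- sigmoid(g[H + seq_len(H)])
  o <- sigmoid(g[2L * H + seq_len(H)])
  cand <- tanh(g[3L * H + seq_len(H)])
  c_new <- f * c_prev + i * cand
  list(h = o * tanh(c_new), c = c_new)
}

# Batched LSTM over a direction. Xbig: (p*B) x h_in matrix, rows grouped by
# time step (rows (t-1)*B + 1:B are the batch inputs at step t). Caches are
# stored as big stacked matrices for a single-matmul backward pass.
lstm_run <- function(Xbig, B, w, H, keep_cache = TRUE) {
  lstm_forward_cpp(Xbig, B, w$W, w$U, w$b, keep_cache)
}

# Pure-R reference implementation of the same kernel (kept for cross-checks).
lstm_run_r <- function(Xbig, B, w, H, keep_cache = TRUE) {
  pB <- nrow(Xbig)
  p <- pB %/% B
  XW <- sweep(tcrossprod(Xbig, w$W), 2L, w$b, "+")    # (p*B) x 4H
  Hc <- matrix(0, B, H)
  Cc <- matrix(0, B, H)
  cache <- NULL
  if (keep_cache) {
    cache <- list(gates = matrix(0, pB, 4L * H),      # f,i,o,g post-activation
                  tC = matrix(0, pB, H),
                  Cprev = matrix(0, pB, H),
                  Hprev = matrix(0, pB, H))
  }
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(p)) {
    rows <- (t - 1L) * B + seq_len(B)
    G <- XW[rows, , drop = FALSE] + tcrossprod(Hc, w$U)
    f <- sigmoid(G[, i1, drop = FALSE])
    i <- sigmoid(G[, i2, drop = FALSE])
    o <- sigmoid(G[, i3, drop = FALSE])
    g <- tanh(G[, i4, drop = FALSE])
    Cn <- f * Cc + i * g
    tC <- tanh(Cn)
    if (keep_cache) {
      cache$gates[rows, ] <- cbind(f, i, o, g)
      cache$tC[rows, ] <- tC
      cache$Cprev[rows, ] <- Cc
      cache$Hprev[rows, ] <- Hc
    }
    Cc <- Cn
    Hc <- o * tC
  }
  list(h = Hc, cache = cache)
}

lstm_backward <- function(dH_final, Xbig, B, w, cache) {
  lstm_backward_cpp(dH_final, Xbig, B, w$U, cache$gates, cache$tC,
                    cache$Cprev, cache$Hprev)
}

lstm_backward_r <- function(dH_final, Xbig, B, w, cache) {
  H <- ncol(dH_final)
  pB <- nrow(Xbig)
  p <- pB %/% B
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  dGbig <- matrix(0, pB, 4L * H)
  dH <- dH_final
  dC <- matrix(0, B, H)
  for (t in p:1L) {
    rows <- (t - 1L) * B + seq_len(B)
    f <- cache$gates[rows, i1, drop = FALSE]
    i <- cache$gates[rows, i2, drop = FALSE]
    o <- cache$gates[rows, i3, drop = FALSE]
    g <- cache$gates[rows, i4, drop = FALSE]
    tC <- cache$tC[rows, , drop = FALSE]
    do_ <- dH * tC
    dC <- dC + dH * o * (1 - tC^2)
    dG <- cbind((dC * cache$Cprev[rows, , drop = FALSE]) * f * (1 - f),
                (dC * g) * i * (1 - i),
                do_ * o * (1 - o),
                (dC * i) * (1 - g^2))
    dGbig[rows, ] <- dG
    dH <- dG %*% w$U
    dC <- dC * f
  }
  list(W = crossprod(dGbig, Xbig),
       U = crossprod(dGbig, cache$Hprev),
       b = colSums(dGbig))
}

# stack a list of p x h sequences into the (p*B) x h layout of lstm_run
stack_sequences <- function(seqs, reverse = FALSE) {
  arr <- simplify2array(seqs)                    # p x h x B
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (reverse) arr <- arr[dim(arr)[1L]:1L, , , drop = FALSE]
  ap <- aperm(arr, c(3L, 1L, 2L))                # B x p x h
  matrix(ap, dim(ap)[1L] * dim(ap)[2L], dim(ap)[3L])
}

#' Bidirectional LSTM over one lifetime sequence
#'
#' Runs the LSTM forward over components `t = 1..p` and backward over
#' `t = p..1` from zero initial states, and concatenates the two final
#' hidden states. In training mode inverted dropout is applied to the
#' concatenated vector: each element is zeroed independently with the given
#' probability and survivors are scaled by `1 / (1 - rate)`, so inference is
#' the identity.
#'
#' @param seq `p x h` matrix (a lifetime sequence).
#' @param w_fwd,w_bwd LSTM weights, as in [lstm_cell_step()].
#' @param mode `"inference"` or `"train"`.
#' @param dropout_rate Dropout probability (training mode only).
#' @return Numeric vector of length `2H`.
#' @export
blstm_forward <- function(seq, w_fwd, w_bwd, mode = c("inference", "train"),
                          dropout_rate = 0.5) {
  mode <- match.arg(mode)
  if (!is.matrix(seq) || nrow(seq) < 1L) abort_glia("empty sequence", "glia_shape_mismatch")
  H <- ncol(w_fwd$U)
  out <- c(lstm_run(seq, 1L, w_fwd, H, keep_cache = FALSE)$h,
           lstm_run(seq[nrow(seq):1L, , drop = FALSE], 1L, w_bwd, H, keep_cache = FALSE)$h)
  if (mode == "train" && dropout_rate > 0) {
    keep <- stats::runif(length(out)) >= dropout_rate
    out <- out * keep / (1 - dropout_rate)
  }
  out
}

#' Mean cross-entropy loss
#'
#' `-log p_label`, averaged over the batch; probabilities below `1e-12` are
#' clipped there with a warning.
#'
#' @param probs Numeric matrix (`B x 2`) or vector (length 2) of class
#'   probabilities, column 2 = activated.
#' @param labels Integer labels in `{0, 1}`.
#' @return Mean cross-entropy (scalar).
#' @export
cross_entropy_loss <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  stopifnot(nrow(probs) == length(labels), all(labels %in% c(0, 1)))
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  if (any(p < CE_CLIP)) {
    warning("probabilities clipped at 1e-12 in cross-entropy")
    p <- pmax(p, CE_CLIP)
  }
  mean(-log(p))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise a joint model
#'
#' Feature-convolution kernels start uniform in `+/- 1/sqrt(n)`; dense and
#' LSTM weights are Glorot-uniform; biases zero; batch-norm scale 1, shift 0.
#'
#' @param n_features Input shape-feature count (after any `tau_mean` append).
#' @param config `glia_config`.
#' @param seq_h Histogram bins per component actually present in the
#'   sequences (defaults to `config$h`).
#' @return A list of class `glia_model`.
#' @export
init_model <- function(n_features, config, seq_h = config$h) {
  n <- as.integer(n_features)
  H <- config$hidden_size
  with_lstm <- config$modality == "joint"
  K <- 50L + if (with_lstm) 2L * H else 0L
  pr <- pair_index(n)
  D <- n + pr$P
  par <- with_seed(derive_seed(config$seed, "init"), {
    p <- list(
      alpha = stats::runif(n, -1 / sqrt(n), 1 / sqrt(n)),
      beta = stats::runif(n, -1 / sqrt(n), 1 / sqrt(n)),
      Wc = glorot(50L, D), bc = numeric(50L),
      g1 = rep(1, 50L), s1 = numeric(50L),
      Wh = glorot(2L, K), bh = numeric(2L),
      g2 = rep(1, 2L), s2 = numeric(2L)
    )
    if (with_lstm) {
      p$lstm_f <- list(W = glorot(4L * H, seq_h), U = glorot(4L * H, H), b = numeric(4L * H))
      p$lstm_b <- list(W = glorot(4L * H, seq_h), U = glorot(4L * H, H), b = numeric(4L * H))
    }
    p
  })
  structure(list(
    par = par,
    pairs = pr,
    n_features = n,
    seq_h = as.integer(seq_h),
    hidden_size = H,
    modality = config$modality,
    dropout_rate = config$dropout_rate,
    feature_subset = config$feature_subset,
    feat_mean = numeric(n),
    bn1_mean = numeric(50L), bn1_var = rep(1, 50L),
    bn2_mean = numeric(2L), bn2_var = rep(1, 2L),
    bin_edges = NULL,
    loss_trace = NULL
  ), class = "glia_model")
}

# Full batched forward pass. X: B x n features; seqs: list of B sequences or
# NULL; dropout_mask: B x 2H matrix of {0, 1/(1-rate)} or NULL for none.
model_forward <- function(model, X, seqs = NULL, training = FALSE,
                          dropout_mask = NULL, update_stats = FALSE) {
  par <- model$par
  Xc <- sweep(X, 2L, model$feat_mean)
  U <- batch_feature_conv(Xc, par$alpha, par$beta, model$pairs)
  A1 <- sweep(tcrossprod(U, par$Wc), 2L, par$bc, "+")
  bn1 <- bn_forward(A1, par$g1, par$s1, model$bn1_mean, model$bn1_var, training)
  S <- pmax(bn1$out, 0)
  cache <- list(Xc = Xc, U = U, bn1 = bn1, S = S)
  if (model$modality == "joint") {
    B <- nrow(X)
    xs_f <- stack_sequences(seqs, reverse = FALSE)
    xs_b <- stack_sequences(seqs, reverse = TRUE)
    rf <- lstm_run(xs_f, B, par$lstm_f, model$hidden_size, keep_cache = training)
    rb <- lstm_run(xs_b, B, par$lstm_b, model$hidden_size, keep_cache = training)
    Zl <- cbind(rf$h, rb$h)
    if (training && !is.null(dropout_mask)) Zl <- Zl * dropout_mask
    cache$xs_f <- xs_f; cache$xs_b <- xs_b
    cache$rf <- rf; cache$rb <- rb
    cache$dropout_mask <- dropout_mask
    Z <- cbind(S, Zl)
  } else {
    Z <- S
  }
  logits <- sweep(tcrossprod(Z, par$Wh), 2L, par$bh, "+")
  bn2 <- bn_forward(logits, par$g2, par$s2, model$bn2_mean, model$bn2_var, training)
  Y <- bn2$out
  Y <- Y - apply(Y, 1L, max)
  E <- exp(Y)
  probs <- E / rowSums(E)
  cache$Z <- Z; cache$bn2 <- bn2; cache$probs <- probs
  if (update_stats) {
    model$bn1_mean <- bn1$run_mean; model$bn1_var <- bn1$run_var
    model$bn2_mean <- bn2$run_mean; model$bn2_var <- bn2$run_var
  }
  list(probs = probs, cache = cache, model = model)
}

# Analytic gradients of the mean cross-entropy w.r.t. every parameter.
model_backward <- function(model, cache, labels, training = TRUE) {
  par <- model$par
  B <- nrow(cache$probs)
  onehot <- matrix(0, B, 2L)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1
  dY <- (cache$probs - onehot) / B
  bb2 <- bn_backward(dY, cache$bn2, par$g2, training)
  dlogits <- bb2$dx
  grads <- list(g2 = bb2$dgamma, s2 = bb2$dshift)
  grads$Wh <- crossprod(dlogits, cache$Z)
  grads$bh <- colSums(dlogits)
  dZ <- dlogits %*% par$Wh
  if (model$modality == "joint") {
    dS <- dZ[, 1:50, drop = FALSE]
    dZl <- dZ[, -(1:50), drop = FALSE]
    if (!is.null(cache$dropout_mask)) dZl <- dZl * cache$dropout_mask
    H <- model$hidden_size
    B <- nrow(cache$probs)
    grads$lstm_f <- lstm_backward(dZl[, seq_len(H), drop = FALSE],
                                  cache$xs_f, B, par$lstm_f, cache$rf$cache)
    grads$lstm_b <- lstm_backward(dZl[, H + seq_len(H), drop = FALSE],
                                  cache$xs_b, B, par$lstm_b, cache$rb$cache)
  } else {
    dS <- dZ
  }
  dY1 <- dS * (cache$bn1$out > 0)
  bb1 <- bn_backward(dY1, cache$bn1, par$g1, training)
  dA1 <- bb1$dx
  grads$g1 <- bb1$dgamma; grads$s1 <- bb1$dshift
  grads$Wc <- crossprod(dA1, cache$U)
  grads$bc <- colSums(dA1)
  dU <- dA1 %*% par$Wc
  pr <- model$pairs
  n <- model$n_features
  dPhi <- dU[, n + seq_len(pr$P), drop = FALSE]
  XcI <- cache$Xc[, pr$i, drop = FALSE]
  XcJ <- cache$Xc[, pr$j, drop = FALSE]
  ga <- numeric(n)
  agg_a <- tapply(colSums(dPhi * XcI), pr$i, sum)
  ga[as.integer(names(agg_a))] <- agg_a
  grads$alpha <- ga
  gb <- numeric(n)
  agg_b <- tapply(colSums(dPhi * XcJ), pr$j, sum)
  gb[as.integer(names(agg_b))] <- agg_b
  grads$beta <- gb
  grads
}

#' Forward pass of the fused classifier for one sample
#'
#' Runs the shape subnetwork (feature convolution, 50-unit fully connected
#' layer, batch normalisation, ReLU), the BLSTM branch when the modality
#' requires it, and the fused head (2-unit fully connected layer, batch
#' normalisation, softmax). Inference mode uses the stored running batch-norm
#' statistics and is deterministic.
#'
#' @param sample List with `features` (numeric vector matching the model's
#'   configured input) and, for the joint modality, `sequence` (`p x h`).
#' @param model `glia_model`.
#' @param mode `"inference"` or `"train"`.
#' @return Numeric vector of 2 class probabilities (resting, activated),
#'   summing to 1.
#' @export
joint_forward <- function(sample, model, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  x <- sample$features
  if (length(x) != model$n_features) {
    abort_glia(sprintf("feature length %d does not match model (%d)",
                       length(x), model$n_features), "glia_shape_mismatch")
  }
  seqs <- NULL
  if (model$modality == "joint") {
    if (is.null(sample$sequence)) abort_glia("joint modality needs a sequence",
                                             "glia_modality_mismatch")
    seqs <- list(sample$sequence)
  }
  fw <- model_forward(model, matrix(x, 1L), seqs, training = (mode == "train"))
  as.vector(fw$probs)
}

#' Shape subnetwork forward pass
#'
#' `ReLU(BN(W_c . fconv(x - feature_mean)))` — the morphology branch only.
#'
#' @param x Feature vector matching the model input.
#' @param model `glia_model`.
#' @param mode `"inference"` (running batch-norm statistics) or `"train"`.
#' @return Numeric vector of 50 non-negative activations.
#' @export
shape_subnet_forward <- function(x, model, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  if (length(x) != model$n_features) abort_glia("dimension mismatch", "glia_shape_mismatch")
  par <- model$par
  Xc <- matrix(x - model$feat_mean, 1L)
  U <- batch_feature_conv(Xc, par$alpha, par$beta, model$pairs)
  A1 <- sweep(tcrossprod(U, par$Wc), 2L, par$bc, "+")
  bn1 <- bn_forward(A1, par$g1, par$s1, model$bn1_mean, model$bn1_var,
                    training = (mode == "train"))
  as.vector(pmax(bn1$out, 0))
}
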