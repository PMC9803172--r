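# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

raster_disk <- function(m, center, radius) {
  r <- matrix(seq_len(m), m, m) - center[1L]
  cc <- matrix(seq_len(m), m, m, byrow = TRUE) - center[2L]
  as_glia_mask(matrix(as.integer(r^2 + cc^2 <= radius^2), m, m))
}

raster_ellipse <- function(m, center, semi_row, semi_col) {
  r <- matrix(seq_len(m), m, m) - center[1L]
  cc <- matrix(seq_len(m), m, m, byrow = TRUE) - center[2L]
  as_glia_mask(matrix(as.integer((r / semi_row)^2 + (cc / semi_col)^2 <= 1), m, m))
}

raster_square <- function(m, r0, c0, side) {
  x <- matrix(0L, m, m)
  x[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 1L
  as_glia_mask(x)
}

# convex-hull solidity oracle (area / hull area), independent of the package
solidity_oracle <- function(mask) {
  fg <- which(mask == 1L)
  r <- (fg - 1L) %% nrow(mask) + 1L
  cc <- (fg - 1L) %/% nrow(mask) + 1L
  pts <- cbind(r, cc)
  hp <- pts[chull(pts), , drop = FALSE]
  x <- hp[, 2L]; y <- hp[, 1L]
  hull_area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  length(fg) / max(hull_area, length(fg))
}

# dense-polygon elliptic Fourier oracle: Kuhl-Giardina integrals evaluated on
# an arbitrary polygon (not a chain code), used to verify efd_coefficients
efd_polygon_oracle <- function(x, y, N) {
  dx <- diff(c(x, x[1L])); dy <- diff(c(y, y[1L]))
  dt <- sqrt(dx^2 + dy^2)
  tt <- cumsum(dt); T <- tt[length(tt)]; t0 <- c(0, tt[-length(tt)])
  coef <- matrix(0, N, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(N)) {
    w <- 2 * n * pi / T
    k <- T / (2 * n^2 * pi^2)
    cosd <- cos(w * tt) - cos(w * t0)
    sind <- sin(w * tt) - sin(w * t0)
    coef[n, ] <- k * c(sum(dx / dt * cosd), sum(dx / dt * sind),
                       sum(dy / dt * cosd), sum(dy / dt * sind))
  }
  coef
}

# brute-force Zernike moment: direct double sum over foreground pixels with
# an independently coded radial polynomial (explicit factorial series)
zernike_oracle <- function(mask, n, m) {
  fg <- which(mask == 1L)
  nr <- nrow(mask)
  r0 <- (fg - 1L) %% nr + 1L
  c0 <- (fg - 1L) %/% nr + 1L
  dy <- r0 - mean(r0); dx <- c0 - mean(c0)
  rad <- sqrt(dx^2 + dy^2); R <- max(rad)
  r <- rad / R
  keep <- r <= 1
  th <- atan2(dy[keep], dx[keep])
  r <- r[keep]
  Rnm <- 0
  for (k in 0:((n - m) / 2)) {
    Rnm <- Rnm + (-1)^k * gamma(n - k + 1) /
      (gamma(k + 1) * gamma((n + m) / 2 - k + 1) * gamma((n - m) / 2 - k + 1)) *
      r^(n - 2 * k)
  }
  Mod(sum(Rnm * exp(-1i * m * th)) * (n + 1) / pi / R^2)
}

# scalar LSTM rollout oracle: every gate computed element by element with
# explicit loops over units (no matrix products)
lstm_scalar_oracle <- function(xseq, w, H) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); cs <- numeric(H)
  for (t in seq_len(nrow(xseq))) {
    hn <- numeric(H); cn <- numeric(H)
    for (u in seq_len(H)) {
      pre <- function(block) {
        row <- (block - 1L) * H + u
        s <- w$b[row]
        for (k in seq_len(ncol(w$W))) s <- s + w$W[row, k] * xseq[t, k]
        for (k in seq_len(H)) s <- s + w$U[row, k] * h[k]
        s
      }
      f <- sig(pre(1L)); i <- sig(pre(2L)); o <- sig(pre(3L)); g <- tanh(pre(4L))
      cn[u] <- f * cs[u] + i * g
      hn[u] <- o * tanh(cn[u])
    }
    h <- hn; cs <- cn
  }
  h
}

# exact 1-D optimal transport via the quantile-function coupling:
# W1 = integral over u in (0,1) of |Qp(u) - Qq(u)|, evaluated exactly by
# merging the two step-function breakpoints (independent of the CDF-sum route)
wasserstein_quantile_oracle <- function(p, q, bin_width = 1) {
  cp <- cumsum(p / sum(p)); cq <- cumsum(q / sum(q))
  br <- sort(unique(pmin(pmax(c(0, cp, cq, 1), 0), 1)))
  tot <- 0
  for (k in seq_len(length(br) - 1L)) {
    u <- (br[k] + br[k + 1L]) / 2
    Qp <- which(cp >= u - 1e-15)[1L]
    Qq <- which(cq >= u - 1e-15)[1L]
    tot <- tot + (br[k + 1L] - br[k]) * abs(Qp - Qq)
  }
  tot * bin_width
}

# Mann-Whitney AUC oracle: pairwise comparison statistic
auc_mw_oracle <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# memoised small synthetic dataset written to disk once per test session
local_dataset_cache <- new.env(parent = emptyenv())
tiny_dataset <- function(n = 16, p = 16, seed = 7, key = "default", ...) {
  if (!is.null(local_dataset_cache[[key]])) return(local_dataset_cache[[key]])
  dir <- file.path(tempdir(), paste0("glia_fix_", key))
  man <- generate_dataset(n, 0.5, p = p, seed = seed, out_dir = dir, ...)
  bundle <- load_dataset(man)
  out <- list(dir = dir, manifest = man, bundle = bundle, p = p)
  local_dataset_cache[[key]] <- out
  out
}

tiny_config <- function(..., epochs = 4) {
  glia_config(h = 8, epochs = epochs, k_folds = 2, batch_size = 8,
              hidden_size = 6, seed = 11, ...)
}
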