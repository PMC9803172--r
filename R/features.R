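#' Zernike moment magnitudes (10 features)
#'
#' Foreground pixels are mapped to the unit disk centred at the foreground
#' centroid with radius equal to the maximum centroid-to-pixel distance
#' (pixels outside the disk are dropped), which makes the magnitudes
#' translation- and scale-invariant. The moment of radial order `n` and
#' repetition `m` is
#' `Z_nm = (n+1)/pi * sum_px R_nm(r) exp(-i m theta) / R^2`
#' (the `1/R^2` factor is the pixel area element in unit-disk coordinates, so
#' the sum approximates the area integral and `|Z_00|` of a disk is ~1).
#' The first 10 valid index pairs in lexicographic order with
#' `n >= m >= 0`, `n - m` even are used:
#' (0,0),(1,1),(2,0),(2,2),(3,1),(3,3),(4,0),(4,2),(4,4),(5,1).
#'
#' @param mask `glia_mask`.
#' @return Named numeric vector of 10 magnitudes `|Z_nm|`.
#' @export
zernike_block <- function(mask) {
  fg <- which(mask == 1L)
  if (!length(fg)) abort_glia("empty mask", "glia_empty_mask")
  nr <- nrow(mask)
  r0 <- (fg - 1L) %% nr + 1L
  c0 <- (fg - 1L) %/% nr + 1L
  cen <- c(mean(r0), mean(c0))
  dy <- r0 - cen[1L]; dx <- c0 - cen[2L]
  rad <- sqrt(dx * dx + dy * dy)
  R <- max(rad)
  if (R == 0) R <- 1
  r <- rad / R
  keep <- r <= 1
  r <- r[keep]
  theta <- atan2(dy[keep], dx[keep])
  pairs <- zernike_pairs()
  out <- vapply(seq_len(nrow(pairs)), function(i) {
    n <- pairs[i, 1L]; m <- pairs[i, 2L]
    Rnm <- zernike_radial(n, m, r)
    z <- sum(Rnm * exp(-1i * m * theta)) * (n + 1) / pi / (R * R)
    Mod(z)
  }, numeric(1))
  names(out) <- paste0("zernike_", seq_along(out) - 1L)
  out
}

zernike_pairs <- function() {
  cbind(n = c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L),
        m = c(0L, 1L, 0L, 2L, 1L, 3L, 0L, 2L, 4L, 1L))
}

#' Radial Zernike polynomial `R_nm(r)`
#'
#' @param n Radial order; `m` repetition with `n >= m >= 0`, `n - m` even.
#' @param m Repetition.
#' @param r Radii in `[0, 1]`.
#' @return `R_nm` evaluated at `r`.
#' @export
zernike_radial <- function(n, m, r) {
  stopifnot(n >= m, m >= 0, (n - m) %% 2 == 0)
  out <- numeric(length(r))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
    out <- out + coef * r^(n - 2 * k)
  }
  out
}

#' Chord-length histogram (10 features)
#'
#' For each boundary point the tangent is estimated by a central difference
#' over the +/-2 contour neighbours; the chord is the segment of the inward
#' normal ray from the point to its first exit from the foreground. Chord
#' lengths are normalised by their maximum and histogrammed on `[0, 1]` with
#' `bins` equal-width bins (last bin right-closed); the histogram is
#' normalised to sum 1, so the block is scale-invariant.
#'
#' @param contour `glia_contour` from [trace_contour()].
#' @param mask The `glia_mask` the contour was traced from (used for the ray
#'   march through the foreground).
#' @param bins Number of histogram bins.
#' @return Named numeric vector of `bins` proportions summing to 1.
#' @export
chord_block <- function(contour, mask, bins = 10L) {
  pts <- contour$points
  n <- nrow(pts)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- seq_len(n)
  fwd <- ((idx - 1L + 2L) %% n) + 1L
  bwd <- ((idx - 1L - 2L) %% n) + 1L
  tg <- pts[fwd, , drop = FALSE] - pts[bwd, , drop = FALSE]
  lens <- rep(NA_real_, n)
  step <- 0.25
  max_steps <- ceiling(1.5 * max(nr, nc) / step)
  inside <- function(r, cc) {
    ri <- round(r); ci <- round(cc)
    ri >= 1 && ri <= nr && ci >= 1 && ci <= nc && mask[ri, ci] == 1L
  }
  for (i in idx) {
    t_norm <- sqrt(sum(tg[i, ]^2))
    if (t_norm == 0) next
    nvec <- c(-tg[i, 2L], tg[i, 1L]) / t_norm
    # pick the inward of the two normal directions
    dir <- NULL
    for (cand in list(nvec, -nvec)) {
      probe <- pts[i, ] + cand * 1.0
      if (inside(probe[1L], probe[2L])) { dir <- cand; break }
    }
    if (is.null(dir)) next
    s <- step
    for (k in seq_len(max_steps)) {
      q <- pts[i, ] + dir * s
      if (!inside(q[1L], q[2L])) break
      s <- s + step
    }
    lens[i] <- s
  }
  ok <- !is.na(lens)
  if (mean(ok) < 0.5) abort_glia("chord failure: no valid chord for > 50% of points",
                                 "glia_chord_failure")
  lens <- lens[ok] / max(lens[ok])
  bin <- pmin(floor(lens * bins) + 1L, bins)
  h <- tabulate(bin, nbins = bins)
  out <- h / sum(h)
  names(out) <- paste0("chord_", seq_len(bins) - 1L)
  out
}

#' Elliptic Fourier descriptors (37 features for N = 10 harmonics)
#'
#' Kuhl-Giardina coefficients `(a_n, b_n, c_n, d_n)` for `n = 1..N` computed
#' from the Freeman chain code, then normalised for starting point (first
#' harmonic phase), rotation (semi-major axis of the first ellipse aligned
#' with the x-axis), scale (division by the first semi-major magnitude) and
#' reflection (`d_1 > 0`). A residual two-fold phase ambiguity (start shifted
#' by half a period combined with a 180 degree rotation, which flips the sign
#' of every even harmonic) is resolved by requiring the largest-magnitude
#' even-harmonic coefficient to be positive. After normalisation
#' `a_1 = 1, b_1 = 0, c_1 = 0` are constants and are dropped, leaving
#' `4N - 3` features ordered `d_1, a_2, b_2, c_2, d_2, ..., d_N`.
#'
#' @param contour `glia_contour`.
#' @param N Number of harmonics.
#' @return Named numeric vector of `4 * N - 3` normalised coefficients.
#' @export
efd_block <- function(contour, N = 10L) {
  coef <- efd_coefficients(contour, N)
  coef <- efd_normalize(coef)
  out <- c(coef[1L, 4L], as.vector(t(coef[-1L, , drop = FALSE])))
  names(out) <- paste0("efd_", seq_along(out) - 1L)
  out
}

#' Raw Kuhl-Giardina elliptic Fourier coefficients
#'
#' @param contour `glia_contour`.
#' @param N Number of harmonics.
#' @return `N x 4` matrix with columns `a, b, c, d` (x-cosine, x-sine,
#'   y-cosine, y-sine), y taken as `-row` so the frame is right-handed.
#' @export
efd_coefficients <- function(contour, N = 10L) {
  pts <- contour$points
  dxy <- rbind(diff(pts), pts[1L, , drop = FALSE] - pts[nrow(pts), , drop = FALSE])
  dx <- dxy[, 2L]                 # x = col
  dy <- -dxy[, 1L]                # y = -row
  dt <- sqrt(dx^2 + dy^2)
  if (sum(dt) == 0) abort_glia("zero-length contour", "glia_contour_error")
  t <- cumsum(dt)
  T <- t[length(t)]
  t0 <- c(0, t[-length(t)])
  coef <- matrix(0, N, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(N)) {
    w <- 2 * n * pi / T
    cosd <- cos(w * t) - cos(w * t0)
    sind <- sin(w * t) - sin(w * t0)
    k <- T / (2 * n^2 * pi^2)
    coef[n, ] <- k * c(sum(dx / dt * cosd), sum(dx / dt * sind),
                       sum(dy / dt * cosd), sum(dy / dt * sind))
  }
  coef
}

efd_normalize <- function(coef) {
  N <- nrow(coef)
  a1 <- coef[1L, 1L]; b1 <- coef[1L, 2L]; c1 <- coef[1L, 3L]; d1 <- coef[1L, 4L]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 - b1^2 + c1^2 - d1^2)
  for (n in seq_len(N)) {
    M <- matrix(coef[n, ], 2L, 2L, byrow = TRUE)     # [a b; c d]
    Rt <- matrix(c(cos(n * theta), -sin(n * theta),
                   sin(n * theta), cos(n * theta)), 2L, 2L, byrow = TRUE)
    coef[n, ] <- as.vector(t(M %*% Rt))
  }
  psi <- atan2(coef[1L, 3L], coef[1L, 1L])
  Rp <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2L, 2L, byrow = TRUE)
  for (n in seq_len(N)) {
    M <- matrix(coef[n, ], 2L, 2L, byrow = TRUE)
    coef[n, ] <- as.vector(t(Rp %*% M))
  }
  scale <- abs(coef[1L, 1L])
  if (scale == 0) abort_glia("degenerate first harmonic", "glia_contour_error")
  coef <- coef / scale
  if (coef[1L, 1L] < 0) coef <- -coef                 # semi-major toward +x
  if (coef[1L, 4L] < 0) coef[, 3:4] <- -coef[, 3:4]   # reflection: d1 > 0
  if (N >= 2L) {                                       # even-harmonic phase fold
    ev <- seq(2L, N, by = 2L)
    v <- as.vector(coef[ev, , drop = FALSE])
    if (length(v) && v[which.max(abs(v))] < 0) {
      coef[ev, ] <- -coef[ev, ]
    }
  }
  coef
}

#' Reconstruct contour points from elliptic Fourier coefficients
#'
#' Inverse of the harmonic expansion (used to check the monotone
#' approximation property of increasing `N`).
#'
#' @param coef `N x 4` coefficient matrix (raw, from [efd_coefficients()]).
#' @param n_points Number of samples along the period.
#' @param locus Optional `(x0, y0)` bias term; defaults to `(0, 0)`.
#' @return `n_points x 2` matrix of (x, y).
#' @export
efd_reconstruct <- function(coef, n_points = 200L, locus = c(0, 0)) {
  tt <- seq(0, 1, length.out = n_points)
  x <- rep(locus[1L], n_points); y <- rep(locus[2L], n_points)
  for (n in seq_len(nrow(coef))) {
    x <- x + coef[n, 1L] * cos(2 * n * pi * tt) + coef[n, 2L] * sin(2 * n * pi * tt)
    y <- y + coef[n, 3L] * cos(2 * n * pi * tt) + coef[n, 4L] * sin(2 * n * pi * tt)
  }
  cbind(x, y)
}

#' General geometric shape features (10 features)
#'
#' In order: area (px), perimeter (contour traversal length `T`),
#' eccentricity of the second-moment ellipse, major and minor axis lengths
#' (4 sqrt of the covariance eigenvalues, the ellipse-with-equal-moments
#' convention), bounding box as (min_row, min_col, height, width) with
#' 0-based corner, and equivalent diameter `sqrt(4 area / pi)`. The bounding
#' box corner coordinates are the only position-bearing entries of the whole
#' feature vector.
#'
#' @param mask `glia_mask`.
#' @param contour Optional precomputed `glia_contour` (re-traced if missing).
#' @return Named numeric vector of 10 features.
#' @export
general_block <- function(mask, contour = NULL) {
  fg <- which(mask == 1L)
  if (!length(fg)) abort_glia("empty mask", "glia_empty_mask")
  if (is.null(contour)) contour <- trace_contour(mask)
  nr <- nrow(mask)
  r0 <- (fg - 1L) %% nr + 1L
  c0 <- (fg - 1L) %/% nr + 1L
  area <- length(fg)
  mu_rr <- mean((r0 - mean(r0))^2)
  mu_cc <- mean((c0 - mean(c0))^2)
  mu_rc <- mean((r0 - mean(r0)) * (c0 - mean(c0)))
  ev <- eigen(matrix(c(mu_rr, mu_rc, mu_rc, mu_cc), 2L, 2L), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1L]); minor <- 4 * sqrt(ev[2L])
  ecc <- if (ev[1L] > 0) sqrt(1 - ev[2L] / ev[1L]) else 0
  out <- c(area, contour$T, ecc, major, minor,
           min(r0) - 1L, min(c0) - 1L, diff(range(r0)) + 1L, diff(range(c0)) + 1L,
           sqrt(4 * area / pi))
  names(out) <- paste0("general_", seq_along(out) - 1L)
  out
}

#' Extract the concatenated shape-feature vector for one mask
#'
#' Concatenation order is fixed: zernike (10), general (10), chord (10),
#' efd (37) — 67 features for the full set. A subset returns only the
#' requested blocks in the same relative order.
#'
#' @param mask `glia_mask`.
#' @param subset `"all"` or a character vector over
#'   `c("Mom", "GenShape", "ChordLen", "ElliFou")`.
#' @return Named numeric vector (length 67 for the full set).
#' @export
extract_shape_features <- function(mask, subset = "all") {
  blocks <- resolve_subset(subset)
  need_contour <- any(c("general", "chord", "efd") %in% blocks)
  contour <- if (need_contour) trace_contour(mask) else NULL
  parts <- lapply(blocks, function(b) {
    switch(b,
      zernike = zernike_block(mask),
      general = general_block(mask, contour),
      chord = chord_block(contour, mask),
      efd = efd_block(contour)
    )
  })
  out <- unlist(parts, use.names = TRUE)
  if (identical(blocks, c("zernike", "general", "chord", "efd")) && length(out) != 67L) {
    abort_glia("internal error: full feature vector is not 67-dimensional",
               "glia_feature_length")
  }
  out
}

#' Extract a feature table for a whole dataset
#'
#' @param bundle `glia_bundle` from [load_dataset()] (or any tibble with
#'   `cell_id` and a `mask` list-column).
#' @param subset Feature-family subset, as in [extract_shape_features()].
#' @return Tibble: `cell_id` plus one numeric column per feature.
#' @export
extract_feature_table <- function(bundle, subset = "all") {
  feats <- purrr::map(bundle$mask, extract_shape_features, subset = subset)
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(tibble::tibble(cell_id = bundle$cell_id),
                   tibble::as_tibble(mat))
}
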