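#' 1-D Wasserstein distance between binned distributions
#'
#' For histograms on a shared equal-width grid the optimal-transport
#' distance has the closed form
#' `W1 = bin_width * sum_k |CDF_p(k) - CDF_q(k)|`.
#' Inputs must each sum to 1 within `1e-6` (they are renormalised).
#'
#' @param pdist,qdist Non-negative vectors of equal length summing to 1.
#' @param bin_width Width of one bin (distance between adjacent bin centres).
#' @return Non-negative scalar distance.
#' @export
wasserstein_1d <- function(pdist, qdist, bin_width = 1) {
  stopifnot(length(pdist) == length(qdist))
  if (any(pdist < 0) || any(qdist < 0)) abort_glia("negative mass", "glia_invalid_counts")
  sp <- sum(pdist); sq <- sum(qdist)
  if (abs(sp - 1) > 1e-6 || abs(sq - 1) > 1e-6) {
    abort_glia("distributions must sum to 1 (within 1e-6)", "glia_invalid_counts")
  }
  bin_width * sum(abs(cumsum(pdist / sp) - cumsum(qdist / sq)))
}

#' Lifetime kernel from summed per-component Wasserstein distances
#'
#' `d_ij` is the sum over lifetime components of the 1-D Wasserstein
#' distance between the two cells' per-component histograms;
#' `K_ij = exp(-t d_ij)` with bandwidth `t` (default `1 / median(d)` over
#' off-diagonal entries). `d` is a metric (each summand is), so `K` is
#' symmetric with unit diagonal.
#'
#' @param sequences List of `p x h` lifetime sequences sharing edges.
#' @param bandwidth Positive scalar `t`, or `NULL` for the median heuristic.
#' @param bin_width Bin width forwarded to [wasserstein_1d()].
#' @return List of class `glia_kernel`: `K` (n x n), `d` (distances),
#'   `bandwidth`.
#' @export
lifetime_kernel <- function(sequences, bandwidth = NULL, bin_width = 1) {
  n <- length(sequences)
  dims <- vapply(sequences, dim, integer(2))
  if (any(dims != dims[, 1L])) abort_glia("sequences differ in shape", "glia_shape_mismatch")
  # precompute scaled CDFs once; W1 sums over all components at once
  cdfs <- lapply(sequences, function(s) t(apply(s, 1L, cumsum)))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- bin_width * sum(abs(cdfs[[i]] - cdfs[[j]]))
    }
  }
  if (is.null(bandwidth)) {
    med <- stats::median(d[upper.tri(d)])
    bandwidth <- if (med > 0) 1 / med else 1
  }
  structure(list(K = exp(-bandwidth * d), d = d, bandwidth = bandwidth),
            class = "glia_kernel")
}

#' Gaussian kernel on standardized shape features
#'
#' `K_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` after column
#' standardisation (constant columns are left centred).
#'
#' @param features Numeric matrix or feature tibble.
#' @param sigma Positive bandwidth, or `NULL` for the median pairwise
#'   distance heuristic.
#' @return List of class `glia_kernel`: `K`, `d` (Euclidean distances),
#'   `bandwidth` (sigma).
#' @export
feature_kernel <- function(features, sigma = NULL) {
  X <- as_feature_matrix(features)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  d <- as.matrix(stats::dist(X))
  if (is.null(sigma)) {
    med <- stats::median(d[upper.tri(d)])
    sigma <- if (med > 0) med else 1
  }
  stopifnot(sigma > 0)
  structure(list(K = exp(-d^2 / (2 * sigma^2)), d = d, bandwidth = sigma),
            class = "glia_kernel")
}

center_kernel <- function(K) {
  n <- nrow(K)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% K %*% J
}

#' Regularized kernel canonical correlation analysis
#'
#' Hardoon-style KCCA between a lifetime kernel and a feature kernel: both
#' kernels are centred, the regularised generalised eigenproblem
#' `(K_L + kappa I)^{-1} K_F (K_F + kappa I)^{-1} K_L alpha = rho^2 alpha`
#' is solved, and the data are projected on the leading directions of each
#' view.
#'
#' @param KL,KF `glia_kernel` objects (or plain kernel matrices) on the same
#'   n cells: lifetime view and feature view.
#' @param reg Regularisation `kappa > 0` (default `0.1 n`).
#' @param n_dirs Number of canonical directions (default 2).
#' @param labels Optional 0/1 labels for per-class summaries.
#' @return List of class `glia_kcca`: `correlations` (non-increasing, in
#'   `[0, 1]`), `proj_lifetime` and `proj_feature` (n x n_dirs), `reg`, and
#'   (with labels) `class_summary` — per-class projected variance along the
#'   first direction and per-class correlation between the two views'
#'   first projections.
#' @export
kcca <- function(KL, KF, reg = NULL, n_dirs = 2L, labels = NULL) {
  Kl <- if (inherits(KL, "glia_kernel")) KL$K else KL
  Kf <- if (inherits(KF, "glia_kernel")) KF$K else KF
  n <- nrow(Kl)
  stopifnot(nrow(Kf) == n, ncol(Kl) == n, ncol(Kf) == n)
  if (is.null(reg)) reg <- 0.1 * n
  stopifnot(reg > 0)
  Klc <- center_kernel(Kl)
  Kfc <- center_kernel(Kf)
  Rl <- Klc + reg * diag(n)
  Rf <- Kfc + reg * diag(n)
  M <- tryCatch(
    solve(Rl, Kfc) %*% solve(Rf, Klc),
    error = function(e) abort_glia(
      "singular KCCA system; increase the regularization kappa", "glia_kcca_singular")
  )
  eg <- eigen(M)
  vals <- Re(eg$values)
  vecs <- Re(eg$vectors)
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord][seq_len(n_dirs)]
  alpha <- vecs[, ord[seq_len(n_dirs)], drop = FALSE]
  # paired feature-view directions: beta proportional to (K_F + kI)^-1 K_L alpha
  beta <- solve(Rf, Klc %*% alpha)
  proj_l <- Klc %*% alpha
  proj_f <- Kfc %*% beta
  # canonical correlations measured on the projections
  cors <- vapply(seq_len(n_dirs), function(k) {
    if (stats::sd(proj_l[, k]) == 0 || stats::sd(proj_f[, k]) == 0) return(0)
    abs(stats::cor(proj_l[, k], proj_f[, k]))
  }, numeric(1))
  ord2 <- order(cors, decreasing = TRUE)
  cors <- cors[ord2]
  proj_l <- proj_l[, ord2, drop = FALSE]
  proj_f <- proj_f[, ord2, drop = FALSE]
  # fix sign: first element of each lifetime direction non-negative
  for (k in seq_len(ncol(proj_l))) {
    if (proj_l[1L, k] < 0) proj_l[, k] <- -proj_l[, k]
    if (proj_f[1L, k] < 0) proj_f[, k] <- -proj_f[, k]
  }
  out <- list(correlations = pmin(pmax(cors, 0), 1),
              proj_lifetime = proj_l, proj_feature = proj_f, reg = reg)
  if (!is.null(labels)) {
    out$class_summary <- dplyr::bind_rows(lapply(sort(unique(labels)), function(cl) {
      sel <- labels == cl
      tibble::tibble(
        label = cl,
        n = sum(sel),
        proj_variance = stats::var(proj_l[sel, 1L]),
        correlation = if (sum(sel) > 2L) {
          abs(stats::cor(proj_l[sel, 1L], proj_f[sel, 1L]))
        } else {
          NA_real_
        }
      )
    }))
  }
  class(out) <- "glia_kcca"
  out
}

#' @export
print.glia_kcca <- function(x, ...) {
  cat(sprintf("<glia_kcca> canonical correlations: %s (kappa = %.3g)\n",
              paste(sprintf("%.3f", x$correlations), collapse = ", "), x$reg))
  invisible(x)
}

#' Tidy KCCA projections
#'
#' @param x `glia_kcca`.
#' @param ... Unused.
#' @return Tibble: `sample`, `view`, `dim1`, `dim2`.
#' @method tidy glia_kcca
#' @export
tidy.glia_kcca <- function(x, ...) {
  n <- nrow(x$proj_lifetime)
  dplyr::bind_rows(
    tibble::tibble(sample = seq_len(n), view = "lifetime",
                   dim1 = x$proj_lifetime[, 1L],
                   dim2 = if (ncol(x$proj_lifetime) > 1L) x$proj_lifetime[, 2L] else NA_real_),
    tibble::tibble(sample = seq_len(n), view = "feature",
                   dim1 = x$proj_feature[, 1L],
                   dim2 = if (ncol(x$proj_feature) > 1L) x$proj_feature[, 2L] else NA_real_)
  )
}

#' One-row KCCA summary
#'
#' @param x `glia_kcca`.
#' @param ... Unused.
#' @return Tibble with the canonical correlations and regularisation.
#' @method glance glia_kcca
#' @export
glance.glia_kcca <- function(x, ...) {
  tibble::tibble(correlation_1 = x$correlations[1L],
                 correlation_2 = if (length(x$correlations) > 1L) x$correlations[2L] else NA_real_,
                 reg = x$reg)
}

#' Shape-lifetime KCCA for a dataset bundle
#'
#' Convenience wrapper: extracts features, builds sequences with
#' dataset-wide edges, forms both kernels with the median heuristics and
#' runs [kcca()] jointly, inspecting the two classes on the shared
#' projection.
#'
#' @param bundle `glia_bundle`.
#' @param config `glia_config` (for `h` and `seed`).
#' @param features Optional precomputed feature tibble.
#' @param reg Regularisation forwarded to [kcca()].
#' @return `glia_kcca` with `class_summary` and a `cells` tibble
#'   (cell_id, label, per-view projections).
#' @export
kcca_analysis <- function(bundle, config = glia_config(), features = NULL, reg = NULL) {
  if (is.null(features)) features <- extract_feature_table(bundle, "all")
  edges <- compute_bin_edges(bundle$counts, config$h)
  seqs <- lapply(bundle$counts, decay_to_sequence, edges = edges)
  KL <- lifetime_kernel(seqs, bin_width = edges[2L] - edges[1L])
  KF <- feature_kernel(features)
  res <- kcca(KL, KF, reg = reg, labels = bundle$label)
  res$cells <- tibble::tibble(
    cell_id = bundle$cell_id, label = bundle$label,
    lifetime_dim1 = res$proj_lifetime[, 1L], lifetime_dim2 = res$proj_lifetime[, 2L],
    feature_dim1 = res$proj_feature[, 1L], feature_dim2 = res$proj_feature[, 2L]
  )
  res
}
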