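#' Histogram bin edges shared across a dataset
#'
#' Edges span `[0, M]` in `h` equal-width bins, where `M` is the global
#' maximum masked per-pixel photon count over all *training* stacks and
#' lifetime components; using one edge set across the dataset makes the
#' per-component histograms comparable as a multivariate time series. The
#' caller is responsible for passing training cells only, so no test
#' information leaks into the edges.
#'
#' @param counts_list List of `p x n_masked` count matrices (foreground-pixel
#'   counts per component), e.g. the `counts` column of a `glia_bundle`.
#' @param h Number of bins (`>= 2`).
#' @return Numeric vector of `h + 1` ascending edges; `[0, 1]` span when the
#'   data are all zero.
#' @export
compute_bin_edges <- function(counts_list, h) {
  stopifnot(length(counts_list) >= 1, h >= 2)
  M <- max(vapply(counts_list, function(x) if (length(x)) max(x) else 0, numeric(1)))
  if (M <= 0) M <- 1
  seq(0, M, length.out = h + 1L)
}

#' Convert a decay stack to the p x h lifetime sequence
#'
#' For each lifetime component the masked pixels' photon counts are
#' histogrammed with the shared edges (last bin right-closed; counts above
#' the top edge are clipped into the top bin) and divided by the number of
#' masked pixels, so every row is a probability vector over bins.
#'
#' @param counts `p x n_masked` matrix of foreground-pixel counts (from
#'   [load_dataset()]), or a `p x m x m` stack together with `mask`.
#' @param edges `h + 1` ascending shared bin edges.
#' @param mask Optional `glia_mask`; required when `counts` is a 3-D stack.
#' @return `p x h` matrix; each row sums to 1.
#' @export
decay_to_sequence <- function(counts, edges, mask = NULL) {
  if (length(dim(counts)) == 3L) {
    if (is.null(mask)) abort_glia("mask required for a 3-D stack", "glia_empty_mask")
    fg <- which(mask == 1L)
    if (!length(fg)) abort_glia("empty mask", "glia_empty_mask")
    counts <- matrix(counts, dim(counts)[1L], length(mask))[, fg, drop = FALSE]
  }
  stopifnot(is.matrix(counts), all(diff(edges) > 0))
  h <- length(edges) - 1L
  npix <- ncol(counts)
  if (npix == 0L) abort_glia("empty mask", "glia_empty_mask")
  # left-closed bins, right-closed last bin; clip above top edge into top bin
  bin <- findInterval(counts, edges, rightmost.closed = TRUE)
  bin <- matrix(pmin.int(pmax.int(bin, 1L), h), nrow(counts), npix)
  X <- t(apply(bin, 1L, tabulate, nbins = h)) / npix
  dimnames(X) <- NULL
  X
}

#' Fit a bi-exponential decay to one curve
#'
#' Nonlinear least squares of
#' `f(t) = a1 exp(-t / tau1) + a2 exp(-t / tau2)` (optionally convolved with
#' a provided instrument response, causally, as in the simulator) against the
#' measured curve, with multi-start over 4 lifetime-pair initialisations
#' spanning the component range; returns the best fit by residual and
#' enforces `tau1 <= tau2` by swapping.
#'
#' @param curve Non-negative numeric vector of length `p` (counts per
#'   component, t = 0..p-1).
#' @param irf Optional IRF kernel (normalised internally); `NULL` for none.
#' @return A list of class `glia_decay_fit`: `a1, a2, tau1, tau2, residual`
#'   (sum of squares) and `converged`. Non-convergence of every start yields
#'   `residual = Inf` and `converged = FALSE`.
#' @export
fit_biexponential <- function(curve, irf = NULL) {
  if (any(curve < 0)) abort_glia("negative counts in curve", "glia_invalid_counts")
  if (all(curve == 0)) abort_glia("all-zero curve", "glia_invalid_counts")
  p <- length(curve)
  t <- 0:(p - 1L)
  if (!is.null(irf)) irf <- irf / sum(irf)
  model_curve <- function(a1, a2, tau1, tau2) {
    f <- a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
    if (!is.null(irf)) {
      f <- stats::convolve(f, rev(irf), type = "open")[seq_len(p)]
    }
    f
  }
  tot <- max(curve)
  starts <- list(c(p / 50, p / 5), c(p / 20, p / 2.5), c(p / 100, p / 10), c(p / 10, p / 1.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a1 = tot / 2, a2 = tot / 2, tau1 = s[1L], tau2 = s[2L]),
        fn = function(par) {
          model_curve(par[1L], par[2L], par[3L], par[4L]) - curve
        },
        lower = c(0, 0, 1e-3, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(a1 = NA_real_, a2 = NA_real_, tau1 = NA_real_,
                          tau2 = NA_real_, residual = Inf, converged = FALSE),
                     class = "glia_decay_fit"))
  }
  par <- best$par
  if (par[["tau1"]] > par[["tau2"]]) {
    par <- c(a1 = par[["a2"]], a2 = par[["a1"]],
             tau1 = par[["tau2"]], tau2 = par[["tau1"]])
  }
  structure(list(a1 = par[["a1"]], a2 = par[["a2"]], tau1 = par[["tau1"]],
                 tau2 = par[["tau2"]], residual = best$rss, converged = TRUE),
            class = "glia_decay_fit")
}

#' Amplitude-weighted mean lifetime over pixels
#'
#' Each pixel's amplitudes are first normalised to `a1 + a2 = 1`; the
#' returned summary is the mean over pixels of `a1 tau1 + a2 tau2` (the
#' standard FLIM amplitude-weighted mean lifetime).
#'
#' @param fits A list of `glia_decay_fit` objects (one per pixel).
#' @return A single numeric mean lifetime, in component units.
#' @export
mean_lifetime <- function(fits) {
  if (!length(fits)) abort_glia("empty fit set", "glia_invalid_counts")
  vals <- vapply(fits, function(f) {
    s <- f$a1 + f$a2
    (f$a1 * f$tau1 + f$a2 * f$tau2) / s
  }, numeric(1))
  mean(vals)
}

#' Per-cell mean-lifetime feature
#'
#' The scalar lifetime summary used by the `shape_plus_tau` modality. The
#' default `"pooled"` route fits one bi-exponential to the cell's summed
#' masked decay and returns its amplitude-weighted mean lifetime;
#' `"per_pixel"` fits every masked pixel individually and averages the
#' per-pixel mean lifetimes (the textbook definition; far slower).
#'
#' @param counts `p x n_masked` count matrix for one cell.
#' @param irf Optional IRF kernel passed to [fit_biexponential()].
#' @param method `"pooled"` or `"per_pixel"`.
#' @return Single numeric `tau_mean`, in component units.
#' @export
cell_tau_mean <- function(counts, irf = NULL, method = c("pooled", "per_pixel")) {
  method <- match.arg(method)
  if (method == "pooled") {
    fit <- fit_biexponential(rowSums(counts), irf)
    mean_lifetime(list(fit))
  } else {
    fits <- lapply(seq_len(ncol(counts)), function(j) fit_biexponential(counts[, j], irf))
    ok <- vapply(fits, function(f) f$converged, logical(1))
    if (!any(ok)) abort_glia("no pixel fit converged", "glia_invalid_counts")
    mean_lifetime(fits[ok])
  }
}
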