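test_that("bin edges span the training maximum in equal widths", {
  counts <- list(matrix(c(0, 15, 80, 3), 2, 2), matrix(c(7, 7, 7, 7), 2, 2))
  expect_equal(compute_bin_edges(counts, 4), c(0, 20, 40, 60, 80))
  # degenerate all-zero data falls back to a [0, 1] span
  expect_equal(compute_bin_edges(list(matrix(0, 2, 2)), 2), c(0, 0.5, 1))
})

test_that("sequences match a brute-force per-pixel tally", {
  set.seed(8)
  counts <- matrix(sample(0:9, 5 * 5, TRUE), 5, 5)  # p = 5 components, 5 px
  edges <- c(0, 2, 4, 6, 10)
  X <- decay_to_sequence(counts, edges)
  expect_equal(dim(X), c(5L, 4L))
  for (t in 1:5) {
    tally <- c(
      sum(counts[t, ] >= 0 & counts[t, ] < 2),
      sum(counts[t, ] >= 2 & counts[t, ] < 4),
      sum(counts[t, ] >= 4 & counts[t, ] < 6),
      sum(counts[t, ] >= 6 & counts[t, ] <= 10)
    )
    expect_equal(X[t, ], tally / 5)
  }
  # constant plane is one-hot at its bin
  Xc <- decay_to_sequence(matrix(3, 4, 9), edges)
  expect_equal(Xc, matrix(rep(c(0, 1, 0, 0), 4), 4, byrow = TRUE))
})

test_that("sequence rows are probability vectors invariant to pixel order", {
  set.seed(9)
  counts <- matrix(rpois(16 * 40, 20), 16, 40)
  edges <- compute_bin_edges(list(counts), 8)
  X <- decay_to_sequence(counts, edges)
  expect_equal(rowSums(X), rep(1, 16))
  perm <- counts[, sample(40)]
  expect_equal(decay_to_sequence(perm, edges), X)
  # counts above the top edge clip into the top bin
  Xhi <- decay_to_sequence(matrix(999, 3, 4), edges)
  expect_equal(Xhi[, 8], rep(1, 3))
})

test_that("bi-exponential fits recover noiseless parameters", {
  t <- 0:255
  curve <- 300 * exp(-t / 5) + 700 * exp(-t / 40)
  fit <- fit_biexponential(curve)
  expect_true(fit$converged)
  expect_equal(c(fit$a1, fit$a2, fit$tau1, fit$tau2), c(300, 700, 5, 40),
               tolerance = 0.01)
  expect_lte(fit$tau1, fit$tau2)

  # single-exponential input: one amplitude dominates
  fit1 <- fit_biexponential(1000 * exp(-t / 12))
  expect_gte(max(fit1$a1, fit1$a2) / (fit1$a1 + fit1$a2), 0.99)

  expect_error(fit_biexponential(rep(0, 64)), class = "glia_invalid_counts")
})

test_that("parameter recovery holds across 50 noiseless draws", {
  set.seed(5)
  t <- 0:255
  errs <- replicate(50, {
    tau1 <- runif(1, 2, 12)
    tau2 <- tau1 * runif(1, 4, 8)
    fr <- runif(1, 0.2, 0.8)
    a <- 1000 * c(fr, 1 - fr)
    fit <- fit_biexponential(a[1] * exp(-t / tau1) + a[2] * exp(-t / tau2))
    max(abs(c(fit$a1 - a[1], fit$a2 - a[2], fit$tau1 - tau1, fit$tau2 - tau2)) /
          c(a, tau1, tau2))
  })
  expect_lt(median(errs), 0.02)
})

test_that("tau ordering is enforced on noisy random curves", {
  set.seed(6)
  t <- 0:63
  for (i in 1:5) {
    curve <- rpois(64, 50 * exp(-t / runif(1, 3, 20)) + 1)
    fit <- fit_biexponential(curve)
    if (fit$converged) expect_lte(fit$tau1, fit$tau2)
  }
})

test_that("mean lifetime is the amplitude-weighted pixel average", {
  f <- function(a1, a2, t1, t2) {
    structure(list(a1 = a1, a2 = a2, tau1 = t1, tau2 = t2,
                   residual = 0, converged = TRUE), class = "glia_decay_fit")
  }
  expect_equal(mean_lifetime(list(f(0.5, 0.5, 2, 2))), 2)
  expect_equal(mean_lifetime(list(f(1, 0, 0.4, 9))), 0.4)
  expect_equal(mean_lifetime(list(f(1, 0, 1, 5), f(0.5, 0.5, 2, 4))), 2)
  # amplitudes are fraction-normalised before combining
  expect_equal(mean_lifetime(list(f(200, 200, 2, 2))), 2)
  expect_error(mean_lifetime(list()), class = "glia_invalid_counts")
})

test_that("the IRF-convolved fit recovers parameters through the instrument blur", {
  t <- 0:127
  irf <- exp(-((-9:9)^2) / 8)
  clean <- 400 * exp(-t / 6) + 600 * exp(-t / 30)
  observed <- stats::convolve(clean, rev(irf / sum(irf)), type = "open")[1:128]
  fit <- fit_biexponential(observed, irf = irf)
  expect_equal(c(fit$a1, fit$a2, fit$tau1, fit$tau2), c(400, 600, 6, 30),
               tolerance = 0.01)
})

test_that("pooled and per-pixel tau summaries agree on homogeneous cells", {
  mask <- raster_disk(32, c(16, 16), 5)
  prm <- decay_sim_params(irf_fwhm = 0, peak_counts = 5000,
                          background_counts = 0, noise = "none")
  stack <- simulate_decay_stack(mask, prm, 0L, p = 64, seed = 2)
  counts <- matrix(stack, 64, 32 * 32)[, which(mask == 1L)]
  pooled <- cell_tau_mean(counts, method = "pooled")
  cls <- prm$resting
  expected <- (cls$a1 * cls$tau1 + cls$a2 * cls$tau2) / (cls$a1 + cls$a2)
  expect_equal(pooled, expected, tolerance = 0.05)
  per_px <- cell_tau_mean(counts[, 1:4], method = "per_pixel")
  expect_equal(per_px, expected, tolerance = 0.05)
})
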