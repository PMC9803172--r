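test_that("zernike radial polynomial matches its closed form", {
  expect_equal(zernike_radial(4, 0, 1), 6 * 1 - 6 * 1 + 1)
  r <- seq(0, 1, by = 0.1)
  expect_equal(zernike_radial(4, 0, r), 6 * r^4 - 6 * r^2 + 1)
  expect_equal(zernike_radial(3, 1, r), 3 * r^3 - 2 * r)
  expect_equal(zernike_radial(2, 2, r), r^2)
})

test_that("zernike block matches the direct double-sum oracle", {
  mask <- generate_mask(0L, seed = 31)
  z <- zernike_block(mask)
  pairs <- gliastate:::zernike_pairs()
  oracle <- vapply(seq_len(nrow(pairs)), function(i) {
    zernike_oracle(mask, pairs[i, 1L], pairs[i, 2L])
  }, numeric(1))
  expect_equal(unname(z), oracle, tolerance = 1e-10)
})

test_that("odd-repetition zernike magnitudes of a centered disk vanish", {
  disk <- raster_disk(64, c(32, 32), 20)
  z <- zernike_block(disk)
  # (n,m) pairs with m odd: indices 2, 5, 6, 10
  expect_true(all(z[c(2, 5, 6, 10)] < 1e-2))
  expect_gt(z[1], 0.9)   # |Z_00| of a disk ~ area/pi in unit-disk coords = 1
})

test_that("zernike magnitudes are invariant to 90-degree rotation", {
  for (seed in c(3, 14)) {
    mask <- generate_mask(seed %% 2L, seed = seed)
    rot <- as_glia_mask(t(unclass(mask))[ncol(mask):1, ])
    z0 <- zernike_block(mask); z1 <- zernike_block(rot)
    expect_lt(max(abs(z0 - z1) / pmax(abs(z0), 1e-6)), 0.02)
  }
})

test_that("chord histogram of a circle concentrates at the diameter", {
  disk <- raster_disk(64, c(32, 32), 20)
  ct <- trace_contour(disk)
  h <- chord_block(ct, disk)
  expect_equal(sum(h), 1)
  expect_gte(h[10], 0.9)
  # identical contours give identical histograms
  expect_identical(h, chord_block(trace_contour(disk), disk))
})

test_that("chord histogram is scale-invariant within one bin", {
  small <- raster_disk(64, c(32, 32), 10)
  big <- raster_disk(64, c(32, 32), 20)
  h_small <- chord_block(trace_contour(small), small)
  h_big <- chord_block(trace_contour(big), big)
  # mass may shift by at most one bin between scales
  cdf_s <- cumsum(h_small); cdf_b <- cumsum(h_big)
  expect_lt(max(abs(cdf_s - cdf_b)[1:8]), 0.15)
  expect_gt(h_small[9] + h_small[10], 0.9)
})

test_that("efd coefficients match the dense-polygon oracle on an ellipse", {
  em <- raster_ellipse(64, c(32, 32), 10, 20)
  co <- efd_coefficients(trace_contour(em), N = 10)
  phi <- seq(0, 2 * pi, length.out = 2001)[-2001]
  # oracle polygon in the same (x = col, y = -row) frame, rasterization-free
  oracle <- efd_polygon_oracle(20 * cos(phi), 10 * sin(phi), N = 10)
  # compare rotation/start-invariant harmonic norms (the rasterized contour
  # has an arbitrary start point relative to the smooth polygon)
  norms <- function(m) sqrt(rowSums(m^2))
  expect_equal(norms(co), norms(oracle), tolerance = 0.06)
  # first-harmonic ellipse axis ratio: smooth-oracle value, rasterized error
  ratio <- function(m) { s <- svd(matrix(m[1, ], 2, 2, byrow = TRUE))$d; s[2] / s[1] }
  expect_equal(ratio(co), ratio(oracle), tolerance = 0.05)
})

test_that("normalized efd of a 2:1 ellipse matches the oracle-derived values", {
  em <- raster_ellipse(64, c(32, 32), 10, 20)
  ef <- efd_block(trace_contour(em))
  # oracle: arc-length-parametrized 2:1 ellipse has first-harmonic minor/major
  # ratio 0.587 (not the 0.5 of the elliptic-angle parametrization)
  phi <- seq(0, 2 * pi, length.out = 4001)[-4001]
  oracle <- efd_polygon_oracle(20 * cos(phi), 10 * sin(phi), N = 10)
  d1_oracle <- {
    s <- svd(matrix(oracle[1, ], 2, 2, byrow = TRUE))$d
    s[2] / s[1]
  }
  expect_equal(ef[["efd_0"]], d1_oracle, tolerance = 0.05)
  # even harmonics vanish for the centrally symmetric ellipse; odd harmonics
  # carry the small arc-length correction only
  expect_lt(max(abs(ef[-1])), 0.1)
  expect_lt(max(abs(ef[c("efd_1", "efd_2", "efd_3", "efd_4")])), 0.02)
})

test_that("normalized efd is invariant to the traversal starting point", {
  mask <- generate_mask(0L, seed = 17)
  ct <- trace_contour(mask)
  ef0 <- efd_block(ct)
  n <- nrow(ct$points)
  for (off in round(c(0.25, 0.5, 0.8) * n)) {
    ct2 <- ct
    ct2$points <- ct$points[c(off:n, 1:(off - 1L)), , drop = FALSE]
    expect_lt(max(abs(efd_block(ct2) - ef0)), 1e-3)
  }
})

test_that("reconstruction error decreases with more harmonics", {
  mask <- generate_mask(0L, seed = 23)
  ct <- trace_contour(mask)
  co <- efd_coefficients(ct, N = 10)
  target <- cbind(ct$points[, 2L], -ct$points[, 1L])
  target <- sweep(target, 2L, colMeans(target))
  dev <- function(N) {
    rec <- efd_reconstruct(co[seq_len(N), , drop = FALSE], n_points = 400)
    mean(vapply(seq_len(nrow(rec)), function(i) {
      sqrt(min(colSums((t(target) - rec[i, ])^2)))
    }, numeric(1)))
  }
  expect_lte(dev(10), dev(2))
})

test_that("general block reproduces closed-form values for simple shapes", {
  sq <- raster_square(20, 1, 1, 10)
  g <- general_block(sq)
  expect_equal(unname(g[c(1, 6, 7, 8, 9)]), c(100, 0, 0, 10, 10))
  expect_equal(g[["general_9"]], sqrt(400 / pi), tolerance = 1e-12)
  expect_equal(g[["general_1"]], 36)

  disk <- raster_disk(64, c(32, 32), 20)
  gd <- general_block(disk)
  expect_lt(gd[["general_2"]], 0.1)              # eccentricity of a circle
  expect_gte(gd[["general_3"]], gd[["general_4"]])  # major >= minor

  for (seed in 1:4) {
    gg <- general_block(generate_mask(seed %% 2L, seed = seed))
    expect_gte(gg[["general_3"]], gg[["general_4"]])
  }
})

test_that("concatenation yields the documented block layout and lengths", {
  mask <- generate_mask(1L, seed = 9)
  full <- extract_shape_features(mask)
  expect_length(full, 67L)
  expect_identical(names(full), feature_names("all"))
  expect_length(extract_shape_features(mask, "Mom"), 10L)
  expect_length(extract_shape_features(mask, c("GenShape", "ChordLen")), 20L)
  expect_length(extract_shape_features(mask, "ElliFou"), 37L)
  # subsets are sub-vectors of the full extraction, in the same order
  sub <- extract_shape_features(mask, c("GenShape", "ChordLen"))
  expect_identical(sub, full[names(sub)])
  expect_error(extract_shape_features(mask, character(0)), class = "glia_bad_subset")
  # deterministic: bit-identical on repeat
  expect_identical(full, extract_shape_features(mask))
})

test_that("all 67 features are translation-invariant except the bbox corner", {
  mask <- generate_mask(0L, seed = 41)
  m <- nrow(mask)
  fg <- which(mask == 1L)
  r <- (fg - 1L) %% m + 1L; cc <- (fg - 1L) %/% m + 1L
  shifted <- matrix(0L, m, m)
  shifted[cbind(r + 3L, cc - 2L)] <- 1L
  v0 <- extract_shape_features(mask)
  v1 <- extract_shape_features(as_glia_mask(shifted))
  moving <- c("general_5", "general_6")   # bbox min_row, min_col
  expect_equal(v1[setdiff(names(v1), moving)], v0[setdiff(names(v0), moving)])
  expect_equal(unname(v1[moving] - v0[moving]), c(3, -2))
})
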