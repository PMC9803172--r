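test_that("mask generation is deterministic and class morphology separates", {
  mp <- morphology_params()
  m1 <- generate_mask(0L, mp, seed = 5)
  m2 <- generate_mask(0L, mp, seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_mask(0L, mp, seed = 6)))

  sol_act <- vapply(1:40, function(i) solidity_oracle(generate_mask(1L, mp, seed = i)),
                    numeric(1))
  sol_rest <- vapply(1:40, function(i) solidity_oracle(generate_mask(0L, mp, seed = i)),
                     numeric(1))
  expect_gt(mean(sol_act), mean(sol_rest))
  # ramified silhouettes are substantially less solid on average
  expect_gt(mean(sol_act) - mean(sol_rest), 0.2)
})

test_that("zero irregularity produces an exact rasterized disk", {
  mp <- morphology_params(amoeboid_irregularity = 0)
  mask <- generate_mask(1L, mp, seed = 3)
  fg <- which(mask == 1L)
  r <- (fg - 1L) %% nrow(mask) + 1L
  cc <- (fg - 1L) %/% nrow(mask) + 1L
  # recover the generating circle: centroid + max radius must reproduce it
  cen <- c(mean(r), mean(cc))
  rad2 <- (r - cen[1L])^2 + (cc - cen[2L])^2
  R2 <- max(rad2)
  all_px <- expand.grid(r = seq_len(nrow(mask)), c = seq_len(ncol(mask)))
  inside <- (all_px$r - cen[1L])^2 + (all_px$c - cen[2L])^2 <= R2
  expect_equal(sum(inside), length(fg))
  expect_true(all(mask[cbind(all_px$r[inside], all_px$c[inside])] == 1L))
})

test_that("noiseless single-exponential stacks decay at the exact rate", {
  mask <- raster_disk(32, c(16, 16), 6)
  prm <- decay_sim_params(
    resting = list(a1 = 1, a2 = 0, tau1 = 4, tau2 = 8),
    activated = list(a1 = 1, a2 = 0, tau1 = 4, tau2 = 8),
    irf_fwhm = 0, peak_counts = 10000, background_counts = 0, noise = "none"
  )
  stack <- simulate_decay_stack(mask, prm, label = 0L, p = 16, seed = 1)
  fg <- which(mask == 1L)[1L]
  rr <- (fg - 1L) %% 32 + 1L; cc <- (fg - 1L) %/% 32 + 1L
  curve <- stack[, rr, cc]
  expected <- round(10000 * exp(-(0:15) / 4))
  expect_equal(curve, as.integer(expected))
  # all foreground pixels carry the identical expected curve
  flat <- matrix(stack, 16, 32 * 32)[, which(mask == 1L)]
  expect_true(all(flat == curve))
})

test_that("poisson totals concentrate around their expectation", {
  mask <- raster_disk(32, c(16, 16), 8)
  prm <- decay_sim_params(noise = "poisson")
  p <- 32
  stack <- simulate_decay_stack(mask, prm, label = 1L, p = p, seed = 9)
  cls <- prm$activated
  lam_fg <- gliastate:::expected_curve(cls, p, prm$irf_fwhm, prm$peak_counts,
                                       prm$background_counts)
  n_fg <- sum(mask); n_bg <- sum(mask == 0L)
  expected_total <- n_fg * sum(lam_fg) + n_bg * prm$background_counts
  sd_total <- sqrt(expected_total)   # Poisson sum variance = mean
  expect_lt(abs(sum(stack) - expected_total), 5 * sd_total)
  expect_identical(stack, simulate_decay_stack(mask, prm, 1L, p = p, seed = 9))
})

test_that("generated datasets have exact class counts and loadable artifacts", {
  fix <- tiny_dataset()
  man <- fix$manifest
  expect_equal(sum(man$label == 1L), 8L)
  expect_equal(nrow(man), 16L)
  expect_true(all(file.exists(man$mask_path)))
  expect_true(all(file.exists(man$decay_path)))
  m <- read_mask(man$mask_path[1L])
  s <- read_decay_stack(man$decay_path[1L], fix$p)
  expect_equal(dim(s)[2:3], dim(m))
  # regenerating with the same seed is file-identical (up to the directory)
  dir2 <- file.path(tempdir(), "glia_regen")
  man2 <- generate_dataset(16, 0.5, p = fix$p, seed = 7, out_dir = dir2)
  expect_identical(man2$label, man$label)
  for (i in c(1L, 3L, 16L)) {
    expect_identical(
      readBin(man$mask_path[i], "raw", file.size(man$mask_path[i])),
      readBin(man2$mask_path[i], "raw", file.size(man2$mask_path[i]))
    )
    expect_identical(
      readBin(man$decay_path[i], "raw", file.size(man$decay_path[i])),
      readBin(man2$decay_path[i], "raw", file.size(man2$decay_path[i]))
    )
  }
})

test_that("signal switches remove the class contrast they target", {
  # with lifetime_signal = FALSE both classes share the resting kinetics
  dir <- file.path(tempdir(), "glia_off")
  man <- generate_dataset(8, 0.5, p = 16, seed = 21, out_dir = dir,
                          lifetime_signal = FALSE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(length(unique(truth$tau2)), 1L)
  # with shape_signal = FALSE all masks come from the ramified procedure
  dir2 <- file.path(tempdir(), "glia_shapeoff")
  man2 <- generate_dataset(10, 0.5, p = 16, seed = 22, out_dir = dir2,
                           shape_signal = FALSE)
  bundle <- load_dataset(man2)
  sol <- vapply(bundle$mask, solidity_oracle, numeric(1))
  # amoeboid blobs would be near 1; ramified stand-ins are not
  expect_lt(mean(sol[bundle$label == 1L]) - mean(sol[bundle$label == 0L]), 0.15)
})
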