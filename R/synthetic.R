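#' Morphology parameters for the synthetic mask generator
#'
#' The generator emulates the two microglial phenotypes: resting cells are
#' ramified (a small soma with several thin processes, hence low solidity),
#' activated cells are amoeboid (a single compact blob with a low-frequency
#' boundary perturbation). Defaults target 64 px frames and produce clearly
#' separated mean solidity between classes while leaving enough overlap that a
#' morphology-only classifier is good but not perfect.
#'
#' @param m Image side in pixels (`>= 32`).
#' @param soma_radius_range Min/max soma (or blob) radius in px.
#' @param n_branches_range Min/max number of processes (resting cells only).
#' @param branch_length_range Min/max process length in steps (px).
#' @param branch_width Process width in px (`>= 1`).
#' @param amoeboid_irregularity Amplitude of the radial boundary perturbation
#'   of activated blobs, unitless in `[0, 1]`; `0` gives an exact disk.
#' @return A list of class `glia_morph_params`.
#' @export
morphology_params <- function(m = 64L,
                              soma_radius_range = c(5, 9),
                              n_branches_range = c(1L, 6L),
                              branch_length_range = c(5, 18),
                              branch_width = 2,
                              amoeboid_irregularity = 0.5) {
  stopifnot(m >= 32, diff(soma_radius_range) >= 0, diff(n_branches_range) >= 0,
            diff(branch_length_range) >= 0, branch_width >= 1,
            amoeboid_irregularity >= 0, amoeboid_irregularity <= 1)
  structure(list(m = as.integer(m), soma_radius_range = soma_radius_range,
                 n_branches_range = as.integer(n_branches_range),
                 branch_length_range = branch_length_range,
                 branch_width = branch_width,
                 amoeboid_irregularity = amoeboid_irregularity),
            class = "glia_morph_params")
}

#' Decay-simulation parameters
#'
#' Class-conditional bi-exponential kinetics: each class has amplitudes
#' `a1, a2` and lifetimes `tau1 < tau2` (in lifetime-component units). The
#' default contrast gives the activated class a larger short-lifetime
#' amplitude fraction `a1/(a1+a2)` and a smaller `tau2` than the resting
#' class, the direction expected from the metabolic shift toward glycolysis
#' on activation. The numbers themselves are synthetic defaults, not
#' measured values.
#'
#' @param resting,activated Named lists with `a1`, `a2`, `tau1`, `tau2`.
#' @param irf_fwhm Full width at half maximum of the Gaussian instrument
#'   response, in components (`>= 0`; `0` disables convolution).
#' @param peak_counts Expected photons in the first component of a bright
#'   foreground pixel before IRF spreading.
#' @param background_counts Expected total background photons per pixel.
#' @param noise `"poisson"` or `"none"`.
#' @return A list of class `glia_decay_params`.
#' @export
decay_sim_params <- function(resting = list(a1 = 0.4, a2 = 0.6, tau1 = 2.5, tau2 = 14),
                             activated = list(a1 = 0.7, a2 = 0.3, tau1 = 2.5, tau2 = 10),
                             irf_fwhm = 3, peak_counts = 200,
                             background_counts = 2, noise = "poisson") {
  noise <- match.arg(noise, c("poisson", "none"))
  for (cls in list(resting, activated)) {
    stopifnot(cls$a1 >= 0, cls$a2 >= 0, cls$a1 + cls$a2 > 0,
              cls$tau1 > 0, cls$tau1 < cls$tau2)
  }
  stopifnot(irf_fwhm >= 0, peak_counts > 0, background_counts >= 0)
  structure(list(resting = resting, activated = activated, irf_fwhm = irf_fwhm,
                 peak_counts = peak_counts, background_counts = background_counts,
                 noise = noise),
            class = "glia_decay_params")
}

rasterize_disk <- function(m, center, radius) {
  r <- matrix(seq_len(m), m, m) - center[1L]
  cc <- matrix(seq_len(m), m, m, byrow = TRUE) - center[2L]
  matrix(as.integer(r * r + cc * cc <= radius * radius), m, m)
}

# Amoeboid blob: disk with low-frequency radial perturbation
# r(theta) = R * (1 + irregularity * s(theta)), s a random 2..4-mode signal.
amoeboid_mask <- function(params) {
  m <- params$m
  R <- stats::runif(1L, params$soma_radius_range[1L], params$soma_radius_range[2L])
  maxr <- R * (1 + params$amoeboid_irregularity)
  lim <- m - 2 - maxr
  if (lim <= maxr + 2) abort_glia("blob cannot fit in frame", "glia_generation_error")
  center <- stats::runif(2L, maxr + 2, lim)
  if (params$amoeboid_irregularity == 0) return(rasterize_disk(m, center, R))
  modes <- 2:4
  amp <- stats::runif(length(modes)); amp <- amp / sum(amp)
  phase <- stats::runif(length(modes), 0, 2 * pi)
  rr <- matrix(seq_len(m), m, m) - center[1L]
  cc <- matrix(seq_len(m), m, m, byrow = TRUE) - center[2L]
  theta <- atan2(rr, cc)
  s <- matrix(0, m, m)
  for (k in seq_along(modes)) s <- s + amp[k] * cos(modes[k] * theta + phase[k])
  rad <- R * (1 + params$amoeboid_irregularity * s)
  matrix(as.integer(rr * rr + cc * cc <= rad * rad), m, m)
}

# Ramified cell: soma disk + processes grown as self-avoiding lattice walks
# with drift away from the soma, dilated to branch_width.
ramified_mask <- function(params) {
  m <- params$m
  R <- stats::runif(1L, params$soma_radius_range[1L], params$soma_radius_range[2L]) * 0.8
  margin <- R + max(params$branch_length_range) + params$branch_width + 2
  margin <- min(margin, m / 2 - 2)
  center <- stats::runif(2L, margin, m - margin)
  nb <- sample(seq(params$n_branches_range[1L], params$n_branches_range[2L]), 1L)
  pts <- list()
  dirs8 <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  base_angle <- stats::runif(1L, 0, 2 * pi)
  for (b in seq_len(nb)) {
    ang <- base_angle + 2 * pi * (b - 1) / nb + stats::rnorm(1L, 0, 0.25)
    pos <- center + (R - 0.5) * c(sin(ang), cos(ang))
    len <- round(stats::runif(1L, params$branch_length_range[1L], params$branch_length_range[2L]))
    walk <- matrix(0, len, 2L)
    for (s in seq_len(len)) {
      away <- pos - center
      away <- away / max(sqrt(sum(away^2)), 1e-9)
      scores <- dirs8 %*% away + stats::rnorm(8L, 0, 0.6)
      step <- dirs8[which.max(scores), ]
      pos <- pos + step
      pos <- pmin(pmax(pos, 2), m - 1)
      walk[s, ] <- pos
    }
    pts[[b]] <- walk
  }
  mask <- rasterize_disk(m, center, R)
  all_pts <- do.call(rbind, pts)
  half <- params$branch_width / 2
  rr <- matrix(seq_len(m), m, m)
  cc <- matrix(seq_len(m), m, m, byrow = TRUE)
  for (i in seq_len(nrow(all_pts))) {
    d2 <- (rr - all_pts[i, 1L])^2 + (cc - all_pts[i, 2L])^2
    mask[d2 <= half * half + 0.5] <- 1L
  }
  mask
}

touches_border <- function(mask) {
  any(mask[1L, ] == 1L) || any(mask[nrow(mask), ] == 1L) ||
    any(mask[, 1L] == 1L) || any(mask[, ncol(mask)] == 1L)
}

#' Generate one synthetic cell mask
#'
#' `label = 1` (activated) produces a compact amoeboid blob; `label = 0`
#' (resting) a ramified soma-plus-branches silhouette. The result is a single
#' 8-connected foreground component that does not touch the frame border;
#' generation retries with fresh randomness up to 100 times before erroring.
#'
#' @param label Class label, 0 = resting, 1 = activated.
#' @param params A [morphology_params()] object.
#' @param seed Integer seed; identical inputs give identical masks.
#' @return A `glia_mask` matrix (`m x m`).
#' @export
generate_mask <- function(label, params = morphology_params(), seed = 1L) {
  stopifnot(label %in% c(0L, 1L))
  with_seed(derive_seed(seed, paste0("mask", label)), {
    for (attempt in seq_len(100L)) {
      mask <- tryCatch(
        if (label == 1L) amoeboid_mask(params) else ramified_mask(params),
        gliastate_error = function(e) NULL
      )
      if (is.null(mask) || !any(mask == 1L) || touches_border(mask)) next
      mask <- largest_component(mask)
      if (sum(mask) >= 8L) {
        class(mask) <- c("glia_mask", class(mask))
        return(mask)
      }
    }
    abort_glia("mask generation failed after 100 attempts", "glia_generation_error")
  })
}

gaussian_irf <- function(fwhm) {
  if (fwhm <= 0) return(1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * fwhm))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Expected per-pixel decay curve: bi-exponential, IRF-convolved (causal full
# convolution truncated to p), plus uniform background.
expected_curve <- function(cls, p, irf_fwhm, peak_counts, background_counts) {
  t <- 0:(p - 1L)
  decay <- peak_counts * (cls$a1 * exp(-t / cls$tau1) + cls$a2 * exp(-t / cls$tau2)) /
    (cls$a1 + cls$a2)
  k <- gaussian_irf(irf_fwhm)
  if (length(k) > 1L) {
    full <- stats::convolve(decay, rev(k), type = "open")
    decay <- full[seq_len(p)]
  }
  decay + background_counts / p
}

#' Simulate a TCSPC decay stack for one cell
#'
#' Every foreground pixel receives the class-conditional expected decay
#' (bi-exponential normalised to `peak_counts` at its origin, convolved with a
#' discrete Gaussian instrument response of the given FWHM, plus uniform
#' background); background pixels receive background only. Counts are Poisson
#' draws around the expectation, or the rounded expectation when
#' `noise = "none"`.
#'
#' @param mask `glia_mask` foreground.
#' @param params A [decay_sim_params()] object.
#' @param label Class label 0/1 selecting the kinetics.
#' @param p Number of lifetime components (`>= 8`).
#' @param seed Integer seed.
#' @return A `p x m x m` integer array.
#' @export
simulate_decay_stack <- function(mask, params = decay_sim_params(), label,
                                 p = 64L, seed = 1L) {
  stopifnot(p >= 8, label %in% c(0L, 1L))
  m <- nrow(mask)
  cls <- if (label == 1L) params$activated else params$resting
  lam_fg <- expected_curve(cls, p, params$irf_fwhm, params$peak_counts,
                           params$background_counts)
  lam_bg <- rep(params$background_counts / p, p)
  lam <- array(0, dim = c(p, m, m))
  fg <- which(mask == 1L)
  bg <- which(mask == 0L)
  for (t in seq_len(p)) {
    plane <- matrix(lam_bg[t], m, m)
    plane[fg] <- lam_fg[t]
    lam[t, , ] <- plane
  }
  counts <- if (params$noise == "poisson") {
    with_seed(derive_seed(seed, "decay"), array(stats::rpois(length(lam), lam), dim = dim(lam)))
  } else {
    round(lam)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `masks/<id>.png`, `decays/<id>.tif`, `manifest.csv`, `truth.csv`
#' (per-cell simulation ground truth for recovery tests) and `config.json`
#' (generator provenance) under `out_dir`. The activated class receives
#' `round(n_cells * activated_fraction)` cells.
#'
#' @param n_cells Total cells (`>= 4`).
#' @param activated_fraction Fraction in `(0, 1)` labelled activated.
#' @param morph [morphology_params()].
#' @param decay [decay_sim_params()].
#' @param p Lifetime components per stack.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param shape_signal If `FALSE`, every cell's mask is drawn from the
#'   resting-morphology procedure regardless of label, so morphology carries
#'   no class information (ablation control).
#' @param lifetime_signal If `FALSE`, every cell's decay uses the resting
#'   kinetics regardless of label, so lifetime carries no class information.
#' @return The manifest tibble (invisibly carries attribute `p`).
#' @export
generate_dataset <- function(n_cells, activated_fraction = 0.5,
                             morph = morphology_params(),
                             decay = decay_sim_params(),
                             p = 64L, seed = 1L, out_dir,
                             shape_signal = TRUE, lifetime_signal = TRUE) {
  stopifnot(n_cells >= 4, activated_fraction > 0, activated_fraction < 1)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "decays"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_glia("out_dir not writable", "glia_io_error")
  n_act <- round(n_cells * activated_fraction)
  labels <- c(rep(1L, n_act), rep(0L, n_cells - n_act))
  ids <- sprintf("cell_%04d", seq_len(n_cells))
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell_seed <- derive_seed(seed, paste0("cell", i))
    mask_label <- if (shape_signal) labels[i] else 0L
    decay_label <- if (lifetime_signal) labels[i] else 0L
    mask <- generate_mask(mask_label, morph, seed = cell_seed)
    stack <- simulate_decay_stack(mask, decay, decay_label, p = p, seed = cell_seed)
    mask_path <- file.path(out_dir, "masks", paste0(ids[i], ".png"))
    decay_path <- file.path(out_dir, "decays", paste0(ids[i], ".tif"))
    write_mask(mask, mask_path)
    write_decay_stack(stack, decay_path)
    cls <- if (decay_label == 1L) decay$activated else decay$resting
    rows[[i]] <- tibble::tibble(
      cell_id = ids[i], mask_path = mask_path, decay_path = decay_path,
      label = labels[i], area = sum(mask),
      a1 = cls$a1, a2 = cls$a2, tau1 = cls$tau1, tau2 = cls$tau2
    )
  }
  truth <- dplyr::bind_rows(rows)
  manifest <- truth[, c("cell_id", "mask_path", "decay_path", "label")]
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_cells = n_cells, activated_fraction = activated_fraction,
         p = p, seed = seed, shape_signal = shape_signal,
         lifetime_signal = lifetime_signal,
         morph = unclass(morph), decay = unclass(decay)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  validate_manifest(manifest, p)
}

#' Load a dataset into memory
#'
#' Reads every mask and decay stack referenced by a manifest and reduces each
#' stack to the `p x n_masked` matrix of foreground-pixel counts (all that the
#' downstream histogram sequences need), keeping memory modest.
#'
#' @param manifest A `glia_manifest` (see [read_manifest()]) or the tibble
#'   returned by [generate_dataset()].
#' @return A tibble of class `glia_bundle`: `cell_id`, `label`, list-columns
#'   `mask` and `counts`; attribute `p`.
#' @export
load_dataset <- function(manifest) {
  p <- attr(manifest, "p")
  stopifnot(!is.null(p))
  masks <- purrr::map(manifest$mask_path, read_mask)
  counts <- purrr::map2(manifest$decay_path, masks, function(path, mask) {
    stack <- read_decay_stack(path, p)
    fg <- which(mask == 1L)
    matrix(stack, dim(stack)[1L], length(mask))[, fg, drop = FALSE]
  })
  out <- tibble::tibble(cell_id = manifest$cell_id, label = manifest$label,
                        mask = masks, counts = counts)
  attr(out, "p") <- p
  class(out) <- c("glia_bundle", class(out))
  out
}
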