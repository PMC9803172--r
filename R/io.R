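#' Read a binary cell mask
#'
#' Reads a single-page TIFF or PNG, thresholds at zero (any pixel `> 0` is
#' foreground) and retains the largest 8-connected foreground component.
#' Ties on component size are broken by the smallest top-left (row-major
#' scan order) foreground coordinate.
#'
#' @param path Path to a single-page TIFF or PNG file.
#' @return An integer 0/1 matrix of class `glia_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort_glia(paste0("cannot read mask: ", path), "glia_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, all = FALSE),
    abort_glia(paste0("unsupported mask format: .", ext), "glia_io_error")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse channels
  as_glia_mask(img > 0)
}

#' Coerce a logical/numeric matrix to a validated mask
#'
#' @param x Matrix; nonzero entries are foreground.
#' @param largest_only Keep only the largest 8-connected component.
#' @return Integer 0/1 matrix of class `glia_mask`.
#' @export
as_glia_mask <- function(x, largest_only = TRUE) {
  stopifnot(is.matrix(x))
  m <- matrix(as.integer(x > 0), nrow(x), ncol(x))
  if (!any(m == 1L)) abort_glia("empty mask", "glia_empty_mask")
  if (largest_only) m <- largest_component(m)
  class(m) <- c("glia_mask", class(m))
  m
}

# Label 8-connected components by BFS; return mask of the largest component.
# Ties broken by smallest row-major index of a member pixel.
largest_component <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fg <- which(m == 1L)  # column-major order
  # scan in row-major order for deterministic tie-breaking by top-left coord
  ord <- order((fg - 1L) %% nr, (fg - 1L) %/% nr)
  sizes <- integer(0)
  firsts <- integer(0)
  doff <- as.integer(c(-1, 0, 1, -1, 1, -1, 0, 1))
  coff <- as.integer(c(-1, -1, -1, 0, 0, 1, 1, 1))
  for (s in fg[ord]) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur; size <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      r <- (v - 1L) %% nr + 1L
      cc <- (v - 1L) %/% nr + 1L
      rr <- r + doff; ccn <- cc + coff
      ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
      nb <- (ccn[ok] - 1L) * nr + rr[ok]
      nb <- nb[m[nb] == 1L & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    sizes[cur] <- size
    firsts[cur] <- s
  }
  if (cur == 1L) return(m)
  best <- which(sizes == max(sizes))[1L]  # firsts ordered by row-major scan
  matrix(as.integer(lab == best), nr, nc)
}

#' Write a binary mask as PNG
#'
#' @param mask 0/1 matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a TCSPC decay stack
#'
#' A decay stack holds per-pixel photon counts for each of `p` lifetime
#' components, stored as a multi-page TIFF with one page per component in
#' acquisition order.
#'
#' @param path Multi-page TIFF path.
#' @param p Expected number of lifetime components (pages).
#' @return A `p x m x m` integer array (component, row, col).
#' @export
read_decay_stack <- function(path, p) {
  if (!file.exists(path)) abort_glia(paste0("cannot read stack: ", path), "glia_io_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != p) {
    abort_glia(sprintf("component count mismatch: %d pages, expected %d", length(pages), p),
               "glia_component_mismatch")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims != dims[, 1L])) abort_glia("pages differ in shape", "glia_io_error")
  stack <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  if (any(stack < 0)) abort_glia("invalid counts: negative values", "glia_invalid_counts")
  storage.mode(stack) <- "integer"
  stack
}

#' Write a decay stack as multi-page TIFF
#'
#' Counts are stored as 16-bit unsigned samples, so per-pixel counts must not
#' exceed 65535; the read/write pair round-trips integer counts exactly.
#'
#' @param stack `p x m x m` non-negative integer array.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_decay_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  if (any(stack < 0)) abort_glia("invalid counts: negative values", "glia_invalid_counts")
  if (max(stack) > 65535) abort_glia("counts exceed 16-bit range", "glia_io_error")
  pages <- lapply(seq_len(dim(stack)[1L]), function(t) stack[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

feature_block_sizes <- c(zernike = 10L, general = 10L, chord = 10L, efd = 37L)

#' Column names of the 67-dimensional shape feature vector
#'
#' @param subset Character vector over `c("Mom","GenShape","ChordLen","ElliFou")`;
#'   `"all"` for every block. Blocks are always emitted in the fixed
#'   concatenation order zernike, general, chord, efd.
#' @return Character vector of feature names, e.g. `zernike_0 ... efd_36`.
#' @export
feature_names <- function(subset = "all") {
  blocks <- resolve_subset(subset)
  unlist(lapply(blocks, function(b) {
    paste0(b, "_", seq_len(feature_block_sizes[[b]]) - 1L)
  }), use.names = FALSE)
}

subset_aliases <- c(Mom = "zernike", GenShape = "general",
                    ChordLen = "chord", ElliFou = "efd")

resolve_subset <- function(subset) {
  if (!length(subset)) abort_glia("feature subset is empty", "glia_bad_subset")
  if (identical(subset, "all") ||
      (length(unique(subset)) == 4L &&
         setequal(subset, unname(subset_aliases)))) {
    return(c("zernike", "general", "chord", "efd"))
  }
  blocks <- unname(subset_aliases[match(subset, names(subset_aliases))])
  bad <- is.na(blocks)
  if (any(bad)) {
    blocks2 <- subset
    blocks2[!bad] <- blocks[!bad]
    unknown <- setdiff(blocks2, unname(subset_aliases))
    if (length(unknown)) {
      abort_glia(paste0("unknown feature family: ", paste(unknown, collapse = ", ")),
                 "glia_bad_subset")
    }
    blocks <- blocks2
  }
  if (!length(blocks)) abort_glia("feature subset is empty", "glia_bad_subset")
  # fixed relative order
  ord <- c("zernike", "general", "chord", "efd")
  ord[ord %in% blocks]
}

#' Write a shape-feature table as CSV
#'
#' One row per cell, a `cell_id` column plus one column per feature, written
#' with 17 significant digits so that `read_feature_table()` round-trips the
#' doubles losslessly.
#'
#' @param features Tibble with `cell_id` and 67 feature columns (or a
#'   sub-vector layout from a feature subset).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), "cell_id" %in% names(features))
  num_cols <- setdiff(names(features), "cell_id")
  known <- feature_names("all")
  if (!all(num_cols %in% c(known, "tau_mean")) ||
      !(length(num_cols) %in% c(feature_block_sizes,
                                 67L, 67L + 1L,
                                 utils::combn(feature_block_sizes, 2, sum),
                                 utils::combn(feature_block_sizes, 3, sum)))) {
    abort_glia(sprintf("feature table has unexpected layout (%d feature columns)",
                       length(num_cols)), "glia_feature_length")
  }
  body <- vapply(num_cols, function(cn) sprintf("%.17g", features[[cn]]),
                 character(nrow(features)))
  if (nrow(features) == 1L) body <- matrix(body, nrow = 1L)
  lines <- c(paste(c("cell_id", num_cols), collapse = ","),
             apply(cbind(as.character(features$cell_id), body), 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a shape-feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Tibble with `cell_id` (character) and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  out <- tibble::as_tibble(df)
  for (cn in setdiff(names(out), "cell_id")) out[[cn]] <- as.numeric(out[[cn]])
  out
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `cell_id`, `mask_path`, `decay_path`,
#' `label` (0 = resting, 1 = activated). Relative paths are resolved against
#' the manifest's directory. Validates id uniqueness, label domain and path
#' resolvability.
#'
#' @param path Manifest CSV path.
#' @param p Number of lifetime components shared by all decay stacks.
#' @param check_paths Verify that every referenced file exists.
#' @return A tibble of class `glia_manifest` with attribute `p`.
#' @export
read_manifest <- function(path, p, check_paths = TRUE) {
  df <- tibble::as_tibble(utils::read.csv(path, colClasses = c(
    cell_id = "character", mask_path = "character",
    decay_path = "character", label = "integer"
  )))
  base <- dirname(normalizePath(path))
  df$mask_path <- ifelse(grepl("^(/|[A-Za-z]:)", df$mask_path),
                         df$mask_path, file.path(base, df$mask_path))
  df$decay_path <- ifelse(grepl("^(/|[A-Za-z]:)", df$decay_path),
                          df$decay_path, file.path(base, df$decay_path))
  validate_manifest(df, p, check_paths = check_paths)
}

validate_manifest <- function(df, p, check_paths = TRUE) {
  stopifnot(all(c("cell_id", "mask_path", "decay_path", "label") %in% names(df)))
  if (anyDuplicated(df$cell_id)) abort_glia("duplicate cell_id in manifest", "glia_manifest_error")
  if (!all(df$label %in% c(0L, 1L))) abort_glia("labels must be 0/1", "glia_manifest_error")
  if (check_paths) {
    missing <- c(df$mask_path[!file.exists(df$mask_path)],
                 df$decay_path[!file.exists(df$decay_path)])
    if (length(missing)) {
      abort_glia(paste0("unresolvable paths in manifest: ", missing[[1L]]), "glia_manifest_error")
    }
  }
  stopifnot(is.numeric(p), p >= 1)
  attr(df, "p") <- as.integer(p)
  class(df) <- c("glia_manifest", class(df))
  df
}

#' Write a dataset manifest CSV
#'
#' @param manifest Tibble with `cell_id`, `mask_path`, `decay_path`, `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(
    manifest[, c("cell_id", "mask_path", "decay_path", "label")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Default run configuration
#'
#' Central configuration for training and evaluation. Defaults: 50 epochs and
#' learning rate 1e-4 (the published training schedule), SGD momentum 0.9,
#' batch size 32, `h = 32` histogram bins per lifetime component, BLSTM hidden
#' size 32 per direction, 5-fold cross-validation.
#'
#' @param modality One of `"joint"`, `"shape_only"`, `"shape_plus_tau"`.
#' @param h Histogram bins per lifetime component (`h >= 2`).
#' @param epochs Training epochs (`>= 1`).
#' @param learning_rate Positive SGD step size.
#' @param batch_size Minibatch size.
#' @param momentum SGD momentum coefficient.
#' @param k_folds Cross-validation folds (`>= 2`).
#' @param seed Master seed; all stage seeds are derived from it.
#' @param feature_subset Character vector over
#'   `c("Mom","GenShape","ChordLen","ElliFou")`, or `"all"`.
#' @param hidden_size BLSTM hidden units per direction.
#' @param dropout_rate Dropout probability on the BLSTM output (training only).
#' @return A list of class `glia_config`.
#' @export
glia_config <- function(modality = "joint", h = 32L, epochs = 50L,
                        learning_rate = 1e-4, batch_size = 32L, momentum = 0.9,
                        k_folds = 5L, seed = 1L, feature_subset = "all",
                        hidden_size = 32L, dropout_rate = 0.5) {
  modality <- match.arg(modality, c("joint", "shape_only", "shape_plus_tau"))
  stopifnot(h >= 2, epochs >= 1, learning_rate > 0, k_folds >= 2,
            batch_size >= 1, hidden_size >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  resolve_subset(feature_subset)  # validates non-empty / known
  structure(list(
    modality = modality, h = as.integer(h), epochs = as.integer(epochs),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    momentum = momentum, k_folds = as.integer(k_folds), seed = as.integer(seed),
    feature_subset = feature_subset, hidden_size = as.integer(hidden_size),
    dropout_rate = dropout_rate
  ), class = "glia_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_config()` returns a `glia_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(glia_config, x[intersect(names(x), names(formals(glia_config)))])
}

#' @rdname read_config
#' @param config A `glia_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
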