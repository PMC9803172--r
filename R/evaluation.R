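#' Stratified k-fold assignment
#'
#' Within each class the ids are shuffled (seeded) and dealt round-robin to
#' folds, so folds are pairwise disjoint, cover all ids, differ in size by at
#' most one and preserve class balance.
#'
#' @param ids Character or integer sample ids.
#' @param labels Class labels in `{0, 1}`.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#' @return List of `k` id vectors.
#' @export
kfold_split <- function(ids, labels, k, seed = 1L) {
  n <- length(ids)
  stopifnot(length(labels) == n)
  if (n < k) abort_glia("fewer samples than folds", "glia_fold_error")
  if (length(unique(labels)) < 2L) abort_glia("both classes must be present", "glia_fold_error")
  folds <- vector("list", k)
  with_seed(derive_seed(seed, "folds"), {
    # round-robin offset carried across classes keeps fold sizes within 1
    pos <- 0L
    for (cls in sort(unique(labels))) {
      members <- ids[labels == cls]
      members <- members[sample.int(length(members))]
      for (mm in members) {
        fi <- pos %% k + 1L
        folds[[fi]] <- c(folds[[fi]], mm)
        pos <- pos + 1L
      }
    }
  })
  folds
}

#' Classification metrics and ROC
#'
#' Confusion counts are taken at the given probability threshold with
#' activated (label 1) as the positive class. The ROC curve sweeps all unique
#' predicted probabilities plus endpoints and the AUC is the trapezoid-rule
#' area under it.
#'
#' @param labels True labels in `{0, 1}`.
#' @param probs Predicted `P(activated)`.
#' @param threshold Decision threshold for the confusion counts.
#' @return List of class `glia_metrics`: `accuracy`, `precision`, `recall`,
#'   `jaccard`, `auc`, `confusion` (tp, fp, fn, tn) and `roc` (tibble of
#'   `fpr`, `tpr`). With single-class labels the AUC is `NA` and flagged.
#' @export
compute_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  pred <- as.integer(probs > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  single_class <- length(unique(labels)) < 2L
  if (single_class) {
    roc <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
    auc <- NA_real_
  } else {
    thr <- c(Inf, sort(unique(probs), decreasing = TRUE), -Inf)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    tpr <- vapply(thr, function(s) sum(probs >= s & labels == 1L) / n1, numeric(1))
    fpr <- vapply(thr, function(s) sum(probs >= s & labels == 0L) / n0, numeric(1))
    roc <- tibble::tibble(fpr = fpr, tpr = tpr)
    auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(
    accuracy = (tp + tn) / length(labels),
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    jaccard = div(tp, tp + fp + fn),
    auc = auc,
    auc_defined = !single_class,
    confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
    roc = roc
  ), class = "glia_metrics")
}

#' @export
print.glia_metrics <- function(x, ...) {
  cat(sprintf("<glia_metrics> acc %.4f  prec %.4f  rec %.4f  JI %.4f  AUC %s\n",
              x$accuracy, x$precision, x$recall, x$jaccard,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

metrics_row <- function(m) {
  tibble::tibble(accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, jaccard = m$jaccard, auc = m$auc)
}

# Prepare fold inputs: features centred later inside train; here we compute
# per-fold artefacts that must be fit on training cells only (bin edges).
prepare_sequences <- function(bundle, edges) {
  lapply(bundle$counts, decay_to_sequence, edges = edges)
}

#' Cross-validated evaluation of the classifier
#'
#' For each fold, the histogram bin edges (and, through training, the
#' feature mean and batch-norm statistics) are fit on the training cells
#' only; the held-out fold is never seen before evaluation. Shape features
#' are deterministic per cell and are extracted once. Reports per-fold and
#' mean metrics for both training and test sets.
#'
#' @param bundle `glia_bundle` from [load_dataset()].
#' @param config `glia_config`.
#' @param features Optional precomputed feature tibble (from
#'   [extract_feature_table()]); extracted here when `NULL`.
#' @param tau Optional precomputed `tau_mean` vector for the
#'   `shape_plus_tau` modality.
#' @return A list of class `glia_cv`: `folds` (tibble with one row per fold:
#'   fold, n_test, test and train metric columns), `mean` (one-row tibble of
#'   fold-averaged metrics), `predictions` (pooled held-out predictions) and
#'   the config echo.
#' @export
cross_validate <- function(bundle, config, features = NULL, tau = NULL) {
  p <- attr(bundle, "p")
  if (is.null(features)) features <- extract_feature_table(bundle, config$feature_subset)
  X <- as_feature_matrix(features)
  if (config$modality == "shape_plus_tau") {
    if (is.null(tau)) {
      tau <- vapply(bundle$counts, cell_tau_mean, numeric(1))
    }
    X <- cbind(X, tau_mean = tau)
  }
  labels <- bundle$label
  folds <- kfold_split(seq_len(nrow(bundle)), labels, config$k_folds, config$seed)
  fold_rows <- vector("list", length(folds))
  preds <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_len(nrow(bundle)), test_idx)
    seqs_train <- seqs_test <- NULL
    edges <- NULL
    if (config$modality == "joint") {
      edges <- compute_bin_edges(bundle$counts[train_idx], config$h)
      seqs_train <- lapply(bundle$counts[train_idx], decay_to_sequence, edges = edges)
      seqs_test <- lapply(bundle$counts[test_idx], decay_to_sequence, edges = edges)
    }
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, paste0("fold", fi))
    model <- train_joint(X[train_idx, , drop = FALSE], seqs_train,
                         labels[train_idx], fold_cfg)
    model$bin_edges <- edges
    pr_te <- predict(model, X[test_idx, , drop = FALSE], seqs_test)
    pr_tr <- predict(model, X[train_idx, , drop = FALSE], seqs_train)
    m_te <- compute_metrics(labels[test_idx], pr_te$prob_activated)
    m_tr <- compute_metrics(labels[train_idx], pr_tr$prob_activated)
    fold_rows[[fi]] <- dplyr::bind_cols(
      tibble::tibble(fold = fi, n_test = length(test_idx)),
      metrics_row(m_te),
      dplyr::rename_with(metrics_row(m_tr), ~ paste0("train_", .x))
    )
    preds[[fi]] <- tibble::tibble(cell_id = bundle$cell_id[test_idx], fold = fi,
                                  label = labels[test_idx],
                                  prob_activated = pr_te$prob_activated)
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  mean_tbl <- dplyr::summarise(fold_tbl, dplyr::across(-c(fold, n_test), mean))
  structure(list(folds = fold_tbl, mean = mean_tbl,
                 predictions = dplyr::bind_rows(preds),
                 modality = config$modality, k_folds = config$k_folds,
                 seed = config$seed),
            class = "glia_cv")
}

#' @export
print.glia_cv <- function(x, ...) {
  cat(sprintf("<glia_cv> %s, %d folds; mean test accuracy %.4f (AUC %.4f)\n",
              x$modality, x$k_folds, x$mean$accuracy, x$mean$auc))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x `glia_cv`.
#' @param ... Unused.
#' @return Tibble of per-fold test/train metrics.
#' @method tidy glia_cv
#' @export
tidy.glia_cv <- function(x, ...) x$folds

#' One-row cross-validation summary (fold-averaged metrics)
#'
#' @param x `glia_cv`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance glia_cv
#' @export
glance.glia_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(modality = x$modality, k_folds = x$k_folds), x$mean)
}

#' Accuracy over the feature-family subset grid
#'
#' Runs [cross_validate()] for each of the 15 non-empty combinations of the
#' four feature families (4 singletons, 6 pairs, 4 triples, all four) and
#' tabulates the mean test accuracy of each.
#'
#' @param bundle `glia_bundle`.
#' @param config `glia_config`; its `feature_subset` is ignored.
#' @return Tibble: `feature_set` (label like `"GenShape+ChordLen"`),
#'   `n_features`, `accuracy`, `auc`.
#' @export
feature_subset_grid <- function(bundle, config) {
  fams <- c("GenShape", "Mom", "ChordLen", "ElliFou")
  combos <- unlist(lapply(1:4, function(k) {
    utils::combn(fams, k, simplify = FALSE)
  }), recursive = FALSE)
  full <- extract_feature_table(bundle, "all")
  rows <- lapply(combos, function(sub) {
    cfg <- config
    cfg$feature_subset <- sub
    cols <- feature_names(sub)
    feats <- full[, c("cell_id", cols)]
    cv <- cross_validate(bundle, cfg, features = feats)
    tibble::tibble(
      feature_set = if (length(sub) == 4L) "All" else paste(sub, collapse = "+"),
      n_features = length(cols),
      accuracy = cv$mean$accuracy, auc = cv$mean$auc
    )
  })
  dplyr::bind_rows(rows)
}

#' Accuracy as a function of training-set size
#'
#' For each fraction, a stratified seeded split keeps that share of cells for
#' training and evaluates once on the held-out remainder.
#'
#' @param bundle `glia_bundle`.
#' @param config `glia_config`.
#' @param fractions Training fractions in `(0, 1)`.
#' @return Tibble: `fraction`, `n_train`, `n_test`, `accuracy`, `auc`.
#' @export
learning_curve <- function(bundle, config, fractions = c(0.6, 0.7, 0.8, 0.9)) {
  stopifnot(all(fractions > 0 & fractions < 1))
  labels <- bundle$label
  full <- extract_feature_table(bundle, config$feature_subset)
  X <- as_feature_matrix(full)
  rows <- lapply(fractions, function(fr) {
    train_idx <- integer(0)
    with_seed(derive_seed(config$seed, paste0("lc", round(fr * 100))), {
      for (cls in unique(labels)) {
        members <- which(labels == cls)
        take <- round(length(members) * fr)
        train_idx <- c(train_idx, sample(members, take))
      }
    })
    test_idx <- setdiff(seq_along(labels), train_idx)
    seqs_train <- seqs_test <- NULL
    if (config$modality == "joint") {
      edges <- compute_bin_edges(bundle$counts[train_idx], config$h)
      seqs_train <- lapply(bundle$counts[train_idx], decay_to_sequence, edges = edges)
      seqs_test <- lapply(bundle$counts[test_idx], decay_to_sequence, edges = edges)
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("lcfit", round(fr * 100)))
    model <- train_joint(X[train_idx, , drop = FALSE], seqs_train, labels[train_idx], cfg)
    pr <- predict(model, X[test_idx, , drop = FALSE], seqs_test)
    m <- compute_metrics(labels[test_idx], pr$prob_activated)
    tibble::tibble(fraction = fr, n_train = length(train_idx),
                   n_test = length(test_idx), accuracy = m$accuracy, auc = m$auc)
  })
  dplyr::bind_rows(rows)
}
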