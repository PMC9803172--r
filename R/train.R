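par_add <- function(a, b, scale = 1) {
  for (nm in names(a)) {
    if (is.list(a[[nm]])) {
      for (k in names(a[[nm]])) a[[nm]][[k]] <- a[[nm]][[k]] + scale * b[[nm]][[k]]
    } else {
      a[[nm]] <- a[[nm]] + scale * b[[nm]]
    }
  }
  a
}

par_zero <- function(a) {
  for (nm in names(a)) {
    if (is.list(a[[nm]])) {
      for (k in names(a[[nm]])) a[[nm]][[k]][] <- 0
    } else {
      a[[nm]][] <- 0
    }
  }
  a
}

par_scale <- function(a, s) {
  for (nm in names(a)) {
    if (is.list(a[[nm]])) {
      for (k in names(a[[nm]])) a[[nm]][[k]] <- s * a[[nm]][[k]]
    } else {
      a[[nm]] <- s * a[[nm]]
    }
  }
  a
}

#' Train the fused classifier with minibatch SGD
#'
#' Minibatch stochastic gradient descent with momentum on the mean
#' cross-entropy, for `config$epochs` epochs with per-epoch seeded shuffling
#' and seeded inverted dropout on the BLSTM output. The feature training
#' mean (used for centring) and the batch-norm running statistics are stored
#' in the returned model, so inference needs no training data. Fully
#' reproducible from `config$seed`.
#'
#' @param features Numeric matrix (`n_samples x n_features`) or tibble with
#'   `cell_id` plus feature columns. For the `shape_plus_tau` modality the
#'   `tau_mean` column must already be appended.
#' @param sequences List of `p x h` lifetime sequences (joint modality), else
#'   `NULL`.
#' @param labels Integer vector in `{0, 1}`.
#' @param config `glia_config`.
#' @return A fitted `glia_model`; `$loss_trace` is a tibble with one row per
#'   epoch: `epoch`, `cross_entropy`, `misclassification`.
#' @export
train_joint <- function(features, sequences = NULL, labels, config) {
  X <- as_feature_matrix(features)
  n_samp <- nrow(X)
  stopifnot(length(labels) == n_samp)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    abort_glia("training set needs at least 2 samples of each class", "glia_single_class")
  }
  if (config$modality == "joint") {
    stopifnot(!is.null(sequences), length(sequences) == n_samp)
    seq_h <- ncol(sequences[[1L]])
  } else {
    sequences <- NULL
    seq_h <- config$h
  }
  model <- init_model(ncol(X), config, seq_h = seq_h)
  model$feat_mean <- colMeans(X)
  lr <- config$learning_rate
  mom <- config$momentum
  vel <- par_zero(model$par)
  trace <- matrix(0, config$epochs, 2L)
  H2 <- 2L * model$hidden_size
  for (epoch in seq_len(config$epochs)) {
    ep_seed <- derive_seed(config$seed, paste0("epoch", epoch))
    epoch_stats <- with_seed(ep_seed, {
      ord <- sample.int(n_samp)
      n_batches <- ceiling(n_samp / config$batch_size)
      losses <- numeric(n_batches)
      errs <- numeric(n_batches)
      wts <- numeric(n_batches)
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n_samp)]
        Xb <- X[idx, , drop = FALSE]
        sb <- if (!is.null(sequences)) sequences[idx] else NULL
        dm <- if (config$modality == "joint" && model$dropout_rate > 0) {
          matrix((stats::runif(length(idx) * H2) >= model$dropout_rate) /
                   (1 - model$dropout_rate), length(idx), H2)
        } else {
          NULL
        }
        fw <- model_forward(model, Xb, sb, training = TRUE, dropout_mask = dm,
                            update_stats = TRUE)
        model <- fw$model
        lb <- labels[idx]
        losses[bi] <- suppressWarnings(cross_entropy_loss(fw$probs, lb))
        errs[bi] <- mean((fw$probs[, 2L] > 0.5) != (lb == 1L))
        wts[bi] <- length(idx)
        grads <- model_backward(model, fw$cache, lb, training = TRUE)
        vel <- par_add(par_scale(vel, mom), grads, scale = -lr)
        model$par <- par_add(model$par, vel)
      }
      c(sum(losses * wts) / sum(wts), sum(errs * wts) / sum(wts))
    })
    trace[epoch, ] <- epoch_stats
  }
  model$loss_trace <- tibble::tibble(epoch = seq_len(config$epochs),
                                     cross_entropy = trace[, 1L],
                                     misclassification = trace[, 2L])
  model
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[, setdiff(names(features), "cell_id"), drop = FALSE])
  }
  storage.mode(features) <- "double"
  features
}

#' Predict activation probabilities
#'
#' @param object Fitted `glia_model`.
#' @param features Feature matrix or tibble (as in [train_joint()]).
#' @param sequences List of lifetime sequences (joint modality).
#' @param ... Unused.
#' @return Tibble with `prob_activated` and hard `pred` at threshold 0.5.
#' @export
predict.glia_model <- function(object, features, sequences = NULL, ...) {
  X <- as_feature_matrix(features)
  seqs <- if (object$modality == "joint") sequences else NULL
  fw <- model_forward(object, X, seqs, training = FALSE)
  tibble::tibble(prob_activated = fw$probs[, 2L],
                 pred = as.integer(fw$probs[, 2L] > 0.5))
}

#' @export
print.glia_model <- function(x, ...) {
  cat(sprintf("<glia_model> modality=%s, %d input features, hidden=%d/dir\n",
              x$modality, x$n_features, x$hidden_size))
  if (!is.null(x$loss_trace)) {
    n <- nrow(x$loss_trace)
    cat(sprintf("  trained %d epochs; final CE %.4f, misclassification %.4f\n",
                n, x$loss_trace$cross_entropy[n], x$loss_trace$misclassification[n]))
  }
  invisible(x)
}

#' Tidy a fitted model's per-epoch training trace
#'
#' @param x `glia_model`.
#' @param ... Unused.
#' @return Tibble `epoch`, `cross_entropy`, `misclassification`.
#' @method tidy glia_model
#' @export
tidy.glia_model <- function(x, ...) {
  x$loss_trace %||% tibble::tibble(epoch = integer(), cross_entropy = numeric(),
                                   misclassification = numeric())
}

#' One-row model summary
#'
#' @param x `glia_model`.
#' @param ... Unused.
#' @return Tibble with modality, parameter count and final training losses.
#' @method glance glia_model
#' @export
glance.glia_model <- function(x, ...) {
  count <- function(p) {
    if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  }
  tr <- x$loss_trace
  tibble::tibble(
    modality = x$modality,
    n_parameters = count(x$par),
    epochs = if (is.null(tr)) 0L else nrow(tr),
    final_cross_entropy = if (is.null(tr)) NA_real_ else tr$cross_entropy[nrow(tr)],
    final_misclassification = if (is.null(tr)) NA_real_ else tr$misclassification[nrow(tr)]
  )
}

#' Serialize / restore a model as JSON
#'
#' Weights are written as nested arrays together with the architecture
#' echo, so a model round-trips through plain text.
#'
#' @param model `glia_model`.
#' @param path JSON path.
#' @return `write_model()`: `path` invisibly; `read_model()`: a `glia_model`.
#' @export
write_model <- function(model, path) {
  ser <- list(
    meta = list(modality = model$modality, n_features = model$n_features,
                seq_h = model$seq_h, hidden_size = model$hidden_size,
                dropout_rate = model$dropout_rate,
                feature_subset = model$feature_subset),
    par = model$par,
    buffers = list(feat_mean = model$feat_mean,
                   bn1_mean = model$bn1_mean, bn1_var = model$bn1_var,
                   bn2_mean = model$bn2_mean, bn2_var = model$bn2_var,
                   bin_edges = model$bin_edges)
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_mat <- function(x) if (is.matrix(x)) x else as.numeric(x)
  par <- ser$par
  for (nm in names(par)) {
    if (is.list(par[[nm]])) {
      for (k in names(par[[nm]])) par[[nm]][[k]] <- fix_mat(par[[nm]][[k]])
    } else {
      par[[nm]] <- fix_mat(par[[nm]])
    }
  }
  model <- structure(list(
    par = par,
    pairs = pair_index(ser$meta$n_features),
    n_features = ser$meta$n_features,
    seq_h = ser$meta$seq_h,
    hidden_size = ser$meta$hidden_size,
    modality = ser$meta$modality,
    dropout_rate = ser$meta$dropout_rate,
    feature_subset = ser$meta$feature_subset,
    feat_mean = ser$buffers$feat_mean,
    bn1_mean = ser$buffers$bn1_mean, bn1_var = ser$buffers$bn1_var,
    bn2_mean = ser$buffers$bn2_mean, bn2_var = ser$buffers$bn2_var,
    bin_edges = ser$buffers$bin_edges,
    loss_trace = NULL
  ), class = "glia_model")
  model
}
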