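test_that("feature convolution enumerates pairs lexicographically", {
  out <- feature_conv_forward(c(1, 2, 3), alpha = c(1, 1, 1), beta = c(0, 0, 0))
  # pairs (1,2), (1,3), (2,3): phi = alpha_i x_i + beta_j x_j = (1, 1, 2)
  expect_equal(out, c(1, 2, 3, 1, 1, 2))
  out0 <- feature_conv_forward(c(4, -2), alpha = c(0, 0), beta = c(0, 0))
  expect_equal(out0, c(4, -2, 0))
  expect_length(feature_conv_forward(rnorm(67), rnorm(67), rnorm(67)),
                67 + 2211)
  expect_error(feature_conv_forward(1, 1, 1), class = "glia_shape_mismatch")
})

test_that("the LSTM cell obeys its closed-form limits", {
  H <- 3
  w0 <- list(W = matrix(0, 4 * H, 2), U = matrix(0, 4 * H, H), b = rep(0, 4 * H))
  st <- lstm_cell_step(c(5, -7), rep(0, H), rep(0, H), w0)
  expect_equal(st$h, rep(0, H))     # candidate tanh(0) = 0 forces h = c = 0
  expect_equal(st$c, rep(0, H))
  set.seed(4)
  w <- list(W = matrix(rnorm(4 * H * 2, sd = 3), 4 * H, 2),
            U = matrix(rnorm(4 * H * H, sd = 3), 4 * H, H),
            b = rnorm(4 * H, sd = 3))
  h <- rep(0, H); cs <- rep(0, H)
  for (t in 1:20) {
    st <- lstm_cell_step(rnorm(2, sd = 10), h, cs, w)
    h <- st$h; cs <- st$c
    expect_true(all(abs(h) < 1))    # |o| < 1 and |tanh(c)| < 1
  }
  expect_error(lstm_cell_step(c(1, 2, 3), h, cs, w), class = "glia_shape_mismatch")
})

test_that("rollouts match an independent scalar oracle for p <= 16", {
  set.seed(14)
  for (p in c(3, 9, 16)) {
    H <- 2; hin <- 3
    w <- list(W = matrix(rnorm(4 * H * hin), 4 * H, hin),
              U = matrix(rnorm(4 * H * H), 4 * H, H),
              b = rnorm(4 * H))
    xseq <- matrix(rnorm(p * hin), p, hin)
    oracle <- lstm_scalar_oracle(xseq, w, H)
    run <- gliastate:::lstm_run(xseq, 1L, w, H, keep_cache = FALSE)
    expect_lt(max(abs(as.vector(run$h) - oracle)), 1e-12)
    # the pure-R kernel agrees with the compiled one exactly
    run_r <- gliastate:::lstm_run_r(xseq, 1L, w, H, keep_cache = FALSE)
    expect_equal(run$h, run_r$h)
  }
})

test_that("the bidirectional pass is symmetric on palindromes and deterministic", {
  set.seed(15)
  H <- 4; hin <- 3
  w <- list(W = matrix(rnorm(4 * H * hin), 4 * H, hin),
            U = matrix(rnorm(4 * H * H), 4 * H, H), b = rnorm(4 * H))
  half <- matrix(rnorm(4 * hin), 4, hin)
  pal <- rbind(half, half[4:1, ])
  out <- blstm_forward(pal, w, w, mode = "inference")
  expect_equal(out[1:H], out[H + 1:H])
  set.seed(99); o1 <- blstm_forward(pal, w, w, mode = "inference")
  set.seed(1234); o2 <- blstm_forward(pal, w, w, mode = "inference")
  expect_identical(o1, o2)
  expect_error(blstm_forward(matrix(nrow = 0, ncol = 3), w, w),
               class = "glia_shape_mismatch")
})

test_that("training-mode dropout zeroes half the elements and rescales the rest", {
  set.seed(16)
  H <- 10; hin <- 4
  w <- list(W = matrix(rnorm(4 * H * hin), 4 * H, hin),
            U = matrix(rnorm(4 * H * H), 4 * H, H), b = rnorm(4 * H))
  xseq <- matrix(rnorm(5 * hin), 5, hin)
  base <- blstm_forward(xseq, w, w, mode = "inference")
  zeros <- 0L; total <- 0L
  set.seed(17)
  for (rep in 1:500) {
    out <- blstm_forward(xseq, w, w, mode = "train", dropout_rate = 0.5)
    surv <- out != 0
    expect_equal(out[surv], 2 * base[surv])   # inverted dropout: survivors x2
    zeros <- zeros + sum(!surv); total <- total + length(out)
  }
  expect_gte(total, 1e4)
  expect_gt(zeros / total, 0.47)
  expect_lt(zeros / total, 0.53)
})

test_that("joint forward produces a probability pair and honors modality", {
  cfg <- tiny_config(modality = "joint")
  model <- init_model(10, cfg, seq_h = 8)
  x <- rnorm(10)
  sq <- matrix(runif(16 * 8), 16, 8); sq <- sq / rowSums(sq)
  pr <- joint_forward(list(features = x, sequence = sq), model)
  expect_length(pr, 2L)
  expect_equal(sum(pr), 1)
  expect_true(all(pr > 0 & pr < 1))
  expect_error(joint_forward(list(features = x), model),
               class = "glia_modality_mismatch")
  expect_error(joint_forward(list(features = rnorm(4), sequence = sq), model),
               class = "glia_shape_mismatch")

  # shape_only output is independent of the lifetime branch entirely
  cfg2 <- tiny_config(modality = "shape_only")
  m2 <- init_model(10, cfg2)
  p1 <- joint_forward(list(features = x, sequence = sq), m2)
  p2 <- joint_forward(list(features = x, sequence = matrix(runif(128), 16, 8)), m2)
  expect_identical(p1, p2)

  # tied logits give (0.5, 0.5): zero head weights collapse both logits
  m3 <- m2
  m3$par$Wh[] <- 0; m3$par$bh[] <- 0; m3$par$g2[] <- 1; m3$par$s2[] <- 0
  expect_equal(joint_forward(list(features = x), m3), c(0.5, 0.5))
})

test_that("shape subnetwork activations are non-negative and deterministic", {
  cfg <- tiny_config(modality = "shape_only")
  model <- init_model(12, cfg)
  x <- rnorm(12)
  s1 <- shape_subnet_forward(x, model)
  expect_length(s1, 50L)
  expect_true(all(s1 >= 0))
  expect_identical(s1, shape_subnet_forward(x, model))
  mz <- model; mz$par$Wc[] <- 0; mz$par$bc[] <- 0; mz$par$s1[] <- 0
  expect_equal(shape_subnet_forward(rnorm(12), mz), rep(0, 50))
  expect_error(shape_subnet_forward(rnorm(5), model), class = "glia_shape_mismatch")
})

test_that("cross-entropy matches closed forms and clips impossible probabilities", {
  expect_equal(cross_entropy_loss(c(0.4, 0.6), 1L), -log(0.6))
  expect_equal(cross_entropy_loss(c(0, 1), 1L), 0)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), 0L), log(2))
  batch <- rbind(c(0, 1), c(0.5, 0.5))
  expect_equal(cross_entropy_loss(batch, c(1L, 0L)), log(2) / 2)
  expect_warning(l <- cross_entropy_loss(c(1, 0), 1L), "clipped")
  expect_equal(l, -log(1e-12))
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  cfg <- glia_config(modality = "joint", h = 3, hidden_size = 3, epochs = 1,
                     seed = 5, batch_size = 4)
  n <- 4; B <- 4; p <- 5
  model <- init_model(n, cfg, seq_h = 3)
  model$feat_mean <- rnorm(n, 0, 0.1)
  X <- matrix(rnorm(B * n), B, n)
  seqs <- lapply(1:B, function(i) matrix(runif(p * 3), p, 3))
  labels <- c(0L, 1L, 1L, 0L)
  dm <- matrix((runif(B * 6) >= 0.5) * 2, B, 6)  # frozen dropout mask
  fw <- gliastate:::model_forward(model, X, seqs, training = TRUE, dropout_mask = dm)
  gr <- gliastate:::model_backward(model, fw$cache, labels, training = TRUE)
  lossfn <- function(m) {
    f <- gliastate:::model_forward(m, X, seqs, training = TRUE, dropout_mask = dm)
    suppressWarnings(cross_entropy_loss(f$probs, labels))
  }
  eps <- 1e-6
  worst <- 0
  for (nm in names(model$par)) {
    obj <- model$par[[nm]]
    keys <- if (is.list(obj)) names(obj) else NA
    for (k in keys) {
      v <- if (is.list(obj)) obj[[k]] else obj
      for (ix in sample(length(v), min(6, length(v)))) {
        bump <- function(h) {
          m2 <- model
          if (is.list(obj)) m2$par[[nm]][[k]][ix] <- v[ix] + h
          else m2$par[[nm]][ix] <- v[ix] + h
          m2
        }
        num <- (lossfn(bump(eps)) - lossfn(bump(-eps))) / (2 * eps)
        ana <- if (is.list(obj)) gr[[nm]][[k]][ix] else gr[[nm]][ix]
        worst <- max(worst, abs(num - ana) / max(1, abs(num), abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training is reproducible, reduces the loss, and fits a separable set", {
  set.seed(21)
  n <- 40
  labels <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[labels == 1L, 1] <- X[labels == 1L, 1] + 6   # linearly separable feature
  cfg <- glia_config(modality = "shape_only", epochs = 50, seed = 2,
                     batch_size = 8, learning_rate = 0.05, h = 8)
  m1 <- train_joint(X, NULL, labels, cfg)
  m2 <- train_joint(X, NULL, labels, cfg)
  expect_identical(m1$par, m2$par)
  tr <- tidy(m1)
  expect_lt(tr$cross_entropy[nrow(tr)], tr$cross_entropy[1L])
  pr <- predict(m1, X)
  expect_equal(mean(pr$pred == labels), 1.0)
  expect_error(train_joint(X[labels == 0L, ], NULL, labels[labels == 0L], cfg),
               class = "glia_single_class")
})

test_that("models round-trip through JSON serialization", {
  set.seed(22)
  labels <- rep(c(0L, 1L), 8)
  X <- matrix(rnorm(16 * 5), 16, 5)
  sq <- lapply(1:16, function(i) {
    s <- matrix(runif(12 * 8), 12, 8); s / rowSums(s)
  })
  cfg <- tiny_config(modality = "joint", epochs = 2)
  model <- train_joint(X, sq, labels, cfg)
  td <- withr::local_tempdir()
  path <- file.path(td, "model.json")
  write_model(model, path)
  back <- read_model(path)
  p_orig <- predict(model, X, sq)
  p_back <- predict(back, X, sq)
  expect_equal(p_back$prob_activated, p_orig$prob_activated, tolerance = 1e-12)
})
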