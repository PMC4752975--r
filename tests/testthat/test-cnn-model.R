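naive_convolve <- function(x, t, b) {
  # independent double-loop oracle for the convolution
  k <- ncol(t); n <- ncol(x)
  out <- numeric(n - k + 1L)
  for (i in seq_len(n - k + 1L)) {
    acc <- 0
    for (j in seq_len(k)) acc <- acc + sum(t[, j] * x[, i + j - 1L])
    out[i] <- tanh(acc + b)
  }
  out
}

test_that("convolution matches the naive double-loop oracle on random instances", {
  set.seed(100)
  for (rep in 1:5) {
    D <- sample(3:8, 1); n <- 6L; k <- sample(2:4, 1)
    x <- matrix(rnorm(D * n), D, n)
    t <- matrix(rnorm(D * k), D, k)
    b <- rnorm(1)
    expect_equal(convolve_filter(x, t, b), naive_convolve(x, t, b),
                 tolerance = 1e-10)
  }
})

test_that("convolution shape and degenerate cases follow the definition", {
  x <- matrix(rnorm(10 * 150), 10, 150)
  t <- matrix(rnorm(10 * 5), 10, 5)
  expect_length(convolve_filter(x, t, 0), 146L)
  expect_equal(convolve_filter(x, t * 0, 0), rep(0, 146L))  # tanh(0) = 0
  expect_error(convolve_filter(x[, 1:3], t, 0), "smaller than filter width")
})

test_that("max pooling takes per-filter maxima and is permutation-invariant", {
  expect_equal(max_pool(list(c(-0.3, 0.9, 0.1))), 0.9)
  fvs <- replicate(7, rnorm(5), simplify = FALSE)
  z <- max_pool(fvs)
  expect_length(z, 7L)
  expect_equal(max_pool(lapply(fvs, rev)), z)
})

test_that("forward pass yields a normalized probability vector", {
  tm <- tiny_trained_model()
  probs <- cnn_forward(tm$model, tm$instances[[6]])
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_named(probs, DDI_CLASSES)
  # equal logits give uniform probabilities
  expect_equal(ddicnn:::softmax_probs(rep(1.7, 5)), rep(0.2, 5))
})

test_that("with dropout probability 0 the train and test forward agree exactly", {
  tm <- tiny_trained_model()
  inst <- tm$instances[[7]]
  fw_test <- ddicnn:::model_forward_one(tm$model, inst, train = FALSE)
  fw_train <- ddicnn:::model_forward_one(tm$model, inst, train = TRUE)
  expect_identical(fw_test$probs, fw_train$probs)
})

test_that("analytic gradients match central finite differences on a tiny model", {
  tm <- tiny_trained_model()
  model <- tm$model
  batch <- tm$instances[6:10]
  g <- ddicnn:::model_gradients(model, batch)
  relerr <- function(a, b)
    max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
  num_grad <- function(get, set) {
    p <- get(); gn <- p * 0; h <- 1e-4
    for (i in seq_along(p)) {
      p2 <- p
      p2[i] <- p[i] + h; model <- set(model, p2)
      lp <- ddicnn:::model_loss(model, batch)
      p2[i] <- p[i] - h; model <- set(model, p2)
      lm <- ddicnn:::model_loss(model, batch)
      model <- set(model, p)
      gn[i] <- (lp - lm) / (2 * h)
    }
    gn
  }
  gn <- num_grad(function() model$softmax$W,
                 function(m, v) { m$softmax$W <- v; m })
  expect_lt(relerr(g$W, gn), 1e-4)
  gn <- num_grad(function() model$softmax$b,
                 function(m, v) { m$softmax$b <- v; m })
  expect_lt(relerr(g$Wb, gn), 1e-4)
  for (wi in 1:2) {
    gn <- num_grad(function() model$bank$filters[[wi]]$T,
                   function(m, v) { m$bank$filters[[wi]]$T <- v; m })
    expect_lt(relerr(g$conv[[wi]]$dT, gn), 1e-4)
    gn <- num_grad(function() model$bank$filters[[wi]]$b,
                   function(m, v) { m$bank$filters[[wi]]$b <- v; m })
    expect_lt(relerr(g$conv[[wi]]$db, gn), 1e-4)
  }
  gn <- num_grad(function() model$tables$D1,
                 function(m, v) { m$tables$D1 <- v; m })
  expect_lt(relerr(g$D1, gn), 1e-4)
  gn <- num_grad(function() model$tables$D2,
                 function(m, v) { m$tables$D2 <- v; m })
  expect_lt(relerr(g$D2, gn), 1e-4)
  # word embeddings: check the columns actually looked up
  cols <- sort(unique(unlist(lapply(batch, function(inst)
    ddicnn:::encode_instance(inst, model$tables)$word_idx))))
  gn <- num_grad(function() model$tables$C[, cols],
                 function(m, v) { m$tables$C[, cols] <- v; m })
  expect_lt(relerr(g$C[, cols], gn), 1e-4)
  # gradient is zero at columns never looked up
  expect_true(all(g$C[, -cols] == 0))
})

test_that("AdaDelta leaves parameters unchanged under a zero gradient", {
  p <- matrix(rnorm(6), 2, 3)
  st <- ddicnn:::adadelta_init(p)
  up <- ddicnn:::adadelta_update(p, p * 0, st, rho = 0.95, eps = 1e-6)
  expect_identical(up$param, p)
})

test_that("l2 rescaling lands over-norm softmax rows at exactly the threshold", {
  W <- rbind(c(6, 0, 0), c(1, 1, 1), c(0, 0, 0))
  W2 <- ddicnn:::l2_rescale_rows(W, s = 3)
  expect_equal(sqrt(sum(W2[1, ]^2)), 3)
  expect_equal(W2[2, ], W[2, ])   # under-norm rows untouched
  expect_equal(W2[3, ], W[3, ])
})

test_that("training is reproducible: identical seeds give identical loss traces", {
  corp <- make_separable(60, seed = 5)
  insts <- corpus_instances(corp, n = 12L)
  vocab <- build_vocab(insts)
  cfg <- ddi_train_config(d_w = 8L, d_p = 2L, n = 12L, widths = c(3L),
                          n_filters = c(4L), epochs = 3L, minibatch = 10L,
                          dropout = 0.5, seed = 77L)
  tab <- init_tables(vocab, d_w = 8L, d_p = 2L, n = 12L, seed = 77L)
  m1 <- train_cnn(insts, tab, cfg)
  m2 <- train_cnn(insts, tab, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$softmax$W, m2$softmax$W)
})

test_that("training rejects empty or unlabeled streams", {
  corp <- make_separable(10, seed = 5)
  insts <- corpus_instances(corp, n = 12L)
  vocab <- build_vocab(insts)
  tab <- init_tables(vocab, d_w = 4L, d_p = 2L, n = 12L, seed = 1)
  cfg <- ddi_train_config(d_w = 4L, d_p = 2L, n = 12L, widths = 3L,
                          n_filters = 2L, epochs = 1L)
  expect_error(train_cnn(list(), tab, cfg), "empty")
  bad <- insts
  bad[[1]]$label <- NA_character_
  expect_error(train_cnn(bad, tab, cfg), "gold label")
})

test_that("cross-entropy decreases and a separable set is fit to high accuracy", {
  corp <- make_separable(200, seed = 11)
  insts <- corpus_instances(corp, n = 14L)
  vocab <- build_vocab(insts)
  cfg <- ddi_train_config(d_w = 16L, d_p = 4L, n = 14L, widths = c(3L, 4L),
                          n_filters = c(6L, 6L), epochs = 15L,
                          minibatch = 10L, dropout = 0, seed = 5L)
  tab <- init_tables(vocab, d_w = 16L, d_p = 4L, n = 14L, seed = 5L)
  m <- train_cnn(insts, tab, cfg)
  # strictly decreasing over the early epochs
  expect_true(all(diff(m$history$loss[1:5]) < 0))
  pred <- predict_ddi(m, insts)
  gold <- vapply(insts, function(x) x$label, character(1))
  expect_gte(mean(pred$predicted == gold), 0.95)
})

test_that("prediction respects filter decisions and breaks ties by class order", {
  tm <- tiny_trained_model()
  inst <- tm$instances[[11]]
  dec <- data.frame(sentence_id = inst$sentence_id, e1 = inst$e1,
                    e2 = inst$e2, filtered = TRUE, criterion = "same_name")
  pred <- predict_ddi(tm$model, list(inst), dec)
  expect_equal(pred$predicted, "negative")
  expect_equal(pred$source, "filter")
  # unfiltered: deterministic argmax
  p1 <- predict_ddi(tm$model, list(inst))
  p2 <- predict_ddi(tm$model, list(inst))
  expect_identical(p1, p2)
  expect_equal(p1$source, "model")
  # argmax tie goes to the earlier class in DDI_CLASSES order
  expect_equal(DDI_CLASSES[which.max(rep(0.2, 5))], "mechanism")
})

test_that("a model archive round-trips through the plain-text format", {
  tm <- tiny_trained_model()
  dir <- withr::local_tempdir()
  save_ddi_model(tm$model, dir)
  m2 <- load_ddi_model(dir)
  inst <- tm$instances[[3]]
  expect_equal(cnn_forward(m2, inst), cnn_forward(tm$model, inst),
               tolerance = 1e-7)
})
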