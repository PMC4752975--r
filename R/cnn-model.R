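# Convolutional classifier over the (d_w + 2 d_p) x n instance matrix:
# multi-width convolution filters with tanh, max-over-time pooling, dropout,
# and a fully connected softmax over the 5 classes. Training is minibatch
# SGD with the AdaDelta update rule and per-row l2 rescaling of the softmax
# weight matrix. Forward pass and backpropagation are written out in base R
# matrix algebra and verified against finite differences in the test suite.

#' Training / architecture configuration
#'
#' Defaults are the published operating point of the method: 300-dimensional
#' word embeddings, 10-dimensional position embeddings, instance length 150,
#' filter widths 3/4/5 with 200 filters each, dropout 0.5, l2-norm threshold
#' 3 on the softmax rows, minibatch size 50.
#'
#' @param d_w word-embedding dimension.
#' @param d_p position-embedding dimension (0 = words-only ablation).
#' @param n instance length in tokens.
#' @param widths convolution filter widths.
#' @param n_filters filter count per width (recycled to `length(widths)`).
#' @param dropout dropout probability p on the pooled vector at train time.
#' @param l2_threshold s: softmax weight rows are rescaled to norm s whenever
#'   their l2 norm exceeds s.
#' @param minibatch minibatch size.
#' @param adadelta_rho,adadelta_eps AdaDelta decay and stabilizer.
#' @param epochs number of passes over the training data.
#' @param seed RNG seed: fixes parameter init, shuffling and dropout masks.
#' @param loss_agg minibatch loss aggregation, mean (default) or sum.
#' @param paper_exact_dropout if TRUE, masked activations are not rescaled
#'   by 1/(1-p) at train time (the literal published convention); default
#'   FALSE uses inverted dropout so train and test expectations match.
#' @param freeze_words if TRUE, pretrained word vectors are not updated.
#' @param init_range half-width of uniform parameter initialization.
#' @return list of class `ddi_train_config`.
#' @export
ddi_train_config <- function(d_w = 300L, d_p = 10L, n = 150L,
                             widths = c(3L, 4L, 5L),
                             n_filters = c(200L, 200L, 200L),
                             dropout = 0.5, l2_threshold = 3,
                             minibatch = 50L,
                             adadelta_rho = 0.95, adadelta_eps = 1e-6,
                             epochs = 25L, seed = 1L,
                             loss_agg = c("mean", "sum"),
                             paper_exact_dropout = FALSE,
                             freeze_words = FALSE,
                             init_range = 0.05) {
  loss_agg <- match.arg(loss_agg)
  n_filters <- rep_len(as.integer(n_filters), length(widths))
  stopifnot(d_w > 0, d_p >= 0, n > 0, all(widths > 0), all(n_filters > 0),
            dropout >= 0, dropout < 1, l2_threshold > 0, minibatch > 0,
            epochs > 0)
  if (any(widths > n)) stop("filter width exceeds instance length n")
  structure(list(d_w = as.integer(d_w), d_p = as.integer(d_p),
                 n = as.integer(n), widths = as.integer(widths),
                 n_filters = n_filters, dropout = dropout,
                 l2_threshold = l2_threshold,
                 minibatch = as.integer(minibatch),
                 adadelta_rho = adadelta_rho, adadelta_eps = adadelta_eps,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss_agg = loss_agg,
                 paper_exact_dropout = paper_exact_dropout,
                 freeze_words = freeze_words, init_range = init_range),
            class = "ddi_train_config")
}

# stack k consecutive columns of x: column i of the result is
# [x[,i]; x[,i+1]; ...; x[,i+k-1]], for i = 1 .. n-k+1
make_windows <- function(x, k) {
  n <- ncol(x)
  if (n < k) stop("instance length ", n, " is smaller than filter width ", k)
  do.call(rbind, lapply(0:(k - 1L), function(j)
    x[, (1L + j):(n - k + 1L + j), drop = FALSE]))
}

#' Convolve an instance matrix with a single filter
#'
#' f_i = tanh(<t, x[, i:(i+k-1)]> + b) for i = 1 .. n-k+1, the inner product
#' taken elementwise over the (d_w + 2 d_p) x k window.
#'
#' @param x instance matrix, (d_w + 2 d_p) x n.
#' @param t filter matrix, same row count as x, k columns.
#' @param b scalar bias.
#' @return feature vector of length n - k + 1.
#' @export
convolve_filter <- function(x, t, b = 0) {
  k <- ncol(t)
  drop(tanh(as.vector(t) %*% make_windows(x, k) + b))
}

#' Max-over-time pooling
#'
#' Reduces each filter's feature vector to its maximum entry.
#'
#' @param fvs list of numeric feature vectors, one per filter.
#' @return numeric vector of length `length(fvs)`.
#' @export
max_pool <- function(fvs) {
  vapply(fvs, max, numeric(1))
}

new_filter_bank <- function(cfg, D) {
  filters <- list()
  for (wi in seq_along(cfg$widths)) {
    k <- cfg$widths[wi]; lk <- cfg$n_filters[wi]
    filters[[wi]] <- list(
      k = k,
      T = matrix(stats::runif(lk * D * k, -cfg$init_range, cfg$init_range),
                 nrow = lk),
      b = numeric(lk))
  }
  list(widths = cfg$widths, filters = filters, l = sum(cfg$n_filters))
}

new_softmax <- function(cfg, l) {
  list(W = matrix(stats::runif(5L * l, -cfg$init_range, cfg$init_range),
                  nrow = 5L),
       b = numeric(5L))
}

softmax_probs <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

# joint convolution + pooling over all widths; returns pooled z and the
# cache (windows, argmax positions, pooled activations) for backprop
conv_pool_forward <- function(x, bank) {
  z <- numeric(0)
  caches <- vector("list", length(bank$filters))
  for (wi in seq_along(bank$filters)) {
    f <- bank$filters[[wi]]
    W <- make_windows(x, f$k)
    A <- tanh(f$T %*% W + f$b)
    istar <- max.col(A, ties.method = "first")
    fhat <- A[cbind(seq_len(nrow(A)), istar)]
    z <- c(z, fhat)
    caches[[wi]] <- list(windows = W, istar = istar, fhat = fhat)
  }
  list(z = z, caches = caches)
}

conv_pool_backward <- function(dz, bank, caches, D, n) {
  dx <- matrix(0, D, n)
  conv_grads <- vector("list", length(bank$filters))
  off <- 0L
  for (wi in seq_along(bank$filters)) {
    f <- bank$filters[[wi]]; k <- f$k
    lk <- nrow(f$T)
    dzk <- dz[(off + 1L):(off + lk)]; off <- off + lk
    ca <- caches[[wi]]
    dpre <- dzk * (1 - ca$fhat^2)                  # through tanh at the max
    Awin <- ca$windows[, ca$istar, drop = FALSE]   # (D k) x lk
    dT <- t(Awin) * dpre                           # row j scaled by dpre[j]
    db <- dpre
    for (j in seq_len(lk)) {
      if (dpre[j] == 0) next
      i <- ca$istar[j]
      dx[, i:(i + k - 1L)] <- dx[, i:(i + k - 1L)] +
        matrix(dpre[j] * f$T[j, ], D, k)
    }
    conv_grads[[wi]] <- list(dT = dT, db = db)
  }
  list(dx = dx, conv = conv_grads)
}

model_forward_one <- function(model, inst, train = FALSE, mask = NULL) {
  enc <- encode_instance(inst, model$tables)
  cp <- conv_pool_forward(enc$x, model$bank)
  z <- cp$z
  p <- model$cfg$dropout
  if (train && p > 0) {
    if (is.null(mask)) mask <- stats::rbinom(length(z), 1L, 1 - p)
    zd <- if (model$cfg$paper_exact_dropout) z * mask else z * mask / (1 - p)
  } else {
    mask <- NULL
    zd <- z
  }
  logits <- drop(model$softmax$W %*% zd + model$softmax$b)
  list(enc = enc, cp = cp, z = z, mask = mask, zd = zd,
       logits = logits, probs = softmax_probs(logits))
}

zero_grads <- function(model) {
  g <- list(C = model$tables$C * 0,
            W = model$softmax$W * 0, Wb = model$softmax$b * 0,
            conv = lapply(model$bank$filters,
                          function(f) list(dT = f$T * 0, db = f$b * 0)))
  if (model$tables$d_p > 0L) {
    g$D1 <- model$tables$D1 * 0
    g$D2 <- model$tables$D2 * 0
  }
  g
}

# accumulate gradient of (scale * cross-entropy of one instance) into g
model_backward_one <- function(model, fw, y_index, scale, g) {
  dlogits <- fw$probs
  dlogits[y_index] <- dlogits[y_index] - 1
  dlogits <- dlogits * scale
  g$W <- g$W + dlogits %o% fw$zd
  g$Wb <- g$Wb + dlogits
  dzd <- drop(crossprod(model$softmax$W, dlogits))
  p <- model$cfg$dropout
  dz <- if (!is.null(fw$mask)) {
    if (model$cfg$paper_exact_dropout) dzd * fw$mask
    else dzd * fw$mask / (1 - p)
  } else dzd
  D <- nrow(fw$enc$x); n <- ncol(fw$enc$x)
  bk <- conv_pool_backward(dz, model$bank, fw$cp$caches, D, n)
  for (wi in seq_along(g$conv)) {
    g$conv[[wi]]$dT <- g$conv[[wi]]$dT + bk$conv[[wi]]$dT
    g$conv[[wi]]$db <- g$conv[[wi]]$db + bk$conv[[wi]]$db
  }
  d_w <- model$tables$d_w; d_p <- model$tables$d_p
  enc <- fw$enc
  for (i in seq_len(n)) {
    ci <- enc$word_idx[i]
    g$C[, ci] <- g$C[, ci] + bk$dx[1:d_w, i]
  }
  if (d_p > 0L) {
    r1 <- (d_w + 1L):(d_w + d_p)
    r2 <- (d_w + d_p + 1L):(d_w + 2L * d_p)
    for (i in seq_len(n)) {
      g$D1[, enc$pos1_idx[i]] <- g$D1[, enc$pos1_idx[i]] + bk$dx[r1, i]
      g$D2[, enc$pos2_idx[i]] <- g$D2[, enc$pos2_idx[i]] + bk$dx[r2, i]
    }
  }
  g
}

# mean cross-entropy of a batch with dropout off (used by gradient checks
# and for epoch-loss reporting)
model_loss <- function(model, instances) {
  y <- match(vapply(instances, function(x) x$label, character(1)), DDI_CLASSES)
  tot <- 0
  for (i in seq_along(instances)) {
    fw <- model_forward_one(model, instances[[i]], train = FALSE)
    tot <- tot - log(fw$probs[y[i]])
  }
  tot / length(instances)
}

model_gradients <- function(model, instances) {
  y <- match(vapply(instances, function(x) x$label, character(1)), DDI_CLASSES)
  g <- zero_grads(model)
  scale <- 1 / length(instances)
  for (i in seq_along(instances)) {
    fw <- model_forward_one(model, instances[[i]], train = FALSE)
    g <- model_backward_one(model, fw, y[i], scale, g)
  }
  g
}

adadelta_init <- function(param) list(Eg = param * 0, Ed = param * 0)

# one AdaDelta step; returns list(param, state). Zero gradient implies a
# zero step because the numerator accumulator stays zero.
adadelta_update <- function(param, grad, state, rho, eps) {
  state$Eg <- rho * state$Eg + (1 - rho) * grad^2
  delta <- -sqrt(state$Ed + eps) / sqrt(state$Eg + eps) * grad
  state$Ed <- rho * state$Ed + (1 - rho) * delta^2
  list(param = param + delta, state = state)
}

# rescale any row of W whose l2 norm exceeds s to norm exactly s
l2_rescale_rows <- function(W, s) {
  nrm <- sqrt(rowSums(W^2))
  over <- nrm > s
  if (any(over)) W[over, ] <- W[over, , drop = FALSE] * (s / nrm[over])
  W
}

#' Train the convolutional DDI classifier
#'
#' Minibatch stochastic gradient descent with the AdaDelta update rule over
#' cross-entropy loss. Updated parameters: the word-embedding matrix
#' (unless frozen), both position-embedding matrices, all convolution
#' filters and biases, and the softmax weights. After every step, softmax
#' weight rows with l2 norm above the threshold are rescaled onto it.
#' Minibatches are reshuffled each epoch under the configured seed; a fixed
#' seed gives bit-reproducible runs.
#'
#' @param instances labeled `ddi_instance` list (candidates surviving the
#'   negative-instance filter).
#' @param tables a `ddi_embeddings` from [init_tables] (dims must match cfg).
#' @param cfg a [ddi_train_config].
#' @return an object of class `ddi_model`: tables, bank, softmax, cfg, and a
#'   `history` data.frame of per-epoch mean training loss.
#' @export
train_cnn <- function(instances, tables, cfg = ddi_train_config()) {
  if (!length(instances)) stop("empty training stream")
  labels <- vapply(instances, function(x) x$label, character(1))
  if (anyNA(labels)) stop("all training instances must carry a gold label")
  y <- match(labels, DDI_CLASSES)
  if (anyNA(y)) stop("invalid labels: ",
                     paste(unique(labels[is.na(y)]), collapse = ", "))
  stopifnot(tables$d_w == cfg$d_w, tables$d_p == cfg$d_p, tables$n == cfg$n)

  set.seed(cfg$seed)
  D <- cfg$d_w + 2L * cfg$d_p
  bank <- new_filter_bank(cfg, D)
  softmax <- new_softmax(cfg, bank$l)
  model <- structure(list(tables = tables, bank = bank, softmax = softmax,
                          cfg = cfg, classes = DDI_CLASSES),
                     class = "ddi_model")

  st <- list(C = adadelta_init(tables$C),
             W = adadelta_init(softmax$W), Wb = adadelta_init(softmax$b),
             conv = lapply(bank$filters,
                           function(f) list(T = adadelta_init(f$T),
                                            b = adadelta_init(f$b))))
  if (cfg$d_p > 0L) {
    st$D1 <- adadelta_init(tables$D1)
    st$D2 <- adadelta_init(tables$D2)
  }
  rho <- cfg$adadelta_rho; eps <- cfg$adadelta_eps

  N <- length(instances)
  history <- data.frame(epoch = integer(), loss = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    epoch_loss <- 0
    starts <- seq(1L, N, by = cfg$minibatch)
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + cfg$minibatch - 1L, N)]
      scale <- if (cfg$loss_agg == "mean") 1 / length(idx) else 1
      g <- zero_grads(model)
      for (ii in idx) {
        fw <- model_forward_one(model, instances[[ii]], train = TRUE)
        li <- -log(fw$probs[y[ii]])
        if (!is.finite(li))
          stop("non-finite loss at epoch ", epoch, ", instance ",
               instances[[ii]]$sentence_id, " (", instances[[ii]]$e1, ",",
               instances[[ii]]$e2, ")")
        epoch_loss <- epoch_loss + li
        g <- model_backward_one(model, fw, y[ii], scale, g)
      }
      if (!cfg$freeze_words) {
        up <- adadelta_update(model$tables$C, g$C, st$C, rho, eps)
        model$tables$C <- up$param; st$C <- up$state
      }
      if (cfg$d_p > 0L) {
        up <- adadelta_update(model$tables$D1, g$D1, st$D1, rho, eps)
        model$tables$D1 <- up$param; st$D1 <- up$state
        up <- adadelta_update(model$tables$D2, g$D2, st$D2, rho, eps)
        model$tables$D2 <- up$param; st$D2 <- up$state
      }
      for (wi in seq_along(model$bank$filters)) {
        up <- adadelta_update(model$bank$filters[[wi]]$T, g$conv[[wi]]$dT,
                              st$conv[[wi]]$T, rho, eps)
        model$bank$filters[[wi]]$T <- up$param; st$conv[[wi]]$T <- up$state
        up <- adadelta_update(model$bank$filters[[wi]]$b, g$conv[[wi]]$db,
                              st$conv[[wi]]$b, rho, eps)
        model$bank$filters[[wi]]$b <- up$param; st$conv[[wi]]$b <- up$state
      }
      up <- adadelta_update(model$softmax$W, g$W, st$W, rho, eps)
      model$softmax$W <- up$param; st$W <- up$state
      up <- adadelta_update(model$softmax$b, g$Wb, st$Wb, rho, eps)
      model$softmax$b <- up$param; st$Wb <- up$state
      model$softmax$W <- l2_rescale_rows(model$softmax$W, cfg$l2_threshold)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss / N))
  }
  model$history <- history
  model
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("<ddi_model> conv widths ", paste(x$cfg$widths, collapse = "/"),
      " (", x$bank$l, " filters), d_w=", x$cfg$d_w, ", d_p=", x$cfg$d_p,
      ", n=", x$cfg$n, ", |V|=", length(x$tables$vocab), "\n", sep = "")
  if (!is.null(x$history))
    cat("trained ", nrow(x$history), " epochs, final loss ",
        signif(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Forward pass for one instance
#'
#' @param model a `ddi_model`.
#' @param instance a `ddi_instance`.
#' @return named probability vector over the five classes (sums to 1).
#' @export
cnn_forward <- function(model, instance) {
  stats::setNames(model_forward_one(model, instance, train = FALSE)$probs,
                  model$classes)
}

#' Predict labels for candidate instances
#'
#' Candidates removed by the negative-instance filter are assigned
#' `negative` without model evaluation (source `filter`); the rest get the
#' argmax class of the CNN (source `model`), ties broken by class order.
#'
#' @param model a `ddi_model`.
#' @param instances list of `ddi_instance` objects.
#' @param decisions optional data.frame from [corpus_filter_decisions]
#'   aligned by (sentence_id, e1, e2); NULL disables filtering.
#' @return data.frame: sentence_id, e1, e2, predicted, source.
#' @export
predict_ddi <- function(model, instances, decisions = NULL) {
  key <- function(sid, e1, e2) paste(sid, e1, e2, sep = "\r")
  filtered <- character(0)
  if (!is.null(decisions))
    filtered <- key(decisions$sentence_id, decisions$e1,
                    decisions$e2)[decisions$filtered]
  rows <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    if (key(inst$sentence_id, inst$e1, inst$e2) %in% filtered) {
      pred <- "negative"; src <- "filter"
    } else {
      probs <- model_forward_one(model, inst, train = FALSE)$probs
      pred <- DDI_CLASSES[which.max(probs)]; src <- "model"
    }
    rows[[i]] <- data.frame(sentence_id = inst$sentence_id, e1 = inst$e1,
                            e2 = inst$e2, predicted = pred, source = src,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# ---- model archive ---------------------------------------------------------

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

read_matrix_tsv <- function(path, nrow) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == nrow)
  m
}

#' Save a trained model as a plain-text archive directory
#'
#' Layout (version-stamped in `meta.json`): config + vocab as JSON,
#' embedding tables, filter tensors and softmax weights as TSV matrices.
#'
#' @param model a `ddi_model`.
#' @param dir target directory (created if needed).
#' @export
save_ddi_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = 1L,
               package_version = as.character(utils::packageVersion("ddicnn")),
               cfg = unclass(model$cfg), classes = model$classes,
               vocab = names(model$tables$vocab))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(model$tables$C, file.path(dir, "C.tsv"))
  if (model$cfg$d_p > 0L) {
    write_matrix_tsv(model$tables$D1, file.path(dir, "D1.tsv"))
    write_matrix_tsv(model$tables$D2, file.path(dir, "D2.tsv"))
  }
  for (wi in seq_along(model$bank$filters)) {
    f <- model$bank$filters[[wi]]
    write_matrix_tsv(f$T, file.path(dir, sprintf("filters_k%d.tsv", f$k)))
    write_matrix_tsv(matrix(f$b, nrow = 1),
                     file.path(dir, sprintf("bias_k%d.tsv", f$k)))
  }
  write_matrix_tsv(model$softmax$W, file.path(dir, "softmax_W.tsv"))
  write_matrix_tsv(matrix(model$softmax$b, nrow = 1),
                   file.path(dir, "softmax_b.tsv"))
  invisible(dir)
}

#' Load a model archive written by [save_ddi_model]
#'
#' @param dir archive directory.
#' @return a `ddi_model`.
#' @export
load_ddi_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(ddi_train_config,
                 meta$cfg[names(meta$cfg) %in% names(formals(ddi_train_config))])
  vocab <- stats::setNames(seq_along(meta$vocab), meta$vocab)
  C <- read_matrix_tsv(file.path(dir, "C.tsv"), cfg$d_w)
  colnames(C) <- names(vocab)
  if (cfg$d_p > 0L) {
    D1 <- read_matrix_tsv(file.path(dir, "D1.tsv"), cfg$d_p)
    D2 <- read_matrix_tsv(file.path(dir, "D2.tsv"), cfg$d_p)
  } else {
    D1 <- matrix(0, 0L, 2L * cfg$n - 1L)
    D2 <- D1
  }
  tables <- structure(list(C = C, D1 = D1, D2 = D2, vocab = vocab,
                           d_w = cfg$d_w, d_p = cfg$d_p, n = cfg$n),
                      class = "ddi_embeddings")
  filters <- list()
  for (wi in seq_along(cfg$widths)) {
    k <- cfg$widths[wi]
    filters[[wi]] <- list(
      k = k,
      T = read_matrix_tsv(file.path(dir, sprintf("filters_k%d.tsv", k)),
                          cfg$n_filters[wi]),
      b = drop(read_matrix_tsv(file.path(dir, sprintf("bias_k%d.tsv", k)), 1L)))
  }
  bank <- list(widths = cfg$widths, filters = filters,
               l = sum(cfg$n_filters))
  softmax <- list(W = read_matrix_tsv(file.path(dir, "softmax_W.tsv"), 5L),
                  b = drop(read_matrix_tsv(file.path(dir, "softmax_b.tsv"), 1L)))
  structure(list(tables = tables, bank = bank, softmax = softmax, cfg = cfg,
                 classes = meta$classes),
            class = "ddi_model")
}
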