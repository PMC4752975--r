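# Look-up table layer: word-embedding matrix C (d_w x |V|) and position
# embedding matrices D1, D2 (d_p x (2n-1)), one column per signed distance
# in [-n+1, n-1]. An instance becomes a (d_w + 2*d_p) x n matrix whose
# column i stacks the word vector of token i on the two position vectors of
# its distances to drug1 and drug2.

UNK_TOKEN <- "<unk>"

#' Build a vocabulary from training instances
#'
#' @param instances list of `ddi_instance` objects.
#' @return named integer vector mapping token to column index; always
#'   contains `drug1`, `drug2`, `drug0`, `#` and the unknown-token entry.
#' @export
build_vocab <- function(instances) {
  toks <- unique(unlist(lapply(instances, function(x) x$tokens)))
  toks <- union(c("drug1", "drug2", "drug0", "#", UNK_TOKEN), toks)
  stats::setNames(seq_along(toks), toks)
}

#' Read word vectors in word2vec text format
#'
#' Header line "count dim", then one line per token: "token v1 ... v_dim".
#'
#' @param path file path.
#' @return list: `vectors` (dim x count matrix), `tokens` (column names).
#' @export
read_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- scan(text = lines[1], what = integer(), n = 2, quiet = TRUE)
  count <- hdr[1]; dim <- hdr[2]
  toks <- character(count)
  mat <- matrix(0, nrow = dim, ncol = count)
  for (i in seq_len(count)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    if (length(parts) != dim + 1L)
      stop("malformed word2vec line ", i + 1L, " in ", path)
    toks[i] <- parts[1]
    mat[, i] <- as.numeric(parts[-1])
  }
  list(vectors = mat, tokens = toks)
}

#' Initialize the embedding tables
#'
#' Words present in the optional pretrained file get its vectors; all other
#' word columns and all position columns are drawn uniformly from
#' \[-init_range, init_range\] under the given seed.
#'
#' @param vocab named index vector from [build_vocab].
#' @param d_w word-embedding dimension (default 300).
#' @param d_p position-embedding dimension (default 10); 0 disables position
#'   embeddings (words-only ablation).
#' @param n instance length; position matrices get 2n-1 columns.
#' @param pretrained optional path to word2vec-text vectors of dimension d_w.
#' @param seed RNG seed for the random columns.
#' @param init_range half-width of the uniform initialization interval.
#' @return list of class `ddi_embeddings`: C, D1, D2, vocab, d_w, d_p, n.
#' @export
init_tables <- function(vocab, d_w = 300L, d_p = 10L, n = 150L,
                        pretrained = NULL, seed = 1L, init_range = 0.05) {
  stopifnot(d_w > 0, d_p >= 0, n > 0)
  set.seed(seed)
  C <- matrix(stats::runif(d_w * length(vocab), -init_range, init_range),
              nrow = d_w)
  colnames(C) <- names(vocab)
  if (!is.null(pretrained)) {
    w2v <- read_word2vec_text(pretrained)
    if (nrow(w2v$vectors) != d_w)
      stop("pretrained vectors have dimension ", nrow(w2v$vectors),
           " but d_w = ", d_w)
    hit <- intersect(w2v$tokens, names(vocab))
    C[, vocab[hit]] <- w2v$vectors[, match(hit, w2v$tokens)]
  }
  ncolp <- 2L * n - 1L
  D1 <- matrix(stats::runif(d_p * ncolp, -init_range, init_range), nrow = d_p)
  D2 <- matrix(stats::runif(d_p * ncolp, -init_range, init_range), nrow = d_p)
  structure(list(C = C, D1 = D1, D2 = D2, vocab = vocab,
                 d_w = as.integer(d_w), d_p = as.integer(d_p),
                 n = as.integer(n)),
            class = "ddi_embeddings")
}

#' Map a signed distance to a position-embedding column index
#'
#' Bijection from d in \[-n+1, n-1\] to 1-based column d + n.
#'
#' @param d integer distance(s).
#' @param n instance length.
#' @return 1-based column index (vectorized).
#' @export
distance_to_index <- function(d, n) {
  if (any(d < -n + 1L | d > n - 1L))
    stop("distance out of range [-", n - 1L, ", ", n - 1L, "]")
  d + n
}

#' Encode an instance as its embedding matrix
#'
#' Pure lookup: column i stacks the word vector of token i (unknown entry
#' for out-of-vocabulary tokens) on the position vectors of d1[i] and d2[i].
#'
#' @param instance a `ddi_instance`.
#' @param tables a `ddi_embeddings`.
#' @return list: `x` ((d_w + 2 d_p) x n matrix), `word_idx`, `pos1_idx`,
#'   `pos2_idx` (the looked-up column indices, needed for sparse gradient
#'   scatter during training).
#' @export
encode_instance <- function(instance, tables) {
  n <- instance$n
  stopifnot(n == tables$n)
  wi <- tables$vocab[instance$tokens]
  wi[is.na(wi)] <- tables$vocab[[UNK_TOKEN]]
  wi <- unname(wi)
  if (tables$d_p > 0L) {
    i1 <- distance_to_index(instance$d1, n)
    i2 <- distance_to_index(instance$d2, n)
    x <- rbind(tables$C[, wi, drop = FALSE],
               tables$D1[, i1, drop = FALSE],
               tables$D2[, i2, drop = FALSE])
  } else {
    i1 <- i2 <- integer(n)
    x <- tables$C[, wi, drop = FALSE]
  }
  dimnames(x) <- NULL
  list(x = x, word_idx = wi, pos1_idx = i1, pos2_idx = i2)
}
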