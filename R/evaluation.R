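# Challenge-style scoring: a 5x5 gold-vs-predicted confusion matrix over
# {mechanism, effect, advice, int, negative} and micro-averaged
# precision/recall/F pooled over the four positive types. `negative` is
# never a scored class: it only contributes false negatives (gold-positive
# predicted negative) and false positives (gold-negative predicted
# positive).

POSITIVE_CLASSES <- DDI_CLASSES[1:4]

#' Round half away from zero to a fixed number of decimals
#'
#' Matches the rounding convention of the published tables (R's `round`
#' rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a 5x5 confusion matrix from aligned gold and predicted labels
#'
#' @param gold character vector of gold labels.
#' @param predicted character vector of predicted labels, same length.
#' @param source optional character vector (`model`/`filter`) recording the
#'   provenance of each prediction; when present, predicted-negative counts
#'   are additionally split by provenance in the `negative_split` attribute.
#' @return object of class `ddi_confusion`: 5x5 integer matrix, rows gold,
#'   columns predicted, both in [DDI_CLASSES] order.
#' @export
build_confusion <- function(gold, predicted, source = NULL) {
  if (length(gold) != length(predicted))
    stop("gold and predicted streams have different lengths (",
         length(gold), " vs ", length(predicted), ")")
  bad <- setdiff(unique(c(gold, predicted)), DDI_CLASSES)
  if (length(bad)) stop("invalid labels: ", paste(bad, collapse = ", "))
  g <- factor(gold, levels = DDI_CLASSES)
  p <- factor(predicted, levels = DDI_CLASSES)
  cm <- unclass(table(g, p))
  dimnames(cm) <- list(gold = DDI_CLASSES, predicted = DDI_CLASSES)
  out <- structure(cm, class = c("ddi_confusion", class(cm)))
  if (!is.null(source)) {
    stopifnot(length(source) == length(gold))
    neg <- predicted == "negative"
    split <- vapply(DDI_CLASSES, function(cl) {
      c(model = sum(neg & gold == cl & source == "model"),
        filter = sum(neg & gold == cl & source == "filter"))
    }, numeric(2))
    attr(out, "negative_split") <- split
  }
  out
}

#' @export
print.ddi_confusion <- function(x, ...) {
  cat("<ddi_confusion> gold (rows) x predicted (columns)\n")
  print(unclass(x))
  sp <- attr(x, "negative_split")
  if (!is.null(sp)) {
    cat("predicted-negative split (model + filter):\n")
    print(sp)
  }
  invisible(x)
}

#' Micro-averaged precision, recall and F-score
#'
#' Pooled over the given positive classes: TP is the summed diagonal,
#' predicted is the summed columns over all gold rows, gold is the summed
#' rows. P = TP/predicted, R = TP/gold, F = 2PR/(P+R) (0 when P+R = 0).
#' Reported as percentages.
#'
#' @param cm a `ddi_confusion` (or plain 5x5 matrix in class order).
#' @param classes positive classes to score (default all four).
#' @return list of class `ddi_metrics`: precision, recall, f_score (in
#'   percent), plus tp, n_predicted, n_gold.
#' @export
micro_metrics <- function(cm, classes = POSITIVE_CLASSES) {
  stopifnot(length(classes) > 0, all(classes %in% POSITIVE_CLASSES))
  cm <- unclass(cm)
  tp <- sum(diag(cm)[match(classes, DDI_CLASSES)])
  n_pred <- sum(cm[, match(classes, DDI_CLASSES), drop = FALSE])
  n_gold <- sum(cm[match(classes, DDI_CLASSES), , drop = FALSE])
  P <- if (n_pred > 0) tp / n_pred else { message("no predicted positives; precision set to 0"); 0 }
  R <- if (n_gold > 0) tp / n_gold else { message("no gold positives; recall set to 0"); 0 }
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(precision = 100 * P, recall = 100 * R, f_score = 100 * F,
                 tp = tp, n_predicted = n_pred, n_gold = n_gold),
            class = "ddi_metrics")
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf("P = %.2f%%  R = %.2f%%  F = %.2f%%  (TP %d / predicted %d / gold %d)\n",
              round_half_up(x$precision), round_half_up(x$recall),
              round_half_up(x$f_score), x$tp, x$n_predicted, x$n_gold))
  invisible(x)
}

#' Per-type and per-subset evaluation report
#'
#' Micro metrics for each positive type, each corpus subset, and overall.
#' Predictions are matched to gold pairs by (sentence_id, e1, e2) with the
#' pair treated as unordered.
#'
#' @param corpus gold [ddi_corpus].
#' @param predictions data.frame from [predict_ddi] (sentence_id, e1, e2,
#'   predicted, optional source). Candidates without a prediction row count
#'   as predicted negative.
#' @return data.frame with columns row ("mechanism", ..., subset names,
#'   "overall"), precision, recall, f_score (percent, 2 decimals,
#'   half-up) and the pooled counts.
#' @export
per_type_and_subset_report <- function(corpus, predictions) {
  al <- aligned_labels(corpus, predictions)
  rows <- list()
  for (cl in POSITIVE_CLASSES) {
    m <- micro_metrics(build_confusion(al$gold, al$predicted), classes = cl)
    rows[[cl]] <- report_row(cl, m)
  }
  for (sub in unique(al$subset)) {
    keep <- al$subset == sub
    m <- micro_metrics(build_confusion(al$gold[keep], al$predicted[keep]))
    rows[[sub]] <- report_row(sub, m)
  }
  m <- micro_metrics(build_confusion(al$gold, al$predicted))
  rows[["overall"]] <- report_row("overall", m)
  do.call(rbind, rows)
}

report_row <- function(name, m) {
  data.frame(row = name,
             precision = round_half_up(m$precision),
             recall = round_half_up(m$recall),
             f_score = round_half_up(m$f_score),
             tp = m$tp, n_predicted = m$n_predicted, n_gold = m$n_gold,
             stringsAsFactors = FALSE)
}

# align every candidate pair of the corpus with its prediction; scoring
# unit is the candidate pair list, unmatched candidates count as predicted
# negative
aligned_labels <- function(corpus, predictions) {
  key <- function(sid, a, b) {
    swap <- a > b
    paste(sid, ifelse(swap, b, a), ifelse(swap, a, b), sep = "\r")
  }
  pk <- key(predictions$sentence_id, predictions$e1, predictions$e2)
  gold <- character(); pred <- character(); subset <- character()
  src <- character()
  has_src <- !is.null(predictions$source)
  for (s in corpus_sentences(corpus)) {
    prs <- enumerate_pairs(s)
    for (i in seq_len(nrow(prs))) {
      gp <- s$pairs
      hit <- which((gp$e1 == prs$e1[i] & gp$e2 == prs$e2[i]) |
                   (gp$e1 == prs$e2[i] & gp$e2 == prs$e1[i]))
      gold <- c(gold, if (length(hit)) gp$label[hit[1]] else "negative")
      j <- match(key(s$id, prs$e1[i], prs$e2[i]), pk)
      pred <- c(pred, if (is.na(j)) "negative" else predictions$predicted[j])
      src <- c(src, if (is.na(j)) "filter"
               else if (has_src) predictions$source[j] else "model")
      subset <- c(subset, s$subset)
    }
  }
  list(gold = gold, predicted = pred, subset = subset, source = src)
}

#' Write predictions as the TSV interchange format
#'
#' Columns: sentence_id, e1, e2, predicted_label, source.
#'
#' @param predictions data.frame from [predict_ddi].
#' @param path output path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the prediction TSV interchange format
#'
#' @param path file written by [write_predictions_tsv].
#' @return data.frame.
#' @export
read_predictions_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
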