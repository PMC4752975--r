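# Candidate generation: enumerate drug-mention pairs, blind the focus pair
# to drug1/drug2 (all other mentions to drug0), tokenize, lowercase, pad to a
# fixed length and attach signed token distances to each focus drug.

#' Enumerate candidate drug pairs in a sentence
#'
#' All unordered pairs of annotated mentions, ordered by first-mention
#' occurrence in the text; the earlier mention becomes drug1. A sentence
#' with m drug mentions yields choose(m, 2) candidates.
#'
#' @param sentence a [ddi_sentence].
#' @return data.frame with columns `e1`, `e2` (entity ids, text order).
#' @export
enumerate_pairs <- function(sentence) {
  ent <- sentence$entities
  if (nrow(ent) < 2L)
    return(data.frame(e1 = character(), e2 = character(),
                      stringsAsFactors = FALSE))
  ord <- order(ent$char_start, ent$char_end)
  ids <- ent$id[ord]
  idx <- utils::combn(seq_along(ids), 2L)
  data.frame(e1 = ids[idx[1, ]], e2 = ids[idx[2, ]], stringsAsFactors = FALSE)
}

#' Blind drug mentions for one candidate pair
#'
#' Replaces the span of the earlier focus mention with `drug1`, the later
#' with `drug2`, and every other annotated mention with `drug0`. Multi-word
#' mention spans collapse to a single placeholder token so token positions
#' stay well defined. Non-entity text is untouched.
#'
#' @param sentence a [ddi_sentence].
#' @param pair character vector of two entity ids (or a 1-row data.frame with
#'   `e1`, `e2`).
#' @return the blinded sentence string.
#' @export
blind_drugs <- function(sentence, pair) {
  if (is.data.frame(pair)) pair <- c(pair$e1[1], pair$e2[1])
  ent <- sentence$entities
  if (!all(pair %in% ent$id))
    stop("pair entities not found in sentence ", sentence$id)
  ord <- order(ent$char_start, ent$char_end)
  ent <- ent[ord, , drop = FALSE]
  # overlap check: spans must be disjoint to replace consistently
  if (nrow(ent) > 1L) {
    for (i in 2:nrow(ent)) {
      if (ent$char_start[i] <= ent$char_end[i - 1L]) {
        if (ent$char_start[i] == ent$char_start[i - 1L] &&
            ent$char_end[i] == ent$char_end[i - 1L])
          stop("nested mentions at identical position in sentence ",
               sentence$id, " (", ent$id[i - 1L], ", ", ent$id[i], ")")
        stop("overlapping mention spans in sentence ", sentence$id,
             " (", ent$id[i - 1L], ", ", ent$id[i], ")")
      }
    }
  }
  focus_order <- ent$id[ent$id %in% pair]  # text order of the two focus drugs
  placeholder <- function(eid) {
    if (eid == focus_order[1]) "drug1"
    else if (eid == focus_order[2]) "drug2"
    else "drug0"
  }
  # replace right-to-left so earlier offsets stay valid
  text <- sentence$text
  for (i in rev(seq_len(nrow(ent)))) {
    text <- paste0(substr(text, 1L, ent$char_start[i]),
                   placeholder(ent$id[i]),
                   substring(text, ent$char_end[i] + 2L))
  }
  text
}

#' Word-punctuation tokenizer
#'
#' Splits into maximal alphanumeric runs (apostrophes and hyphens kept
#' inside words) and single punctuation characters, after lowercasing.
#' Placeholder tokens drug1/drug2/drug0 survive intact.
#'
#' @param text a string.
#' @return character vector of lowercase tokens.
#' @export
tokenize_text <- function(text) {
  text <- tolower(text)
  m <- gregexpr("[a-z0-9][a-z0-9'-]*|[^a-z0-9[:space:]]", text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  toks[nzchar(toks)]
}

#' Tokenize a blinded sentence and pad to fixed length
#'
#' Lowercases, word-tokenizes, records the token positions of drug1 and
#' drug2, and right-pads with `"#"` to length `n`. Sentences longer than `n`
#' are right-truncated, but never past the later focus drug; if the focus
#' drugs still do not fit the window is centered on the drug span.
#'
#' @param blinded_text output of [blind_drugs]; must contain drug1 and drug2
#'   exactly once each.
#' @param n fixed instance length (token count), default 150.
#' @return list with `tokens` (length n), `p1`, `p2` (0-based positions of
#'   drug1/drug2).
#' @export
tokenize_and_pad <- function(blinded_text, n = 150L) {
  toks <- tokenize_text(blinded_text)
  if (sum(toks == "drug1") != 1L || sum(toks == "drug2") != 1L)
    stop("blinded text must contain drug1 and drug2 exactly once each")
  p1 <- which(toks == "drug1") - 1L
  p2 <- which(toks == "drug2") - 1L
  if (length(toks) > n) {
    span <- p2 - p1 + 1L
    if (span > n)
      stop("focus drugs are ", span, " tokens apart; cannot fit n = ", n)
    if (p2 <= n - 1L) {
      start <- 0L
    } else {
      start <- p1 - (n - span) %/% 2L
      start <- max(0L, min(start, length(toks) - n))
    }
    toks <- toks[(start + 1L):(start + n)]
    p1 <- p1 - start; p2 <- p2 - start
    if (p1 < 0L || p2 > n - 1L)
      stop("focus drugs lost by truncation")
  }
  tokens <- c(toks, rep("#", n - length(toks)))
  list(tokens = tokens, p1 = p1, p2 = p2)
}

#' Compute signed token distances to the focus drugs
#'
#' For token position i (0-based), d1[i] = i - p1 and d2[i] = i - p2; both
#' lie in \[-n+1, n-1\]. Padding tokens continue the same formula.
#'
#' @param p1,p2 0-based positions of drug1 and drug2.
#' @param n instance length.
#' @return list with integer vectors `d1`, `d2` of length n.
#' @export
compute_distances <- function(p1, p2, n) {
  i <- 0:(n - 1L)
  list(d1 = i - p1, d2 = i - p2)
}

#' Build one classification instance for a candidate pair
#'
#' Runs blinding, tokenization, padding and distance computation for one
#' candidate pair and attaches the gold label if present.
#'
#' @param sentence a [ddi_sentence].
#' @param pair character vector `(e1_id, e2_id)` or 1-row data.frame.
#' @param n fixed instance length.
#' @return an object of class `ddi_instance`: sentence_id, e1, e2, tokens,
#'   n, p1, p2, d1, d2, label (`NA` if no gold pair), subset.
#' @export
make_instance <- function(sentence, pair, n = 150L) {
  if (is.data.frame(pair)) pair <- c(pair$e1[1], pair$e2[1])
  blinded <- blind_drugs(sentence, pair)
  tp <- tokenize_and_pad(blinded, n)
  d <- compute_distances(tp$p1, tp$p2, n)
  pr <- sentence$pairs
  hit <- which((pr$e1 == pair[1] & pr$e2 == pair[2]) |
               (pr$e1 == pair[2] & pr$e2 == pair[1]))
  label <- if (length(hit)) pr$label[hit[1]] else NA_character_
  structure(list(sentence_id = sentence$id, e1 = pair[1], e2 = pair[2],
                 tokens = tp$tokens, n = n, p1 = tp$p1, p2 = tp$p2,
                 d1 = d$d1, d2 = d$d2, label = label,
                 blinded_text = blinded, subset = sentence$subset),
            class = "ddi_instance")
}

#' Build all candidate instances for a corpus
#'
#' Enumerates every candidate pair of every sentence and builds an instance
#' for each. Unannotated candidates (no gold pair) get label `negative` when
#' `assume_negative` is TRUE (training convention: annotated pairs are the
#' positives, everything else negative) and `NA` otherwise.
#'
#' @param corpus a [ddi_corpus].
#' @param n fixed instance length.
#' @param assume_negative treat unannotated candidates as gold negatives.
#' @return list of `ddi_instance` objects.
#' @export
corpus_instances <- function(corpus, n = 150L, assume_negative = TRUE) {
  out <- list()
  for (s in corpus_sentences(corpus)) {
    prs <- enumerate_pairs(s)
    for (i in seq_len(nrow(prs))) {
      inst <- make_instance(s, c(prs$e1[i], prs$e2[i]), n)
      if (is.na(inst$label) && assume_negative) inst$label <- "negative"
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}

#' Write instances as JSON-lines for inspection
#'
#' @param instances list of `ddi_instance` objects.
#' @param path output file path.
#' @export
write_instances_jsonl <- function(instances, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (inst in instances) {
    rec <- unclass(inst)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
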