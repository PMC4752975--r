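# Rule-based negative-instance filtering. Four criteria, tested in order
# with first-match-wins, all on surface text only (no parser):
#   1 same_name      the two mention surface texts match case-insensitively
#   2 abbreviation   "drug1 (drug2)" or "drug2 (drug1)" in the blinded text
#   3 coordination   drug1 and drug2 sit in one comma/and/or list of >= 3
#                    drug placeholders
#   4 special_case   hypernym constructions: "drug1 such as ... drug2" and
#                    the including / e.g. variants, either direction
# A filtered candidate is labeled negative up front and never reaches the
# classifier.

#' Default filtering rule set
#'
#' The rule inventory is versioned so pattern dialects are swappable: the
#' hypernym cues, the list separators accepted inside a coordination, and
#' whether initial-letter acronyms count as abbreviations.
#'
#' @param acronym_match also treat an exact initial-letter acronym of the
#'   other mention's words as an abbreviation (criterion 2). Default off.
#' @return list of class `ddi_filter_rules`.
#' @export
default_filter_rules <- function(acronym_match = FALSE) {
  structure(list(
    version = "1",
    hypernym_cues = list(c("such", "as"), c("including"), c("e", ".", "g", ".")),
    list_separators = c(",", "and", "or", "/", "&"),
    acronym_match = acronym_match,
    positive_filter_alarm = 0.01
  ), class = "ddi_filter_rules")
}

placeholders <- c("drug0", "drug1", "drug2")

# maximal runs of drug placeholders separated only by list separators;
# returns a list of integer token-index vectors (placeholder positions only)
coordination_runs <- function(tokens, seps) {
  runs <- list()
  cur <- integer()
  i <- 1L
  nt <- length(tokens)
  while (i <= nt) {
    if (tokens[i] %in% placeholders) {
      cur <- c(cur, i)
      i <- i + 1L
    } else if (length(cur) && tokens[i] %in% seps) {
      # separators only continue a run if another placeholder follows
      j <- i
      while (j <= nt && tokens[j] %in% seps) j <- j + 1L
      if (j <= nt && tokens[j] %in% placeholders) i <- j
      else { runs <- c(runs, list(cur)); cur <- integer(); i <- j }
    } else {
      if (length(cur)) { runs <- c(runs, list(cur)); cur <- integer() }
      i <- i + 1L
    }
  }
  if (length(cur)) runs <- c(runs, list(cur))
  runs
}

acronym_of <- function(short, long) {
  words <- strsplit(trimws(long), "[^[:alnum:]]+")[[1]]
  initials <- paste(substr(words, 1, 1), collapse = "")
  nchar(short) > 1 && identical(tolower(short), tolower(initials))
}

match_cue_at <- function(tokens, pos, cue) {
  pos + length(cue) - 1L <= length(tokens) &&
    identical(tokens[pos:(pos + length(cue) - 1L)], cue)
}

# does a hypernym construction "<head> <cue> <list containing member>" occur,
# with only placeholders/separators between cue and member?
hypernym_match <- function(tokens, head_tok, member_tok, rules) {
  head_pos <- which(tokens == head_tok)
  for (hp in head_pos) {
    cp <- hp + 1L
    while (cp <= length(tokens) && tokens[cp] == ",") cp <- cp + 1L
    for (cue in rules$hypernym_cues) {
      if (!match_cue_at(tokens, cp, cue)) next
      i <- cp + length(cue)
      while (i <= length(tokens)) {
        if (tokens[i] == member_tok) return(TRUE)
        if (tokens[i] %in% placeholders ||
            tokens[i] %in% rules$list_separators) i <- i + 1L
        else break
      }
    }
  }
  FALSE
}

#' Apply the negative-instance filtering criteria to one candidate
#'
#' @param sentence a [ddi_sentence].
#' @param pair character vector `(e1_id, e2_id)` or 1-row data.frame.
#' @param blinded_text the blinded sentence for this pair, from
#'   [blind_drugs]; computed if missing.
#' @param rules a rule set from [default_filter_rules].
#' @return list of class `ddi_filter_decision`: `sentence_id`, `e1`, `e2`,
#'   `filtered` (logical), `criterion` (one of same_name, abbreviation,
#'   coordination, special_case, none).
#' @export
apply_filters <- function(sentence, pair, blinded_text = NULL,
                          rules = default_filter_rules()) {
  if (is.data.frame(pair)) pair <- c(pair$e1[1], pair$e2[1])
  if (is.null(blinded_text)) blinded_text <- blind_drugs(sentence, pair)
  ent <- sentence$entities
  s1 <- ent$text[match(pair[1], ent$id)]
  s2 <- ent$text[match(pair[2], ent$id)]
  tokens <- tokenize_text(blinded_text)

  criterion <- "none"
  if (identical(tolower(trimws(s1)), tolower(trimws(s2)))) {
    criterion <- "same_name"
  } else if (grepl("drug1\\s*\\(\\s*drug2\\s*\\)", blinded_text) ||
             grepl("drug2\\s*\\(\\s*drug1\\s*\\)", blinded_text) ||
             (isTRUE(rules$acronym_match) &&
              (acronym_of(s1, s2) || acronym_of(s2, s1)))) {
    criterion <- "abbreviation"
  } else {
    runs <- coordination_runs(tokens, rules$list_separators)
    coord <- any(vapply(runs, function(r) {
      length(r) >= 3L && "drug1" %in% tokens[r] && "drug2" %in% tokens[r]
    }, logical(1)))
    if (coord) {
      criterion <- "coordination"
    } else if (hypernym_match(tokens, "drug1", "drug2", rules) ||
               hypernym_match(tokens, "drug2", "drug1", rules)) {
      criterion <- "special_case"
    }
  }
  structure(list(sentence_id = sentence$id, e1 = pair[1], e2 = pair[2],
                 filtered = criterion != "none", criterion = criterion),
            class = "ddi_filter_decision")
}

#' Filter decisions for every candidate pair of a corpus
#'
#' @param corpus a [ddi_corpus].
#' @param rules a rule set from [default_filter_rules].
#' @return data.frame: sentence_id, e1, e2, filtered, criterion, label
#'   (gold label, `negative` for unannotated candidates).
#' @export
corpus_filter_decisions <- function(corpus, rules = default_filter_rules()) {
  rows <- list()
  for (s in corpus_sentences(corpus)) {
    prs <- enumerate_pairs(s)
    for (i in seq_len(nrow(prs))) {
      pair <- c(prs$e1[i], prs$e2[i])
      fd <- apply_filters(s, pair, rules = rules)
      gp <- s$pairs
      hit <- which((gp$e1 == pair[1] & gp$e2 == pair[2]) |
                   (gp$e1 == pair[2] & gp$e2 == pair[1]))
      label <- if (length(hit)) gp$label[hit[1]] else "negative"
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = s$id, e1 = pair[1], e2 = pair[2],
        filtered = fd$filtered, criterion = fd$criterion, label = label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(
    sentence_id = character(), e1 = character(), e2 = character(),
    filtered = logical(), criterion = character(), label = character(),
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Filtering report against gold labels
#'
#' Counts how many gold-negative and gold-positive candidates the filter
#' removes. A warning fires when the wrongly-filtered positive fraction
#' exceeds the rule set's alarm threshold (default 1%) — on well-behaved
#' corpora it should stay near zero.
#'
#' @param corpus a [ddi_corpus].
#' @param rules a rule set from [default_filter_rules].
#' @return list: negatives_filtered, negatives_total, positives_filtered,
#'   positives_total.
#' @export
filter_report <- function(corpus, rules = default_filter_rules()) {
  dec <- corpus_filter_decisions(corpus, rules)
  neg <- dec$label == "negative"
  out <- list(negatives_filtered = sum(dec$filtered & neg),
              negatives_total = sum(neg),
              positives_filtered = sum(dec$filtered & !neg),
              positives_total = sum(!neg))
  if (out$positives_total > 0 &&
      out$positives_filtered / out$positives_total > rules$positive_filter_alarm)
    warning(sprintf(
      "%.1f%% of gold-positive candidates were filtered out (alarm threshold %.1f%%)",
      100 * out$positives_filtered / out$positives_total,
      100 * rules$positive_filter_alarm), call. = FALSE)
  out
}
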