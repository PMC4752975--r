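# Synthetic corpus generator. Emits the same XML dialect the reader accepts:
# template sentences with annotated drug-name spans (pronounceable nonsense
# names, so no real drug list is bundled), gold typed pairs driven by
# class-specific lexical triggers, and trap constructions that exercise each
# negative-filtering criterion. A ledger records every gold label and every
# planted trap, so downstream modules can be tested against exact
# bookkeeping rather than re-derived answers.

#' Synthetic corpus configuration
#'
#' @param n_sentences number of sentences to generate.
#' @param class_proportions named non-negative vector over
#'   mechanism/effect/advice/int/negative summing to 1; governs the primary
#'   class of each non-trap sentence. The default keeps the published
#'   corpus flavor: effect commonest among positives, int rare, a quarter
#'   of sentences carrying no interaction.
#' @param drugs_per_sentence integer range (min, max) of drug mentions per
#'   non-trap sentence.
#' @param trigger_lexicons named list class -> character vector of trigger
#'   phrases; defaults provided.
#' @param filter_trap_rate fraction of sentences, per filtering criterion,
#'   built to fire that criterion (4 criteria, so total trap share is 4x).
#' @param noise_rate probability that a sentence's trigger is swapped for a
#'   random trigger of another class (label noise; labels keep the intended
#'   class).
#' @param seed RNG seed; a fixed seed reproduces the corpus byte for byte.
#' @return list of class `ddi_synth_config`.
#' @export
synth_config <- function(n_sentences = 500L,
                         class_proportions = c(mechanism = 0.246,
                                               effect = 0.315,
                                               advice = 0.154,
                                               int = 0.035,
                                               negative = 0.25),
                         drugs_per_sentence = c(2L, 6L),
                         trigger_lexicons = default_trigger_lexicons(),
                         filter_trap_rate = 0.05,
                         noise_rate = 0,
                         seed = 1L) {
  stopifnot(n_sentences >= 0, length(drugs_per_sentence) == 2,
            drugs_per_sentence[1] >= 2, filter_trap_rate >= 0,
            filter_trap_rate <= 0.25, noise_rate >= 0, noise_rate <= 1)
  if (!all(DDI_CLASSES %in% names(class_proportions)))
    stop("class_proportions must name all five classes")
  class_proportions <- class_proportions[DDI_CLASSES]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be non-negative and sum to 1")
  n_traps <- 4L * round(filter_trap_rate * n_sentences)
  if (n_sentences > 0 && n_traps >= n_sentences)
    stop("filter_trap_rate infeasible for n_sentences = ", n_sentences)
  structure(list(n_sentences = as.integer(n_sentences),
                 class_proportions = class_proportions,
                 drugs_per_sentence = as.integer(drugs_per_sentence),
                 trigger_lexicons = trigger_lexicons,
                 filter_trap_rate = filter_trap_rate,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "ddi_synth_config")
}

#' Default class-trigger lexicons
#'
#' Pharmacokinetic phrases for mechanism, pharmacodynamic-effect phrases for
#' effect, recommendation phrases for advice, bare interaction statements
#' for int; negatives use neutral co-occurrence phrasing with no trigger.
#'
#' @return named list of character vectors.
#' @export
default_trigger_lexicons <- function() {
  list(
    mechanism = c("increases the plasma concentration of",
                  "reduces the metabolism of",
                  "decreases the absorption of",
                  "inhibits the renal clearance of"),
    effect = c("enhances the hypotensive effect of",
               "potentiates the sedative effect of",
               "augments the anticoagulant effect of",
               "diminishes the diuretic effect of"),
    advice = c("should not be coadministered with",
               "should be used cautiously with",
               "must not be combined with"),
    int = c("interacts with",
            "may interact with"),
    negative = c("was administered before",
                 "was measured together with",
                 "did not alter the response to")
  )
}

# pronounceable nonsense drug names; ~15% are two-word names so blinding of
# multi-word spans is exercised
make_name_pool <- function(n = 300L) {
  syl <- c("ba", "dor", "fe", "gli", "kam", "lu", "mi", "nor", "pra", "ru",
           "sa", "tev", "vo", "xa", "zol", "qui", "ce", "phi")
  suf <- c("ol", "ine", "ide", "pril", "mab", "nib", "tan", "zide")
  pool <- character(0)
  while (length(pool) < n) {
    nm <- paste0(paste(sample(syl, sample(2:3, 1), replace = TRUE),
                       collapse = ""), sample(suf, 1))
    if (stats::runif(1) < 0.15)
      nm <- paste(sample(c("sodium", "calcium", "depot", "micronized"), 1), nm)
    pool <- union(pool, nm)
  }
  pool[seq_len(n)]
}

# group-style (hypernym) nonsense names for "such as" traps
make_group_name <- function(pool) paste0(sub(" .*", "", sample(pool, 1)), "ates")

# assemble a sentence from parts: each part is either list(text=) plain text
# or list(drug=name). Single spaces join parts; offsets are 0-based
# inclusive over the drug name span.
assemble_sentence <- function(id, parts, labels, subset = "synthetic") {
  words <- character(0)
  ents <- empty_entities()
  pos <- 0L
  k <- 0L
  for (p in parts) {
    txt <- if (!is.null(p$drug)) p$drug else p$text
    if (pos > 0L) pos <- pos + 1L  # joining space
    start <- pos
    pos <- pos + nchar(txt)
    if (!is.null(p$drug)) {
      k <- k + 1L
      ents <- rbind(ents, data.frame(
        id = paste0(id, ".e", k - 1L), char_start = start,
        char_end = pos - 1L, text = p$drug, type = "drug",
        stringsAsFactors = FALSE))
    }
    words <- c(words, txt)
  }
  text <- paste(words, collapse = " ")
  prs <- empty_pairs()
  for (lb in labels) {
    prs <- rbind(prs, data.frame(e1 = ents$id[lb$i], e2 = ents$id[lb$j],
                                 label = lb$label, stringsAsFactors = FALSE))
  }
  ddi_sentence(id, text, ents, prs, subset = subset)
}

w <- function(text) list(text = text)
d <- function(name) list(drug = name)

intro_phrases <- c("in this study", "clinical reports indicate that",
                   "according to the product label",
                   "pharmacokinetic data show that", "")
tail_phrases <- c("in healthy volunteers", "during long-term therapy",
                  "in a randomized crossover trial",
                  "over a two-week observation period", "")

extra_clauses <- function(names) {
  # each extra drug gets its own clause; no commas or and/or between
  # consecutive drugs, so no coordination run of length >= 3 can form
  templates <- c("in patients also receiving %s",
                 "while %s therapy continued",
                 "irrespective of concurrent %s exposure")
  out <- list()
  for (nm in names) {
    tpl <- sample(templates, 1)
    halves <- strsplit(tpl, "%s", fixed = TRUE)[[1]]
    out <- c(out, list(w(trimws(halves[1]))), list(d(nm)))
    if (length(halves) > 1 && nzchar(trimws(halves[2])))
      out <- c(out, list(w(trimws(halves[2]))))
  }
  out
}

build_standard_sentence <- function(id, class, cfg, pool) {
  m <- sample(cfg$drugs_per_sentence[1]:cfg$drugs_per_sentence[2], 1)
  nms <- sample(pool, m)
  trig_class <- class
  if (cfg$noise_rate > 0 && stats::runif(1) < cfg$noise_rate)
    trig_class <- sample(DDI_CLASSES, 1)
  trig <- sample(cfg$trigger_lexicons[[trig_class]], 1)
  parts <- list()
  intro <- sample(intro_phrases, 1)
  if (nzchar(intro)) parts <- c(parts, list(w(intro)))
  parts <- c(parts, list(d(nms[1]), w(trig), d(nms[2])))
  if (m > 2) parts <- c(parts, extra_clauses(nms[3:m]))
  tl <- sample(tail_phrases, 1)
  if (nzchar(tl)) parts <- c(parts, list(w(tl)))
  parts <- c(parts, list(w(".")))
  # gold pairs: the focus pair carries the class, every other candidate is
  # negative
  labels <- list(list(i = 1L, j = 2L, label = class))
  if (m > 2) {
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a < b && !(a == 1L && b == 2L))
        labels <- c(labels, list(list(i = a, j = b, label = "negative")))
    }
  }
  sent <- assemble_sentence(id, parts, labels)
  ledger <- data.frame(sentence_id = id,
                       e1 = vapply(labels, function(l) paste0(id, ".e", l$i - 1L), character(1)),
                       e2 = vapply(labels, function(l) paste0(id, ".e", l$j - 1L), character(1)),
                       label = vapply(labels, function(l) l$label, character(1)),
                       trap = "none", stringsAsFactors = FALSE)
  list(sentence = sent, ledger = ledger)
}

build_trap_sentence <- function(id, criterion, pool) {
  led <- function(pairs) do.call(rbind, lapply(pairs, function(p)
    data.frame(sentence_id = id, e1 = paste0(id, ".e", p[[1]] - 1L),
               e2 = paste0(id, ".e", p[[2]] - 1L), label = "negative",
               trap = p[[3]], stringsAsFactors = FALSE)))
  if (criterion == "same_name") {
    nm <- sample(pool, 1)
    parts <- list(d(nm), w("was compared with"), d(nm),
                  w("in a dose-ranging study ."))
    labels <- list(list(i = 1L, j = 2L, label = "negative"))
    ledger <- led(list(list(1L, 2L, "same_name")))
  } else if (criterion == "abbreviation") {
    nm <- sample(pool, 1)
    abbr <- toupper(paste(substr(strsplit(nm, "")[[1]][c(1, 3, 5)], 1, 1),
                          collapse = ""))
    parts <- list(d(nm), w("("), d(abbr), w(")"),
                  w("required no dose adjustment ."))
    labels <- list(list(i = 1L, j = 2L, label = "negative"))
    ledger <- led(list(list(1L, 2L, "abbreviation")))
  } else if (criterion == "coordination") {
    nms <- sample(pool, 3)
    parts <- list(w("the screening panel contained"),
                  d(nms[1]), w(","), d(nms[2]), w(", and"), d(nms[3]),
                  w("at standard doses ."))
    labels <- list(list(i = 1L, j = 2L, label = "negative"),
                   list(i = 1L, j = 3L, label = "negative"),
                   list(i = 2L, j = 3L, label = "negative"))
    ledger <- led(list(list(1L, 2L, "coordination"),
                       list(1L, 3L, "coordination"),
                       list(2L, 3L, "coordination")))
  } else { # special_case
    grp <- make_group_name(pool)
    nms <- sample(pool, 2)
    parts <- list(d(grp), w("such as"), d(nms[1]), w("or"), d(nms[2]),
                  w("may require closer monitoring ."))
    labels <- list(list(i = 1L, j = 2L, label = "negative"),
                   list(i = 1L, j = 3L, label = "negative"),
                   list(i = 2L, j = 3L, label = "negative"))
    ledger <- led(list(list(1L, 2L, "special_case"),
                       list(1L, 3L, "special_case"),
                       list(2L, 3L, "none")))
  }
  list(sentence = assemble_sentence(id, parts, labels), ledger = ledger)
}

#' Generate a synthetic corpus with a bookkeeping ledger
#'
#' Non-trap sentences draw a primary class from `class_proportions` and
#' realize it with a class-specific trigger phrase between the first two
#' drug mentions; additional mentions sit in separate clauses and pair as
#' gold negatives. Trap sentences are constructed to fire exactly one
#' filtering criterion each (same-name, abbreviation, >= 3-element
#' coordination, "such as" hypernym).
#'
#' @param cfg a [synth_config].
#' @return list: `corpus` (a [ddi_corpus], one document per 25 sentences),
#'   `ledger` (data.frame: sentence_id, e1, e2, label, trap).
#' @export
generate_corpus <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  pool <- make_name_pool()
  n_trap_each <- round(cfg$filter_trap_rate * cfg$n_sentences)
  criteria <- rep(c("same_name", "abbreviation", "coordination",
                    "special_case"), each = n_trap_each)
  n_std <- cfg$n_sentences - length(criteria)
  kinds <- sample(c(criteria, rep("standard", n_std)))
  sents <- vector("list", cfg$n_sentences)
  ledgers <- vector("list", cfg$n_sentences)
  for (i in seq_len(cfg$n_sentences)) {
    id <- sprintf("s%04d", i)
    if (kinds[i] == "standard") {
      cls <- sample(DDI_CLASSES, 1, prob = cfg$class_proportions)
      out <- build_standard_sentence(id, cls, cfg, pool)
    } else {
      out <- build_trap_sentence(id, kinds[i], pool)
    }
    sents[[i]] <- out$sentence
    ledgers[[i]] <- out$ledger
  }
  docs <- split(sents, (seq_along(sents) - 1L) %/% 25L)
  names(docs) <- sprintf("d%03d", seq_along(docs) - 1L)
  ledger <- if (length(ledgers)) do.call(rbind, ledgers) else
    data.frame(sentence_id = character(), e1 = character(),
               e2 = character(), label = character(), trap = character(),
               stringsAsFactors = FALSE)
  list(corpus = ddi_corpus(docs), ledger = ledger)
}

#' Generate a linearly separable corpus for learnability checks
#'
#' Every class (including negative) is realized by exactly one unique
#' single-token trigger in an otherwise shared template, so class and
#' trigger token are in bijection and a small model can reach near-perfect
#' held-out accuracy. Two drugs per sentence, no traps, no noise.
#'
#' @param n_sentences number of sentences.
#' @param seed RNG seed.
#' @return a [ddi_corpus].
#' @export
make_separable <- function(n_sentences = 500L, seed = 1L) {
  set.seed(seed)
  triggers <- c(mechanism = "metabolizes", effect = "potentiates",
                advice = "contraindicates", int = "engages",
                negative = "accompanies")
  pool <- make_name_pool(150L)
  pool <- pool[!grepl(" ", pool)]
  sents <- vector("list", n_sentences)
  for (i in seq_len(n_sentences)) {
    id <- sprintf("s%04d", i)
    cls <- DDI_CLASSES[1L + (i - 1L) %% 5L]
    nms <- sample(pool, 2)
    parts <- list(d(nms[1]), w(triggers[[cls]]), d(nms[2]),
                  w("during maintenance therapy ."))
    sents[[i]] <- assemble_sentence(id, parts,
                                    list(list(i = 1L, j = 2L, label = cls)))
  }
  docs <- split(sents, (seq_along(sents) - 1L) %/% 25L)
  names(docs) <- sprintf("d%03d", seq_along(docs) - 1L)
  ddi_corpus(docs)
}

#' Generate a corpus separable only through inter-drug distance
#'
#' Two classes share an identical bag of context-window types: sentences
#' are `w^3 drug_A w^g drug_B w^b` with a single filler token, where the
#' gap g is 3 for one class and 9 for the other and the total length is
#' constant. For any filter of width <= 3 the set of distinct windows is
#' identical across classes, so a words-only model cannot beat chance,
#' while position embeddings expose the gap. Used for the
#' position-embedding ablation check.
#'
#' @param n_sentences number of sentences (split evenly; class `effect` gets
#'   the short gap, `mechanism` the long one).
#' @param seed RNG seed.
#' @return a [ddi_corpus].
#' @export
make_distance_contrast <- function(n_sentences = 200L, seed = 1L) {
  set.seed(seed)
  pool <- make_name_pool(150L)
  pool <- pool[!grepl(" ", pool)]
  filler <- "concomitantly"
  sents <- vector("list", n_sentences)
  for (i in seq_len(n_sentences)) {
    id <- sprintf("s%04d", i)
    short <- i %% 2L == 0L
    cls <- if (short) "effect" else "mechanism"
    gap <- if (short) 3L else 9L
    tail_n <- 12L - gap
    nms <- sample(pool, 2)
    parts <- c(lapply(rep(filler, 3), w), list(d(nms[1])),
               lapply(rep(filler, gap), w), list(d(nms[2])),
               lapply(rep(filler, tail_n), w))
    sents[[i]] <- assemble_sentence(id, parts,
                                    list(list(i = 1L, j = 2L, label = cls)))
  }
  docs <- split(sents, (seq_along(sents) - 1L) %/% 25L)
  names(docs) <- sprintf("d%03d", seq_along(docs) - 1L)
  ddi_corpus(docs)
}
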