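#' The five interaction classes, in fixed order
#'
#' Class order is load-bearing: the softmax layer emits scores in this order
#' and argmax ties are broken by it. The four positive types come first,
#' `negative` last.
#'
#' @export
DDI_CLASSES <- c("mechanism", "effect", "advice", "int", "negative")

#' Construct a sentence record
#'
#' A sentence record carries the raw sentence text, its annotated drug
#' mentions (character offsets, 0-based inclusive) and the gold typed pairs
#' between them.
#'
#' @param id sentence identifier, unique within the corpus.
#' @param text sentence text (UTF-8).
#' @param entities data.frame with columns `id`, `char_start`, `char_end`,
#'   `text`, `type`. Offsets are 0-based and inclusive; `text` must equal the
#'   corresponding substring of `text`.
#' @param pairs data.frame with columns `e1`, `e2`, `label`; labels from
#'   [DDI_CLASSES].
#' @param subset one of `"drugbank"`, `"medline"`, `"synthetic"`.
#' @return an object of class `ddi_sentence`.
#' @export
ddi_sentence <- function(id, text, entities = empty_entities(),
                         pairs = empty_pairs(), subset = "synthetic") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(text), length(text) == 1L)
  subset <- match.arg(subset, c("drugbank", "medline", "synthetic"))
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  s <- structure(list(id = id, text = text, entities = entities,
                      pairs = pairs, subset = subset),
                 class = "ddi_sentence")
  validate_sentence(s)
  s
}

empty_entities <- function() {
  data.frame(id = character(), char_start = integer(), char_end = integer(),
             text = character(), type = character(), stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(e1 = character(), e2 = character(), label = character(),
             stringsAsFactors = FALSE)
}

validate_sentence <- function(s) {
  ent <- s$entities
  if (nrow(ent)) {
    if (anyDuplicated(ent$id))
      stop("duplicate entity ids in sentence ", s$id)
    nchr <- nchar(s$text)
    for (i in seq_len(nrow(ent))) {
      cs <- ent$char_start[i]; ce <- ent$char_end[i]
      if (cs > ce || cs < 0L || ce >= nchr)
        stop("entity offset outside sentence text: entity ", ent$id[i],
             " in sentence ", s$id)
      span <- substr(s$text, cs + 1L, ce + 1L)
      if (!identical(span, ent$text[i]))
        stop("entity surface text does not match offsets: entity ", ent$id[i],
             " in sentence ", s$id, " ('", span, "' vs '", ent$text[i], "')")
    }
  }
  pr <- s$pairs
  if (nrow(pr)) {
    if (any(pr$e1 == pr$e2))
      stop("pair with identical entity ids in sentence ", s$id)
    known <- c(pr$e1, pr$e2) %in% ent$id
    if (!all(known))
      stop("pair references unknown entity in sentence ", s$id)
    if (!all(pr$label %in% DDI_CLASSES))
      stop("invalid pair label in sentence ", s$id, ": ",
           paste(setdiff(pr$label, DDI_CLASSES), collapse = ", "))
  }
  invisible(s)
}

#' Construct a corpus
#'
#' @param documents named list: document id -> list of [ddi_sentence] records.
#' @return an object of class `ddi_corpus`.
#' @export
ddi_corpus <- function(documents = list()) {
  if (length(documents) && anyDuplicated(names(documents)))
    stop("duplicate document ids")
  structure(list(documents = documents), class = "ddi_corpus")
}

#' @export
print.ddi_corpus <- function(x, ...) {
  sents <- corpus_sentences(x)
  n_pairs <- sum(vapply(sents, function(s) nrow(s$pairs), integer(1)))
  cat("<ddi_corpus> ", length(x$documents), " documents, ",
      length(sents), " sentences, ", n_pairs, " gold pairs\n", sep = "")
  invisible(x)
}

#' Flatten a corpus into a list of sentence records
#'
#' @param corpus a [ddi_corpus].
#' @return unnamed list of `ddi_sentence` records in document order.
#' @export
corpus_sentences <- function(corpus) {
  unlist(unname(corpus$documents), recursive = FALSE)
}

# ---- XML dialect -----------------------------------------------------------

parse_char_offset <- function(offset, entity_id) {
  # dialect: "start-end" 0-based inclusive; discontinuous spans are
  # semicolon-separated and the whole mention is skipped (returns NULL)
  if (grepl(";", offset, fixed = TRUE)) {
    warning("skipping discontinuous mention ", entity_id,
            " (charOffset '", offset, "')", call. = FALSE)
    return(NULL)
  }
  m <- regmatches(offset, regexec("^([0-9]+)-([0-9]+)$", offset))[[1]]
  if (length(m) != 3L)
    stop("malformed charOffset '", offset, "' for entity ", entity_id)
  c(start = as.integer(m[2]), end = as.integer(m[3]))
}

read_sentence_node <- function(node, subset, lenient_type) {
  id <- xml2::xml_attr(node, "id")
  text <- xml2::xml_attr(node, "text")
  ents <- empty_entities()
  dropped <- character()
  for (e in xml2::xml_find_all(node, "./entity")) {
    eid <- xml2::xml_attr(e, "id")
    off <- parse_char_offset(xml2::xml_attr(e, "charOffset"), eid)
    if (is.null(off)) { dropped <- c(dropped, eid); next }
    ents <- rbind(ents, data.frame(
      id = eid, char_start = off[["start"]], char_end = off[["end"]],
      text = xml2::xml_attr(e, "text"),
      type = xml2::xml_attr(e, "type", default = ""),
      stringsAsFactors = FALSE))
  }
  prs <- empty_pairs()
  for (p in xml2::xml_find_all(node, "./pair")) {
    e1 <- xml2::xml_attr(p, "e1"); e2 <- xml2::xml_attr(p, "e2")
    if (e1 %in% dropped || e2 %in% dropped) {
      warning("dropping pair referencing skipped mention in sentence ", id,
              call. = FALSE)
      next
    }
    ddi <- xml2::xml_attr(p, "ddi")
    if (identical(ddi, "false")) {
      label <- "negative"
    } else if (identical(ddi, "true")) {
      label <- xml2::xml_attr(p, "type")
      if (is.na(label)) {
        if (lenient_type) label <- "int"
        else stop("positive pair without type attribute in sentence ", id,
                  " (use lenient_type = TRUE to map to 'int')")
      }
    } else {
      stop("pair with invalid ddi attribute '", ddi, "' in sentence ", id)
    }
    prs <- rbind(prs, data.frame(e1 = e1, e2 = e2, label = label,
                                 stringsAsFactors = FALSE))
  }
  ddi_sentence(id, text, ents, prs, subset = subset)
}

read_document_node <- function(node, lenient_type) {
  subset <- xml2::xml_attr(node, "subset")
  if (is.na(subset)) subset <- "synthetic"
  lapply(xml2::xml_find_all(node, "./sentence"),
         read_sentence_node, subset = subset, lenient_type = lenient_type)
}

#' Read a DDIExtraction-2013-style XML corpus
#'
#' Accepts a single file or a directory of XML files. Each file holds either
#' a `<corpus>` root with `<document>` children or a single `<document>`
#' root. Sentences carry `id` and `text` attributes; `<entity>` children
#' carry `id`, `charOffset` (`start-end`, 0-based inclusive), `type`, `text`;
#' `<pair>` children carry `e1`, `e2`, `ddi` (`true`/`false`) and, for
#' positive pairs, `type`. `ddi="false"` maps to label `negative`.
#'
#' Discontinuous mentions (semicolon-separated charOffset) are skipped with a
#' warning and pairs referencing them dropped.
#'
#' @param path XML file or directory of XML files.
#' @param lenient_type if TRUE, a positive pair lacking a type attribute is
#'   mapped to `int`; if FALSE (default) the file is rejected.
#' @return a [ddi_corpus].
#' @export
read_ddi_xml <- function(path, lenient_type = FALSE) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    path
  }
  docs <- list()
  for (f in files) {
    x <- tryCatch(xml2::read_xml(f),
                  error = function(e) stop("malformed XML in ", f, ": ",
                                           conditionMessage(e)))
    root <- xml2::xml_name(x)
    doc_nodes <- if (root == "corpus") xml2::xml_find_all(x, "./document")
                 else if (root == "document") list(x)
                 else stop("unexpected root element <", root, "> in ", f)
    for (d in doc_nodes) {
      did <- xml2::xml_attr(d, "id")
      if (did %in% names(docs)) stop("duplicate document id ", did)
      docs[[did]] <- read_document_node(d, lenient_type)
    }
  }
  ddi_corpus(docs)
}

#' Write a corpus in the DDIExtraction-2013-style XML dialect
#'
#' Emits the same dialect [read_ddi_xml] accepts; `read(write(c))` equals `c`
#' field for field.
#'
#' @param corpus a [ddi_corpus].
#' @param path output file path.
#' @export
write_ddi_xml <- function(corpus, path) {
  doc <- xml2::xml_new_root("corpus")
  for (did in names(corpus$documents)) {
    sents <- corpus$documents[[did]]
    subset <- if (length(sents)) sents[[1]]$subset else "synthetic"
    dn <- xml2::xml_add_child(doc, "document", id = did, subset = subset)
    for (s in sents) {
      sn <- xml2::xml_add_child(dn, "sentence", id = s$id, text = s$text)
      ent <- s$entities
      for (i in seq_len(nrow(ent))) {
        xml2::xml_add_child(sn, "entity", id = ent$id[i],
          charOffset = paste0(ent$char_start[i], "-", ent$char_end[i]),
          type = ent$type[i], text = ent$text[i])
      }
      pr <- s$pairs
      for (i in seq_len(nrow(pr))) {
        if (pr$label[i] == "negative") {
          xml2::xml_add_child(sn, "pair", id = paste0(s$id, ".p", i - 1L),
                              e1 = pr$e1[i], e2 = pr$e2[i], ddi = "false")
        } else {
          xml2::xml_add_child(sn, "pair", id = paste0(s$id, ".p", i - 1L),
                              e1 = pr$e1[i], e2 = pr$e2[i], ddi = "true",
                              type = pr$label[i])
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Corpus statistics per subset
#'
#' Counts documents, gold pairs, positives, negatives and the four positive
#' types per subset tag, plus a `total` row. Totals satisfy
#' `pairs = positive + negative` and
#' `positive = mechanism + effect + advice + int`.
#'
#' @param corpus a [ddi_corpus].
#' @return data.frame with one row per subset present, plus `total`.
#' @export
corpus_stats <- function(corpus) {
  sents <- corpus_sentences(corpus)
  subsets <- unique(vapply(sents, function(s) s$subset, character(1)))
  row_for <- function(keep_sents, keep_docs) {
    labs <- unlist(lapply(keep_sents, function(s) s$pairs$label))
    counts <- vapply(DDI_CLASSES, function(cl) sum(labs == cl), integer(1))
    data.frame(documents = keep_docs, pairs = length(labs),
               positive = sum(counts[1:4]), negative = counts[["negative"]],
               mechanism = counts[["mechanism"]], effect = counts[["effect"]],
               advice = counts[["advice"]], int = counts[["int"]])
  }
  rows <- list()
  for (sub in subsets) {
    keep <- Filter(function(s) s$subset == sub, sents)
    ndoc <- sum(vapply(corpus$documents, function(d)
      any(vapply(d, function(s) s$subset == sub, logical(1))), logical(1)))
    rows[[sub]] <- row_for(keep, ndoc)
  }
  rows[["total"]] <- row_for(sents, length(corpus$documents))
  out <- do.call(rbind, rows)
  out$subset <- names(rows)
  out[, c("subset", "documents", "pairs", "positive", "negative",
          "mechanism", "effect", "advice", "int")]
}

# ---- JSON-lines internal format -------------------------------------------

#' Write a corpus as JSON-lines (one sentence record per line)
#'
#' @param corpus a [ddi_corpus].
#' @param path output file path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (did in names(corpus$documents)) {
    for (s in corpus$documents[[did]]) {
      rec <- list(doc_id = did, id = s$id, text = s$text, subset = s$subset,
                  entities = s$entities, pairs = s$pairs)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read a corpus from the JSON-lines internal format
#'
#' @param path JSON-lines file written by [write_corpus_jsonl].
#' @return a [ddi_corpus].
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  docs <- list()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    ent <- if (length(rec$entities)) rec$entities else empty_entities()
    prs <- if (length(rec$pairs)) rec$pairs else empty_pairs()
    s <- ddi_sentence(rec$id, rec$text, ent, prs, subset = rec$subset)
    docs[[rec$doc_id]] <- c(docs[[rec$doc_id]], list(s))
  }
  ddi_corpus(docs)
}
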