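test_that("sentence records validate offsets, pairs and labels", {
  expect_error(ddi_sentence("s", "abc def", data.frame(
    id = "e0", char_start = 4L, char_end = 9L, text = "def", type = "drug")),
    "offset outside")
  expect_error(ddi_sentence("s", "abc def", data.frame(
    id = "e0", char_start = 0L, char_end = 2L, text = "zzz", type = "drug")),
    "does not match")
  ents <- data.frame(id = c("e0", "e1"), char_start = c(0L, 4L),
                     char_end = c(2L, 6L), text = c("abc", "def"),
                     type = "drug")
  expect_error(ddi_sentence("s", "abc def", ents,
                            data.frame(e1 = "e0", e2 = "e9", label = "int")),
               "unknown entity")
  expect_error(ddi_sentence("s", "abc def", ents,
                            data.frame(e1 = "e0", e2 = "e0", label = "int")),
               "identical entity ids")
  expect_error(ddi_sentence("s", "abc def", ents,
                            data.frame(e1 = "e0", e2 = "e1", label = "bogus")),
               "invalid pair label")
})

test_that("a sentence with 4 entities and 6 pairs reads back as such", {
  s <- table1_sentence()
  prs <- enumerate_pairs(s)
  pairs <- data.frame(e1 = prs$e1, e2 = prs$e2,
                      label = c("effect", rep("negative", 5)))
  s <- ddi_sentence(s$id, s$text, s$entities, pairs, subset = "drugbank")
  path <- withr::local_tempfile(fileext = ".xml")
  write_ddi_xml(ddi_corpus(list(doc1 = list(s))), path)
  back <- read_ddi_xml(path)
  s2 <- corpus_sentences(back)[[1]]
  expect_equal(nrow(s2$entities), 4L)
  expect_equal(nrow(s2$pairs), 6L)
  expect_equal(s2$subset, "drugbank")
})

test_that("XML round-trip reproduces a synthetic corpus field for field", {
  g <- generate_corpus(synth_config(n_sentences = 30, seed = 21))
  path <- withr::local_tempfile(fileext = ".xml")
  write_ddi_xml(g$corpus, path)
  expect_equal(read_ddi_xml(path), g$corpus)
})

test_that("empty corpus writes and reads as empty", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_ddi_xml(ddi_corpus(), path)
  back <- read_ddi_xml(path)
  expect_length(back$documents, 0L)
  expect_equal(nrow(corpus_stats(back)), 1L)  # just the total row
  expect_true(all(corpus_stats(back)[, -1] == 0))
})

test_that("all five labels survive the ddi/type attribute encoding", {
  sents <- lapply(seq_along(DDI_CLASSES), function(i)
    two_drug_sentence(paste0("s", i), label = DDI_CLASSES[i]))
  path <- withr::local_tempfile(fileext = ".xml")
  write_ddi_xml(ddi_corpus(list(doc = sents)), path)
  back <- corpus_sentences(read_ddi_xml(path))
  expect_equal(vapply(back, function(s) s$pairs$label, character(1)),
               DDI_CLASSES)
})

test_that("discontinuous mentions are skipped with a warning, their pairs dropped", {
  xml <- paste0(
    '<corpus><document id="d0"><sentence id="s0" text="abc def ghi">',
    '<entity id="e0" charOffset="0-2" type="drug" text="abc"/>',
    '<entity id="e1" charOffset="4-6;8-10" type="drug" text="def ghi"/>',
    '<pair id="p0" e1="e0" e2="e1" ddi="false"/>',
    '</sentence></document></corpus>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  expect_warning(expect_warning(corp <- read_ddi_xml(path),
                                "discontinuous"), "dropping pair")
  s <- corpus_sentences(corp)[[1]]
  expect_equal(nrow(s$entities), 1L)
  expect_equal(nrow(s$pairs), 0L)
})

test_that("positive pair without type is rejected in strict mode, int in lenient", {
  xml <- paste0(
    '<corpus><document id="d0"><sentence id="s0" text="abc def">',
    '<entity id="e0" charOffset="0-2" type="drug" text="abc"/>',
    '<entity id="e1" charOffset="4-6" type="drug" text="def"/>',
    '<pair id="p0" e1="e0" e2="e1" ddi="true"/>',
    '</sentence></document></corpus>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  expect_error(read_ddi_xml(path), "without type")
  corp <- read_ddi_xml(path, lenient_type = TRUE)
  expect_equal(corpus_sentences(corp)[[1]]$pairs$label, "int")
})

test_that("malformed XML errors name the file", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<corpus><unclosed>", path)
  expect_error(read_ddi_xml(path), basename(path), fixed = TRUE)
})

test_that("corpus_stats counts are exact sums and internally consistent", {
  s1 <- two_drug_sentence("a1", label = "mechanism")
  prs <- data.frame(e1 = "e0", e2 = "e1", label = "negative")
  s2 <- ddi_sentence("a2", s1$text, s1$entities, prs, subset = "medline")
  st <- corpus_stats(ddi_corpus(list(doc = list(s1), doc2 = list(s2))))
  tot <- st[st$subset == "total", ]
  expect_equal(tot$positive, 1)
  expect_equal(tot$negative, 1)
  expect_equal(tot$mechanism, 1)
  expect_equal(tot$pairs, tot$positive + tot$negative)
  expect_equal(tot$positive,
               tot$mechanism + tot$effect + tot$advice + tot$int)
  expect_setequal(st$subset, c("synthetic", "medline", "total"))
})

test_that("JSON-lines internal format round-trips", {
  g <- generate_corpus(synth_config(n_sentences = 12, seed = 5))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(g$corpus, path)
  expect_equal(read_corpus_jsonl(path), g$corpus)
})
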