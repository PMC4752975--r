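test_that("confusion matrix counts gold x predicted with planted errors", {
  gold <- c("mechanism", "mechanism", "effect", "int", "negative")
  pred <- c("mechanism", "effect", "effect", "negative", "negative")
  cm <- build_confusion(gold, pred)
  expect_equal(unname(cm["mechanism", "mechanism"]), 1L)
  expect_equal(unname(cm["mechanism", "effect"]), 1L)
  expect_equal(unname(cm["int", "negative"]), 1L)
  expect_equal(unname(rowSums(cm)),
               as.vector(table(factor(gold, levels = DDI_CLASSES))))
  expect_error(build_confusion(gold, pred[-1]), "different lengths")
  expect_true(all(build_confusion(character(), character()) == 0L))
})

test_that("all-correct predictions give a diagonal matrix and perfect metrics", {
  gold <- rep(DDI_CLASSES, times = 2:6)
  cm <- build_confusion(gold, gold)
  expect_true(all(cm[upper.tri(cm)] == 0L) && all(cm[lower.tri(cm)] == 0L))
  m <- micro_metrics(cm)
  expect_equal(m$precision, 100)
  expect_equal(m$recall, 100)
  expect_equal(m$f_score, 100)
})

test_that("micro metrics reproduce the published overall scores from the printed counts", {
  m <- micro_metrics(table5_matrix())
  expect_equal(round_half_up(m$precision), 75.72)
  expect_equal(round_half_up(m$recall), 64.66)
  expect_equal(round_half_up(m$f_score), 69.75)
})

test_that("per-type metrics from the printed counts match the published table", {
  cm <- table5_matrix()
  expect_equal(round_half_up(micro_metrics(cm, "advice")$f_score), 77.75)
  expect_equal(round_half_up(micro_metrics(cm, "int")$f_score), 46.38)
  expect_equal(round_half_up(micro_metrics(cm, "mechanism")$recall), 62.91)
  expect_equal(round_half_up(micro_metrics(cm, "mechanism")$precision), 79.50)
  expect_equal(round_half_up(micro_metrics(cm, "effect")$f_score), 69.33)
})

test_that("recall equals a per-instance counting oracle and F obeys its bounds", {
  set.seed(33)
  for (rep in 1:5) {
    gold <- sample(DDI_CLASSES, 200, replace = TRUE, prob = c(2, 3, 2, 1, 8))
    pred <- ifelse(runif(200) < 0.6, gold, sample(DDI_CLASSES, 200, TRUE))
    m <- micro_metrics(build_confusion(gold, pred))
    oracle_r <- 100 * sum(gold == pred & gold != "negative") /
      sum(gold != "negative")
    expect_equal(m$recall, oracle_r)
    if (m$precision + m$recall > 0) {
      expect_lte(m$f_score, (m$precision + m$recall) / 2 + 1e-9)
      expect_lte(m$f_score, 2 * min(m$precision, m$recall) + 1e-9)
    }
  }
})

test_that("metrics ignore the provenance split of predicted negatives", {
  gold <- c("mechanism", "effect", "negative", "negative")
  pred <- c("mechanism", "negative", "negative", "negative")
  m1 <- micro_metrics(build_confusion(gold, pred,
                                      source = c("model", "model", "model", "model")))
  m2 <- micro_metrics(build_confusion(gold, pred,
                                      source = c("model", "filter", "filter", "model")))
  expect_equal(m1$precision, m2$precision)
  expect_equal(m1$recall, m2$recall)
  cm <- build_confusion(gold, pred, source = c("model", "filter", "filter", "model"))
  sp <- attr(cm, "negative_split")
  expect_equal(sum(sp), 3)  # three predicted negatives in total
  expect_equal(unname(sp["filter", "effect"]), 1)
})

test_that("zero denominators give zero metrics with a note", {
  cm <- build_confusion(rep("negative", 3), rep("negative", 3))
  expect_message(m <- micro_metrics(cm), "recall")
  expect_equal(m$f_score, 0)
})

test_that("the per-type/per-subset report matches hand-computed rows", {
  s1 <- two_drug_sentence("r1", label = "mechanism")
  s2 <- two_drug_sentence("r2", label = "effect")
  s3 <- two_drug_sentence("r3", label = "negative")
  s2$subset <- "medline"
  corp <- ddi_corpus(list(d1 = list(s1, s3), d2 = list(s2)))
  preds <- data.frame(
    sentence_id = c("r1", "r2", "r3"), e1 = rep("e0", 3), e2 = rep("e1", 3),
    predicted = c("mechanism", "advice", "negative"),
    source = rep("model", 3), stringsAsFactors = FALSE)
  rep_tab <- per_type_and_subset_report(corp, preds)
  mech <- rep_tab[rep_tab$row == "mechanism", ]
  expect_equal(mech$precision, 100)
  expect_equal(mech$recall, 100)
  eff <- rep_tab[rep_tab$row == "effect", ]
  expect_equal(eff$recall, 0)
  overall <- rep_tab[rep_tab$row == "overall", ]
  expect_equal(overall$precision, 50)      # 1 TP of 2 predicted positives
  expect_equal(overall$recall, 50)         # 1 TP of 2 gold positives
  med <- rep_tab[rep_tab$row == "medline", ]
  expect_equal(med$n_gold, 1)
  # single-subset corpus: subset row equals overall row
  corp1 <- ddi_corpus(list(d1 = list(s1, s3)))
  r1 <- per_type_and_subset_report(corp1, preds[c(1, 3), ])
  expect_equal(r1[r1$row == "synthetic", -1], r1[r1$row == "overall", -1],
               ignore_attr = TRUE)
})

test_that("candidates without a prediction row count as predicted negative", {
  s <- two_drug_sentence("q1", label = "effect")
  corp <- ddi_corpus(list(d = list(s)))
  empty_preds <- data.frame(sentence_id = character(), e1 = character(),
                            e2 = character(), predicted = character(),
                            stringsAsFactors = FALSE)
  rep_tab <- per_type_and_subset_report(corp, empty_preds)
  expect_equal(rep_tab[rep_tab$row == "overall", "recall"], 0)
})

test_that("prediction TSV interchange round-trips", {
  preds <- data.frame(sentence_id = c("a", "b"), e1 = c("e0", "e0"),
                      e2 = c("e1", "e2"), predicted = c("int", "negative"),
                      source = c("model", "filter"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions_tsv(preds, path)
  expect_equal(read_predictions_tsv(path), preds)
})

test_that("half-up rounding matches the published tables' convention", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(75.715, 2), 75.72)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
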