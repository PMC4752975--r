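# Shared fixtures, built in code.

# the published worked example: one sentence, four annotated drug mentions
# (rendered without the prose commas, as the blinded rows print it)
table1_sentence <- function() {
  text <- paste("When ALFENTA is administered in combination with other",
                "CNS depressants such as barbiturates or tranquilizers")
  names <- c("ALFENTA", "CNS depressants", "barbiturates", "tranquilizers")
  ents <- do.call(rbind, lapply(seq_along(names), function(i) {
    m <- regexpr(names[i], text, fixed = TRUE)
    data.frame(id = paste0("s0.e", i - 1L), char_start = m[1] - 1L,
               char_end = m[1] + attr(m, "match.length") - 2L,
               text = names[i], type = "drug", stringsAsFactors = FALSE)
  }))
  ddi_sentence("s0", text, ents, subset = "drugbank")
}

# expected blinded rows for all six candidates of the worked example,
# lowercased, in first-mention pair order
table1_blinded <- function() {
  pre <- "when %s is administered in combination with other %s such as %s or %s"
  c(sprintf(pre, "drug1", "drug2", "drug0", "drug0"),
    sprintf(pre, "drug1", "drug0", "drug2", "drug0"),
    sprintf(pre, "drug1", "drug0", "drug0", "drug2"),
    sprintf(pre, "drug0", "drug1", "drug2", "drug0"),
    sprintf(pre, "drug0", "drug1", "drug0", "drug2"),
    sprintf(pre, "drug0", "drug0", "drug1", "drug2"))
}

# the published test-set confusion counts (gold rows x predicted columns,
# class order mechanism/effect/advice/int/negative); predicted-negative
# cells include both model- and filter-sourced negatives
table5_matrix <- function() {
  matrix(c(190,   8,   7,  0,   97,
             6, 252,   3,  1,   98,
             2,   1, 159,  2,   57,
             0,  39,   0, 32,   25,
            41,  67,  19,  7, 1905 + 2698),
         nrow = 5, byrow = TRUE,
         dimnames = list(gold = DDI_CLASSES, predicted = DDI_CLASSES))
}

# a two-drug sentence with a given connecting phrase
two_drug_sentence <- function(id = "t0", a = "alphazol", b = "betamol",
                              phrase = "increases the effect of",
                              label = "mechanism") {
  text <- paste(a, phrase, b)
  ents <- data.frame(
    id = c("e0", "e1"),
    char_start = c(0L, nchar(a) + nchar(phrase) + 2L),
    char_end = c(nchar(a) - 1L, nchar(text) - 1L),
    text = c(a, b), type = "drug", stringsAsFactors = FALSE)
  pairs <- data.frame(e1 = "e0", e2 = "e1", label = label,
                      stringsAsFactors = FALSE)
  ddi_sentence(id, text, ents, pairs)
}

# split instances into train/held-out under a fixed seed
split_instances <- function(insts, n_train, seed = 1L) {
  set.seed(seed)
  idx <- sample(length(insts))
  list(train = insts[idx[seq_len(n_train)]],
       test = insts[idx[(n_train + 1L):length(insts)]])
}

tiny_trained_model <- function(n_sent = 20L, n = 8L, seed = 9L) {
  corp <- make_separable(n_sent, seed = 3L)
  insts <- corpus_instances(corp, n = n)
  vocab <- build_vocab(insts)
  cfg <- ddi_train_config(d_w = 4L, d_p = 2L, n = n, widths = c(2L, 3L),
                          n_filters = c(1L, 1L), epochs = 1L, dropout = 0,
                          minibatch = 5L, seed = seed)
  tab <- init_tables(vocab, d_w = 4L, d_p = 2L, n = n, seed = seed)
  list(model = train_cnn(insts[1:5], tab, cfg), instances = insts)
}
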