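# ddicnn

Extraction of typed drug–drug interactions (DDIs) from biomedical sentences
with a convolutional neural network, in pure R.

Unexpected interactions between co-administered drugs are a major source of
adverse events, and most newly reported DDIs first appear in free text.
`ddicnn` treats DDI extraction as multi-class relation classification: every
unordered pair of annotated drug mentions in a sentence is a candidate, to
be labeled **mechanism** (pharmacokinetic mechanism described), **effect**
(pharmacodynamic effect described), **advice** (a recommendation about
co-administration), **int** (a bare statement that an interaction exists),
or **negative** (no interaction). The package is aimed at text-mining
researchers and practitioners working with DDIExtraction-2013-style corpora
— XML documents whose sentences carry character-offset drug annotations and
gold typed pairs — and at anyone who wants a fully inspectable, dependency-
light reference implementation of the method.

## The method

For a sentence with *m* annotated drugs, all C(*m*,2) candidate pairs are
generated. For each candidate the two focus mentions are *blinded* to
`drug1` and `drug2` (in order of occurrence) and all other drug mentions to
`drug0`, so the classifier generalizes across drug names. The blinded
sentence is lowercased, word-tokenized and padded with `#` to a fixed
length *n* (default 150, the published corpus maximum).

Deterministic **negative-instance filtering** removes candidates that
cannot interact before classification: identical names, parenthesized
abbreviations (`drug1 (drug2)`), co-membership in a coordination of ≥ 3
drugs, and hypernym constructions (`drug1 such as drug2`, `including`,
`e.g.`).

Each surviving instance is encoded through a look-up table layer: token
*w_i* at position *i* contributes a column
`x_i = [e_w_i; e_{i-p1}; e_{i-p2}]`, stacking its word embedding
(`C ∈ R^{d_w×|V|}`, d_w = 300) on two position embeddings
(`D1, D2 ∈ R^{d_p×(2n−1)}`, d_p = 10) indexed by its signed distance to the
two focus drugs. Convolution filters `t ∈ R^{(d_w+2d_p)×k}` of widths
k ∈ {3,4,5} (200 each) produce features
`f_i = tanh(⟨t, x_{i:i+k−1}⟩ + b)`, reduced by max-over-time pooling to one
scalar per filter; dropout (p = 0.5) and a fully connected softmax over the
five classes finish the forward pass. Training is minibatch SGD (size 50)
with the AdaDelta update rule and per-row l2-norm rescaling (threshold 3)
of the softmax weights. Forward pass and backpropagation are written out in
base R matrix algebra and checked against finite differences in the test
suite.

Evaluation is challenge-style: a 5×5 gold-vs-predicted confusion matrix and
micro-averaged precision/recall/F pooled over the four positive classes,
reported overall, per type and per corpus subset.

A synthetic-corpus generator (`generate_corpus()`, `make_separable()`,
`make_distance_contrast()`) emits the same XML dialect with controllable
class structure, trigger lexicons and planted filter traps, so the entire
pipeline is exercisable without downloading the challenge corpus.

## Worked example

The canonical four-drug sentence produces six candidates; blinding and
filtering behave as follows:

```r
library(ddicnn)
text <- paste("When ALFENTA is administered in combination with other",
              "CNS depressants such as barbiturates or tranquilizers")
names <- c("ALFENTA", "CNS depressants", "barbiturates", "tranquilizers")
ents <- do.call(rbind, lapply(seq_along(names), function(i) {
  m <- regexpr(names[i], text, fixed = TRUE)
  data.frame(id = paste0("s0.e", i - 1), char_start = m[1] - 1,
             char_end = m[1] + attr(m, "match.length") - 2,
             text = names[i], type = "drug")
}))
s <- ddi_sentence("s0", text, ents)
prs <- enumerate_pairs(s)
nrow(prs)
#> [1] 6
tolower(blind_drugs(s, c(prs$e1[4], prs$e2[4])))
#> [1] "when drug0 is administered in combination with other drug1 such as drug2 or drug0"
apply_filters(s, c(prs$e1[4], prs$e2[4]))$criterion
#> [1] "special_case"
```

The fourth and fifth candidates — "CNS depressants" paired with each of its
named examples — are removed by the hypernym rule; the other four proceed
to the classifier.

Scoring recomputed from a 5×5 confusion matrix:

```r
m <- micro_metrics(cm)   # cm: gold x predicted counts, class order
print(m)
#> P = 75.72%  R = 64.66%  F = 69.75%  (TP 633 / predicted 836 / gold 979)
```

Here precision is pooled true positives over all predicted-positive
candidates, recall over all gold-positive candidates, and F their harmonic
mean — a prediction counts only if the interaction *type* matches.

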