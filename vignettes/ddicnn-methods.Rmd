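---
title: "Extracting drug-drug interactions with a convolutional sentence classifier"
author: "ddicnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting drug-drug interactions with a convolutional sentence classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddicnn)
```

## The task and the model

Drug–drug interaction (DDI) extraction is relation classification over
sentences with annotated drug mentions: every unordered mention pair is a
candidate instance, labeled mechanism, effect, advice, int, or negative.
`ddicnn` implements the full pipeline — candidate generation with drug
blinding, rule-based negative filtering, a convolutional classifier over
word and position embeddings, and micro-averaged evaluation — with no
features beyond tokens and token distances. That restriction is the point
of the model family: it avoids parsers, taggers and hand-built lexical
features, and the errors they propagate.

An instance is the blinded, lowercased, `#`-padded token sequence
$S = w_1 \dots w_n$ with the focus drugs at positions $p_1 < p_2$. Token
$i$ is encoded as the stacked column
$x_i = [\,e_{w_i}^\top, e_{d_{i1}}^\top, e_{d_{i2}}^\top\,]^\top$ with
$d_{i1} = i - p_1$, $d_{i2} = i - p_2$; the instance becomes a
$(d_w + 2d_p) \times n$ matrix. A filter $t$ of width $k$ yields
$f_i = \tanh(\langle t, x_{i:i+k-1}\rangle + b)$ for
$i = 1 \dots n-k+1$; max-over-time pooling keeps one scalar per filter;
dropout and a softmax layer over the five classes complete the network.
Training minimizes categorical cross-entropy (the standard companion of a
softmax output; the model family does not prescribe another loss) by
minibatch SGD with AdaDelta, rescaling any softmax weight row whose
$\ell_2$ norm exceeds a threshold $s$ back onto it after every step.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` | 150 tokens | fixed instance length; the published corpus maximum, so truncation never fires there |
| `d_w` | 300 | word-embedding dimension |
| `d_p` | 10 | position-embedding dimension per drug (0 = words-only ablation) |
| widths / counts | 3,4,5 / 200 each | convolution windows in tokens and filters per width |
| `dropout` | 0.5 | Bernoulli drop probability on the pooled vector at train time |
| `l2_threshold` | 3 | cap on each softmax row's $\ell_2$ norm |
| `minibatch` | 50 | instances per AdaDelta step |
| `adadelta_rho`, `adadelta_eps` | 0.95, 1e-6 | the optimizer's original constants; the method names the rule but no constants |
| `epochs` | 25 | fixed pass count; no early stopping by default |
| `init_range` | 0.05 | uniform $[-r, r]$ init for position columns, filters, softmax and out-of-vocabulary word vectors — the small-magnitude convention of this model family, which states only "randomly initialized" |

Pretrained word vectors (word2vec text format) may seed the word matrix;
vectors are fine-tuned by default because the update rule's parameter list
includes the word-embedding matrix, with a `freeze_words` flag for the
alternative reading. The vocabulary is built from the training split only;
unseen test tokens map to a dedicated unknown entry.

## Numerical and design choices

**Dropout convention.** The published description applies no rescaling at
test time. To keep train- and test-time expectations of the softmax input
consistent, the default here is inverted dropout (mask, then divide by
$1-p$ during training); `paper_exact_dropout = TRUE` restores the literal
convention. Masks are drawn independently per element and per instance.

**Pooling ties.** `max.col(..., ties.method = "first")`: the earliest
maximal window wins, making prediction deterministic. Argmax ties over
class probabilities break by class order (mechanism, effect, advice, int,
negative).

**Distance indexing.** Signed distances in $[-n+1, n-1]$ map bijectively
to position-table columns $d + n$ (1-based); padding tokens continue the
$i - p$ formula, which keeps every distance inside the stated range.

**Truncation.** Sentences longer than `n` tokens are right-truncated, never
past the later focus drug; if the drugs still do not fit, the window is
centered on the drug span, and an instance whose drugs are further apart
than `n` is rejected. On data matching the published setting (`n` = corpus
maximum) none of this fires.

**Blinding.** Multi-word mention spans collapse to a single placeholder
token so token positions stay well defined. Mentions at identical offsets
(fully nested annotations) are rejected at blinding; overlapping but
non-identical spans are rejected too, since no consistent replacement
exists. Discontinuous `charOffset` annotations are skipped on read with a
warning.

**Filtering dialect.** The published description gives the four criteria
and three pattern hints, not a full rule inventory; the inventory here
(same-name string match; `drug1 (drug2)`; placeholder lists of ≥ 3 split on
commas/and/or; `such as`/`including`/`e.g.` hypernym constructions with an
optional comma before the cue) is this package's dialect, versioned in the
rule object so alternatives can be swapped in. Criteria are tested in order
1→4, first match wins, for stable attribution. Gold-positive candidates
removed by the filter trigger a warning above a 1% alarm threshold —
mirroring the observation that the published rules removed well under 1%
of positives.

**Gradient correctness.** Backpropagation through lookup, convolution,
pooling, dropout and softmax is verified against central finite differences
(relative error below $10^{-4}$ on a model with $n=8$, $d_w=4$, $d_p=2$,
2 filters), and the convolution against a naive double loop at $10^{-10}$.
Gradients reach embedding columns only through lookups, so never-looked-up
word columns receive exactly zero gradient.

## The synthetic generator: what it emulates and what it does not

`generate_corpus()` emits the DDIExtraction-2013 XML dialect: documents of
template sentences with 2–6 annotated drug mentions (pronounceable nonsense
names, ~15% multi-word), gold pairs for every candidate, class-specific
trigger phrases (pharmacokinetic wording for mechanism, pharmacodynamic
wording for effect, recommendations for advice, bare interaction statements
for int), and trap constructions firing each filtering criterion. Default
class proportions keep the published corpus flavor — effect commonest among
positives, int rare, plus the negatives arising from multi-drug sentences
and traps. A ledger records every gold label and planted trap, so filter
and statistics tests compare against exact bookkeeping.

`make_separable()` puts class and trigger token in bijection (two drugs,
one unique trigger per class, shared context): a small model must reach
near-perfect held-out accuracy, or the training loop is wrong.
`make_distance_contrast()` builds two classes whose sentences share an
identical *set* of width-≤3 token windows and differ only in the gap
between the focus drugs; a words-only model is blind to the difference
(max pooling sees the same window types), while position embeddings expose
it. This isolates, directionally, the contribution position embeddings make
on real data.

What passing these tests does **not** show: synthetic sentences are short,
lexically clean and perfectly annotated. Real corpus performance depends on
long coordinated sentences, annotation noise, register differences between
drug-label text and scientific abstracts, and severe class imbalance —
none of which the generator reproduces. Corpus-level scores therefore
require the actual challenge corpus, and the published filtering counts
additionally depend on the original (unpublished) rule inventory, which
this package's dialect approximates but need not equal.

## Problem sizes used in the checks

The shipped tests and the acceptance script run on deliberately small
models: learnability uses 500 sentences, $d_w = 32$, $d_p = 4$, 16 filters,
20 epochs, minibatches of 10 and no dropout — on a tiny separable task,
dropout and large batches only slow convergence without telling us anything
about correctness; the distance-contrast ablation uses 300 sentences and a
single width-3 filter bank; gradient checks use $n = 8$. The full published
operating point ($d_w = 300$, 600 filters, $n = 150$) is exercised for
shape and forward-pass properties, not trained in the tests.

## Known limitations

- No class reweighting: the rare `int` type suffers most from imbalance,
  as in the published system, which likewise applied no correction.
- Surface-pattern filtering only; no parser-based coordination analysis
  and no external abbreviation resources.
- Minibatch loss defaults to the mean (an AdaDelta-scale choice; a `sum`
  option exists); the epoch count is fixed rather than tuned, as no
  stopping rule is published.
- Single-threaded base-R training: adequate for the test-scale models
  here; the full operating point on the real corpus is compute-hungry.
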