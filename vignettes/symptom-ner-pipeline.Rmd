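---
title: "Extracting and evaluating symptom mentions in patient narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and evaluating symptom mentions in patient narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sympner)
```

## The problem

Clinical narratives written down from the patient's own words — typically
the subjective field of SOAP-format pharmacy or medical records — mention
diseases and symptoms in short, colloquial, loosely structured sentences.
Two decisions must be made for every mention: *where* it is (a character
span) and *whether it is affirmed or denied* ("headache since yesterday"
vs. "no headache"). The denial half matters as much as the extraction
half: a symptom check-list is only usable for adverse-event monitoring if
"no nausea" is not counted as nausea.

`sympner` implements this joint task at desk scale, together with the
measurement apparatus that such systems are judged by: partial-match
scoring with a similarity threshold, a four-way error taxonomy,
inter-annotator agreement, and learning-curve extrapolation of F1 against
training-set size. Because real pharmaceutical care records are protected,
the package also ships a synthetic-corpus generator and a controlled error
injector so that every claim the package makes about its own machinery can
be verified against a known ground truth.

## Text model and preprocessing

All processing is character-based, on full-width (2-byte) text. Raw
record text is normalized by `normalize_text()`:

* the literal marker `"_X000D_"` (a carriage-return artifact of
  spreadsheet exports) is deleted;
* half-width ASCII and half-width katakana are transliterated to their
  full-width forms (ICU `Halfwidth-Fullwidth`, which also composes
  dakuten: `ｶﾞ` becomes `ガ`); the ASCII space becomes the ideographic
  space.

The transform is idempotent, which makes repeated preprocessing safe.

Deleting `_X000D_` (rather than replacing it with a newline) can merge
two sentences that were separated only by the marker. Because the marker
is described as a line-break indicator, there is a case for substitution
instead; both readings are defensible, so deletion is the default and
`x000d = "newline"` is available on `normalize_text()`,
`split_sentences()` and the `preprocess` subcommand.

`split_sentences()` cuts at line breaks, the ideographic full stop `。`
and the full-width period `．`, keeping the terminal period on its
sentence, stripping edge spaces and dropping blank segments. One guard is
applied: a full-width period flanked by full-width digits on both sides is
treated as a decimal point (`体重５．２ｋｇ`), not a boundary. Whether a
period inside an abbreviation should split is left unguarded — after
normalization an abbreviation period is indistinguishable from a sentence
period without a lexicon, and the records this register emulates rarely
contain them.

Annotations are standoff: 0-based, half-open character offsets into the
normalized sentence, each span carrying `polarity` (`"positive"` =
affirmed, `"negative"` = denied). Spans within a sentence must not
overlap; this is what makes the BIO encoding (`to_bio()` / `from_bio()`)
a bijection and the matching algebra well defined, and overlapping gold
annotations are rejected at construction.

Inter-annotator agreement (`cohen_kappa()`) is computed per character
over three classes (outside, affirmed-entity, denied-entity). Free-span
annotation has no natural discrete unit, and the character is the only
unit that is well defined for arbitrary spans; κ computed this way is
conservative with respect to boundary disagreements.

## The tagger

The tagger is a linear-chain conditional random field over the five-tag
label set `O, B-POS, I-POS, B-NEG, I-NEG`. Folding polarity into the span
labels makes extraction and affirmed/denied classification one sequence
prediction, which mirrors how a joint neural extractor behaves and lets a
single decoder produce the final output. The alternative — a separate
polarity classifier on top of polarity-free spans — was rejected because
it cannot represent the common case where the denial cue sits inside or
adjacent to the span and is best resolved jointly.

For a sentence $x$ of length $T$ and tag sequence $y$:

$$\mathrm{score}(x, y) = \sum_{t=1}^{T} \phi(x, t)^\top W_{\cdot, y_t}
  + \sum_{t=1}^{T-1} A_{y_t, y_{t+1}}$$

where $\phi(x, t)$ is a sparse binary feature vector, $W$ the emission
weights and $A$ the transition weights. The conditional likelihood is
$\exp(\mathrm{score})/Z(x)$ with $Z$ the sum over all $5^T$ sequences.

**Features** (`feature_config()`): character n-grams of orders 1–2 within
a window of radius 2 around the position, keyed by their relative offset,
plus one coarse character-class feature (kanji / kana / latin / digit /
symbol) per offset. A character never seen in training contributes only
its class features, because its n-grams match nothing in the trained
feature set — the model degrades gracefully on out-of-vocabulary
characters instead of failing. The whole feature layer sits behind
`crf_emissions()`, a one-method contract (sentence in, a $T \times 5$
matrix of log-potentials out); a dense sentence encoder can be plugged in
by providing another method, reusing training, decoding and evaluation
unchanged.

**Training** (`crf_fit()`): full-batch penalized maximum likelihood,
minimizing $\sum_i (\log Z(x_i) - \mathrm{score}(x_i, y_i)) +
\|w\|^2 / 2\sigma^2$ with L-BFGS from a zero start. `l2_sigma` (default
1) is the Gaussian prior width in weight units: smaller values shrink
harder, and as $\sigma \to 0^+$ the weights collapse to zero and decoding
falls back to the majority class (all `O`). `max_iter` (default 200) and
`tol` (default 1e-6, projected-gradient) control termination. Training is
deterministic — same corpus and configuration, bit-identical weights —
because the objective is convex, the start is fixed and there is no
mini-batching. The forward–backward and Viterbi recursions are C++
(scaled, so no overflow at any sentence length); gradients are exact
expected-minus-observed feature counts and are checked against central
finite differences in the test suite.

**Decoding**: Viterbi with deterministic tie-breaking — among equally
scoring sequences, the one whose tag at the latest differing position
comes earliest in label order wins, so an all-zero model decodes to all
`O`. `decode_entities()` turns maximal `B-x (I-x)*` runs into spans; an
orphan `I-x` is promoted to `B-x` rather than dropped (preserving recall;
the promotion count is attached for diagnostics). Surfaces can be
rendered with out-of-vocabulary characters masked as `＊` while offsets
keep indexing the original sentence.

## The evaluation framework

Two entity sets over the same sentences — gold and predicted — are
compared in three steps.

**Pairing** (`pair_entities()`). Candidates are same-sentence pairs with
character overlap. Assignment is one-to-one, greedy in descending surface
similarity, ties broken by smaller gold then predicted start offset.
Surface similarity is

$$\mathrm{similarity}(W_1, W_2) =
  \frac{\max(|W_1|, |W_2|) - \mathrm{LD}(W_1, W_2)}{\max(|W_1|, |W_2|)}$$

with LD the character Levenshtein distance; the masking placeholder `＊`
counts as an ordinary character. When several candidates tie exactly, the
offset tie-break makes the assignment deterministic and
input-order-invariant. Leftover overlapping entities stay unmatched: if
one side extracts two terms where the other extracted one long term, the
extra extraction is counted as its own error, so disagreement is counted
on the larger side.

**Classification** (`classify_matches()`). The decision table crosses
match status with polarity agreement:

| | exact | partial (sim ≥ 0.66) | partial (sim < 0.66) | no overlap |
|---|---|---|---|---|
| polarity agrees | correct (exact) | correct (partial) | error 4 | error 1 / error 2 |
| polarity differs | error 3 | error 3 | error 1 + error 2 | error 1 / error 2 |

"Exact" requires identical (masked) surfaces *and* identical offsets;
requiring only surface equality would let a correct string at the wrong
position count as exact, which the offset-based pairing already
contradicts. The partial band is inclusive at the threshold
(similarity ≥ 0.66) and the default 0.66 sits where, empirically,
extractions start losing the essential head term — at similarity 0.667
(distance 1 in 3) extractions are mostly usable, while by 0.636 and 0.625
most have lost essential content. A below-threshold pair with a polarity
mismatch has neither a usable span nor a usable polarity, so it dissolves
into one missed-gold error and one spurious-prediction error rather than
a single event.

**Rates** (`error_rates()`, `total_extractions()`). The denominator is

$$\mathrm{total} = n_\mathrm{gold} + n_\mathrm{pred}
  - (n_\mathrm{exact} + n_{\mathrm{partial} \ge 0.66})$$

— every extraction by either side counts once, except that a matched pair
collapses to a single countable item; below-threshold pairs deliberately
count twice, which is why category rates can sum past the correct-answer
complement. Rates are percentages of this total. `variation()` compares a
category's rate across two training amounts as after/before × 100, with
the convention that a 0% baseline yields 100% (treated as "no observable
improvement"), including the 0 → 0 case; the convention is applied
rather than returning NaN so that ranking variations across categories
stays total.

Precision, recall and F1 (`prf()`, `evaluate_ner()`) are computed in two
modes — exact only, and including partial matches at or above the
threshold — and a true positive requires correct polarity in both. All
0/0 ratios are defined as 0. Internally everything is full precision;
`round_half_up()` reproduces printed-table rounding (percentages to 1
decimal, F1 to 2, similarity to 3) only at reporting time.

## Learning curves and extrapolation

`make_folds()` shuffles units (sentences by default, whole records
optionally) under a seed and deals them into k folds differing by at most
one unit. Shuffling and counting use the same unit; record-based counting
is available via `unit = "record"`, since sentence-shuffled folds with
record-counted sizes cannot both hold exactly. `step_sizes(n, k)` gives k
near-uniform training amounts ending exactly at n (e.g. 1200, 2401, …,
12004 for ten steps over 12,004 units; uniform rounding is used rather
than any bespoke spacing, since only schedule endpoints are ever
meaningfully compared). For each size s and fold f, `run_curve()` trains
on the first s units of the shuffled non-f folds — a fixed prefix, so
larger training sets contain smaller ones — evaluates on fold f, and
averages fold metrics per size.

`fit_power()` fits $y = a x^b$ by least squares on $(\ln x, \ln y)$;
`predict_f1()` evaluates it and `required_size()` inverts it,
$x = (y/a)^{1/b}$. With a = 0.40 and b = 0.08 the model reaches F1 0.90
near x = 25,000: a shallow exponent means each F1 increment costs a
multiplicative increase in annotation, which is exactly the budgeting
question the inversion answers. Note the inversion is numerically
delicate — the relative error in x is roughly $1/b$ times the error in
the fitted log-prediction — so curve points need tight per-point noise
for a trustworthy answer (see the simulator below).

Epoch-style model selection does not exist here: the CRF trains to
convergence of a convex objective, so the curve reflects data volume
only, not early-stopping choices.

## The synthetic corpus and the error injector

`generate_corpus()` emulates the register the pipeline targets: short
colloquial sentences, each either carrying exactly one symptom mention
rendered from an affirmation or negation template (with optional
time/site/severity modifier) or being an entity-free distractor. The
default configuration mirrors the shape of a year of pharmaceutical care
records: geometric sentences-per-record with mean 3.63 (43,553 sentences
over 12,004 records), mention probability 0.485 per sentence (21,109
mentions over 43,553 sentences), affirmed fraction 0.582 (12,287 affirmed
vs 8,822 denied), plus a small per-sentence character-substitution noise
rate (0.02) for surface variety. The per-sentence mention-count
distribution is a modeling choice — real records occasionally pack
several mentions into one sentence; the generator keeps one per sentence,
which biases the pairing problem easier. The ~120 symptom terms are
invented compound and onomatopoeic strings; no real patient vocabulary is
included or needed.

What passing tests on this corpus *do* show: the matching algebra, the
taxonomy accounting, the fold/step machinery and the CRF implementation
are correct, and the tagger can learn position-local cues. What they do
*not* show: performance on real narratives, whose vocabulary breadth,
annotation ambiguity (conditional expressions, context-dependent
judgments) and long-range polarity cues the generator deliberately does
not model. Real-data F1 claims require real data.

`inject_errors()` is the taxonomy's constructive inverse: each gold
mention is deleted (→ error 1), polarity-flipped (→ error 3),
boundary-corrupted into a target similarity band (→ error 4 below the
threshold, a partial match above it) or kept, and spurious mentions
(→ error 2) are planted in entity-free sentences. Corruption is
constructive, not rejection-sampled: shrink/extend amounts d are
enumerated with their implied similarities (L−d)/L or L/(L+d) and one
inside the band is drawn; a mention too short to reach the band is kept
and logged (`corrupt_skipped`). Two sampling modes exist: `"bernoulli"`
(independent per-mention fates; recovered rates carry binomial noise) and
`"exact"` (`round(p·n)` manipulations of each kind; realized rates are
deterministic up to rounding). The exact mode exists for the
learning-curve simulator: `degraded_trainer(a, b)` deletes a
$1 - \min(a s^b, 0.99)$ fraction of gold mentions and adds as many
spurious ones, so precision = recall = F1 sits on the target power law
with only count-rounding noise — tight enough for the $1/b$-amplified
inversion above to be meaningful.

## Numerical and interface choices

* Offsets 0-based half-open, counted in characters after normalization,
  everywhere.
* Rounding of reported numbers is half-up at printed precision; all
  internal arithmetic is double precision.
* Similarity of two empty strings is an error (undefined denominator),
  not 0 or 1.
* Viterbi and pairing tie-breaks are fixed and documented above, so every
  pipeline output is reproducible bit for bit given seeds; derived seeds
  (fold plan, per-size-per-fold taggers, generator streams) come from a
  deterministic hash of the user seed and a stream tag, and stay below
  2^31.
* Unknown-character masking is an evaluation-time operation
  (`match_config(vocab = model$char_vocab)`): predicted *and* gold
  surfaces are masked with `＊` before similarity, so a character the
  model could not have seen does not count against it twice. Corpus files
  always store literal surfaces.
* Model files are versioned JSON (`sympner-crf-1`); corpora are UTF-8
  JSON Lines; the CLI writes all outputs atomically.

The test suite exercises the heavy machinery at deliberately modest
problem sizes — a ~5,000-mention corpus for taxonomy recovery, a ~7,800
sentence / 5-fold / 8-size curve for power-law recovery, and a
2,000-sentence separable corpus with 2 folds for the end-to-end CRF run —
sizes at which the statistical bounds being asserted (3 binomial SD, 5%
on the inverted size) are already tight.

## Known limitations

* The bundled emission features are character-local; polarity cues more
  than `window_radius` characters away from a span edge are only
  recoverable through transition structure, and genuinely long-range
  cues (clause-final negation scoping over an early mention) need a
  sentence encoder behind `crf_emissions()`.
* The four-way taxonomy is surface-computable by design; finer semantic
  subcategories (why a spurious extraction happened, where the polarity
  cue sat) require human judgment, and the per-pair TSV dump from the
  `eval` subcommand is the supported path to such manual analyses.
* `cohen_kappa()` at the character level understates span-level
  agreement when annotators agree on presence but not extent.
* The generator's linguistic realism is intentionally minimal; it is an
  instrument for validating the machinery, not a stand-in corpus for
  training deployable models.
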