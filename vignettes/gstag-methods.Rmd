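---
title: "Methods: models, parameters, and design choices in gstag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in gstag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter and why they default as they do,
what the synthetic corpus generator does and does not emulate, and the
choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The tagging model

Construct mention tagging is cast as BIO sequence labeling over 21
labels (`O`, `B-c`, `I-c` for the 10 construct codes). The tagger is a
plain linear-chain conditional random field: state weights attach
feature–label pairs, transition weights attach label bigrams, and there
are no transition–observation conjunctions. The CRF is written in this
package rather than wrapped from an external engine, so that inference
and training are testable against independent oracles: the test suite
compares `forward_log_partition()` and `viterbi()` with exhaustive path
enumeration on instances up to 5 positions × 5 labels, and
`crf_gradient()` with central finite differences. All lattice
arithmetic is in log space with max-shifted log-sum-exp; the inner
recursions use a single global shift with an automatic per-column
fallback if a column underflows entirely.

Assumptions worth stating:

* **BIO, not BIOES.** The two-symbol scheme is the convention of the
  CRF sequence-labeling tool lineage this package follows; nothing in
  the task requires the richer scheme.
* **Invalid transitions are not hard-masked.** A decoded `I-c` with no
  preceding `B-c` is possible in principle; `spans_from_bio()` repairs
  it as `B-c`. This matches the behavior of the standard toolchain,
  where such transitions are merely discouraged by learned weights.
* **Ties in Viterbi** break toward the earliest label in the fixed
  alphabet order (`O` first), making decoding fully deterministic.

## Training

The supported trainer is stochastic gradient descent over the
L2-regularized conditional log-likelihood,

* objective: `Σ_i −log P(y_i|x_i) + (λ/2)‖w‖²`, per-sequence updates
  with the regularizer scaled by `1/N`;
* learning-rate schedule `η_t = η₀ / (1 + t/T₀)` with `T₀ = N`
  sequences;
* `η₀` calibrated by a trial phase — one epoch over a sample of up to
  100 sequences for each candidate in `{0.01, 0.05, 0.1, 0.5}`,
  keeping the best sample objective. The calibration grid and trial
  design are this package's own procedure; production CRF toolkits
  calibrate their SGD internally and do not document an exact rule.
* L2 decay via the standard weight-scaling trick, so an update touches
  only the active feature rows;
* seeded epoch shuffling: a fixed seed reproduces the weight
  trajectory bit for bit.

Default hyperparameters follow the historically best-performing point
for this task, λ = 0.2 and 100 epochs, and the default tuning grid
(`default_grid()`) crosses λ ∈ {0.01, 0.05, 0.1, 0.2, 0.5, 1.0} with
{50, 100} epochs. Model selection is always microaveraged
phrase-partial F1 on the validation split; the tuning API does not
accept a test split, ties break toward smaller λ and then fewer
epochs. An L-BFGS trainer over the full-batch objective is provided
(`crf_train_lbfgs()`) as the optional alternative; SGD is the default.

## Features

The Basic family is reconstructed as 6 feature types per window
position (raw form, lowercase form, POS tag, numeric, uppercase,
titlecase) × 3 positions = 18 types. The published description of this
feature set enumerates five attributes per position, which would give
15; the raw token form alongside the lowercase form is the standard
template in CRF toolkits and reconciles the stated count of 18, so
that reconstruction is used here and documented as a choice.

Enhanced token features: the Porter stem (the original 1980 algorithm,
implemented in the package and pinned against canonical reference
vectors, since no stemmer ships with the targeted R runtime);
Is-ICD9-Code membership against an editable code universe with
token normalization that strips surrounding punctuation but preserves
the internal dot; Is-Medical-Unit membership (case-insensitive) against
an editable unit lexicon; and negation/uncertainty/subject attributes.

Global context: the canonical section key of the enclosing note
section, and 10 binary ICD9-Annotation indicators driven by a shipped
295-code construct map. The map's per-construct counts
(2, 58, 45, 15, 26, 35, 14, 14, 55, 31) are pinned by tests; its
membership is assembled from the standard diagnostic code families for
each syndrome (fall E-codes, 290.x/331.x dementias, 707.x pressure
ulcers, …) because the original curated list is not publicly
deposited — the file is editable configuration, clearly marked a
synthetic stand-in. `ICD9-Annotation-Post` applies the same map at
decoding time, overwriting a mapped token's label with `B-c` (or `I-c`
when the previous token already carries `c`); operating on labels
before span extraction lets rescued code tokens merge naturally into
adjacent spans, and the operation is idempotent.

## Preprocessing stand-ins

Clinical pipelines usually delegate section/sentence segmentation,
tokenization, POS tagging and assertion attributes to a heavyweight
external system. Here each step is a small deterministic rule
component with the same output contract, and the POS tagger and
attribute detector are pluggable function arguments, so an adapter to
an external tool could be swapped in without touching the rest of the
pipeline:

* **Sections**: line-anchored, case-insensitive header matching from an
  editable lexicon (the two headers most characteristic of this note
  genre plus common EHR headers); sections tile the note, with
  unheadered text in a section named `other`.
* **Sentences**: punctuation splitting with guards for clinical
  abbreviations (`Dr.`, `pt.`, `Dx.`) and for periods inside decimals
  and ICD9-shaped codes (`250.00` never splits).
* **Tokens**: whitespace/punctuation splitting that keeps dotted
  numbers (`707.0`, `V60.4`), ordinary decimals and slash-joined
  alphanumerics (`r/o`) whole.
* **POS**: a lexicon + suffix rule tagger over the coarse universal
  tagset. The CRF needs only a deterministic categorical feature, not
  linguistic accuracy, so the contract is determinism and alignment.
* **Entity attributes**: forward-scope triggers in the NegEx tradition.
  The scope window is **W = 5 tokens**, the NegEx-style default, ending
  early at `but`, `.` or `,`; scopes never cross sentences. No
  backward scopes and no dependency parsing — a deliberate non-goal.

## The synthetic corpus generator

`synth_config()` defaults are the study conditions the generator
emulates, chosen once: 185 patients; per-construct patient prevalence
from the annotated training distribution of the emulated corpus (e.g.
walking difficulty 0.66, malnutrition 0.09); mean mentions per positive
patient (e.g. lack of social support 15.23) and mean mention length in
tokens (2.04–4.03) per construct; ~45.6 notes per patient with enough
neutral filler that construct tokens are ≈ 0.76% of all tokens; the
encounter-type mix of a primary-care population (phone calls 37.8%,
office visits 30.2%, refills 11.6%, letters 3.2%, notations 2.6%,
remainder other) as metadata realism. Mention and note counts are
drawn from shifted Poisson distributions matched to the configured
means — only means are known for the emulated corpus, and the shifted
Poisson is the simplest count model guaranteeing every positive
patient at least one mention. Filler is templated text, not a language
model, for determinism and license cleanliness. Note length (filler
sentences per note) is a free parameter of the emulated setting; its
default (44) is set so the construct-token rate lands near the target
sparsity.

Each construct's phrases are built from a 12-word construct-specific
pool, disjoint across constructs and from the filler/template
vocabulary, so generated corpora are lexically separable — the
regime in which a correct implementation must score highly, making
end-to-end recovery a meaningful test. Realistic hardness is injected
explicitly and controllably:

* **negation/family decoys** (defaults 0.15 / 0.10 per positive
  construct): trigger-scoped sentences using construct cue words that
  must *not* be annotated;
* **intentional-weight-loss decoys** (`weight_loss_ambiguity()`):
  unannotated sentences sharing surface tokens with weight-loss
  mentions, the hardest real-world confusion for this task;
* **embedded ICD9 codes** (default 0.3 per positive patient–construct):
  an annotated single-code sentence, exercising the code features, the
  post-processing rule and the rule baseline;
* **vocabulary shift** (`vocabulary_shift()`): the phrase pools are
  split so main-lexicon variants use the first 6 words and held-out
  variants the last 6, with disjoint Porter stems; a holdout fraction
  replaces that share of the test lexicon with held-out variants,
  inducing genuine word-level OOV that neither the word-identity nor
  the stem feature can bridge. Main and held-out lexicons have equal
  length so paired shifted/unshifted runs consume identical random
  streams and differ only in the shifted constructs' phrases.

What the generator does **not** emulate: real lexical diversity and
spelling noise, annotator boundary inconsistency, discourse structure,
temporal patterns, or inter-note redundancy beyond mention counts.
Passing end-to-end tests on this corpus therefore demonstrates that
the pipeline's machinery is correct and that the qualitative OOV
mechanism reproduces — not that real-corpus F1 levels are attainable;
absolute performance on real clinical text is explicitly out of scope.

## Evaluation semantics

* Phrase matching is **one-to-one greedy**: predictions left to right,
  each claiming the leftmost unmatched overlapping gold span (overlap
  = ≥ 1 character, same construct; exact = identical boundaries). The
  published task description does not define multiplicity; greedy is
  the documented convention here, and because gold spans never overlap
  each other, greedy attains the optimal matching — verified in the
  suite against a brute-force matcher on 500 random instances.
* Note/patient levels compare construct *sets* per note / per patient
  (a construct predicted anywhere in any of a patient's notes counts
  once). Whether the original evaluation counted note-level FPs in
  notes of unaffected patients is unknowable from its description;
  set-comparison semantics is this package's contract.
* Macroaverage = mean of per-construct P and of per-construct R, with
  macro-F1 the harmonic mean of the two — not the mean of per-construct
  F1s. This choice is verified against the published benchmark's own
  arithmetic (macro-P 0.496 and macro-R 0.327 yield the printed 0.394;
  the mean of F1s would give 0.378).
* McNemar's test uses the continuity-corrected statistic
  `(|b−c|−1)²/(b+c)` with a χ²(1) p-value, an exact binomial fallback
  when `b+c < 25`, and p = 1 when `b+c = 0`. The pairing unit is the
  gold mention under phrase-partial matching (correct iff matched);
  the original report does not state its unit, so its p-values are not
  reproduction targets.

## Error analysis

Construct-specific bigram language models use add-k smoothing with
**k = 1** by default over the event vocabulary of training types plus
unknown and end symbols; sequences are padded with a start symbol and
the transition into the end symbol counts toward perplexity's `N`.
Perplexity is computed in log base 2 (any base gives the same value).
The smoothing scheme, padding and statistics of the original
perplexity analysis are unstated, so its printed per-construct values
serve only as qualitative ordering intuition, never as reproduction
targets. OOV rate is the fraction of test-mention token instances
whose type never occurs in the same construct's training mentions.
Gold-span errors split into *missed* (no overlapping prediction) and
*confused* (overlapped by a wrong-construct prediction); spurious
predictions are counted once each.

## Numerical and degenerate-input choices

* Zero denominators in P/R/F1 yield 0, not NaN.
* Annotation offsets are 0-based half-open; gold span boundaries that
  fall inside a token are snapped outward to token boundaries (every
  snap logged) — annotators of messy text mark sub-token boundaries;
  spans crossing a sentence boundary are truncated with a warning.
* Overlapping gold spans are rejected at load (one construct per
  phrase is the annotation contract); decoder output needs no such
  check because BIO decoding cannot produce overlaps.
* `sample()`-based code paths all run under locally scoped seeds;
  derived stream seeds stay below 2³¹.

## Problem sizes

The shipped experiments are deliberately desk-scale. The end-to-end
recovery benchmark (`synthetic_benchmark()`) uses 100 patients split
60/20/20, ~3 notes per patient, 5 filler sentences per note,
per-construct mention means capped at 6, a 2-point tuning grid
(λ ∈ {0.1, 0.2}, 20 epochs), and full features; the corpus-statistics
check uses the full 185-patient default configuration (≈ 2.8M tokens)
but no training. These sizes are the package's chosen experimental
conditions and are stated here so results are interpreted at the scale
they were computed.

## Known limitations

* The preprocessing components are deliberate rule-based stand-ins;
  their linguistic quality is below production clinical NLP tools.
* The ICD9 construct map pins counts, not the original membership.
* No embeddings, no deep models, no semi-Markov or higher-order CRFs,
  no ICD10 — out of scope by design.
* Absolute metric levels on real EHR text are not claimed anywhere in
  this package; only arithmetic identities, oracle equivalences, and
  qualitative mechanisms (sparsity, OOV-driven recall loss, missed-
  vs-confused error anatomy) are asserted and tested.
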