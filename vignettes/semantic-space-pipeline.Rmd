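---
title: "Measuring semantic space in spontaneous speech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring semantic space in spontaneous speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semspace)
```

## The measures and what they assume

Speech elicited by a picture-description task is scored along two semantic
tracks and three complementary axes.

**Conceptual track.** Transcripts are lowercased, punctuation-only tokens
dropped, and stopwords removed (frozen per-language lists shipped with the
package, so results cannot drift with an external resource). The remaining
content words receive *static* word embeddings — one fixed vector per word
type. Over the embedded transcript \(U = (e_1, \dots, e_n)\) we compute

* local similarity, the mean cosine over consecutive pairs:
  \(\mathrm{LSim} = \frac{1}{n-1}\sum_{i=1}^{n-1}\cos(e_i, e_{i+1})\);
* global similarity, the mean cosine over all unordered pairs:
  \(\mathrm{GSim} = \frac{2}{n(n-1)}\sum_{i<j}\cos(e_i, e_j)\).

A *contracted* conceptual space — concepts crowded together, as in semantic
memory degradation — raises GSim. Self-pairs are excluded and each
unordered pair counted once, matching the \(2/(n(n-1))\) normalizer.

**Referential track.** The full word sequence (nothing removed — the words
jointly form the context) is segmented into subwords by greedy longest
match against a vocabulary, and embedded *contextually*: a token's vector
depends on its neighbours, so the same word in a new context gets a new
vector. The same LSim/GSim formulas apply to the subword sequence.

**Perplexity.** For token log-probabilities under an autoregressive model,
cross-entropy is \(H = -\frac{1}{n}\sum_i \log_2 p(t_i \mid t_{1:i-1})\)
bits and perplexity \(\mathrm{PPL} = 2^{H}\): the effective number of
equally likely outcomes (a fair die: \(H = \log_2 6 \approx 2.585\) bits,
PPL exactly 6). The first token of a sequence has no preceding context and
is excluded, so \(n\) counts predicted tokens — the standard autoregressive
convention. Entries may arrive in natural log; they are converted once to
bits, and the implementation asserts internally that
\(e^{H_\text{nats}} = 2^{H_\text{bits}}\) to within 1e-10 relative.

**Picture-speech alignment.** Each sentence and the stimulus picture are
encoded into a shared space; the per-subject score is the mean cosine
between sentence vectors and the picture vector. The picture acts as the
external anchor of the discourse, replacing artificial topic vectors.

**Syntactic complexity.** Every sentence carries a dependency parse; for
each head–dependent arc whose two endpoints are both non-punctuation we
take the absolute difference of their 1-based linear positions, and the
averaged dependency distance (ADD) is the mean over all arcs pooled across
sentences. In *Mary ate the juicy red sweet apple*, the arc from *ate*
(position 2) to *apple* (position 7) has distance 5 — counted through the
intervening determiner and adjectives. Arcs touching punctuation are
skipped but remaining words are **not** renumbered; a `words_between`
variant (distance minus one) is available but not default, because the
position-difference reading is the one the worked example fixes.

## Provider contracts and fixtures

Four provider contracts (static embedder, contextual embedder,
autoregressive scorer, bimodal encoder) decouple the metrics from any
particular model. The shipped fixtures are pure functions of their inputs
and a seed:

* static: each word hashes to a pseudo-random unit vector — identical words
  always embed identically;
* contextual: a token's base vector is blended with its neighbours' (weight
  0.5) and renormalized, so position matters; sequences beyond the context
  limit are encoded in 50%-overlapping windows and each token keeps the
  vector from the window where it is most central, preserving one vector
  per token;
* autoregressive: per-token surprisal is drawn from a Gamma distribution
  with shape 4 and mean equal to the target entropy, guaranteeing
  non-positive log-probabilities and a controlled mean cross-entropy;
* bimodal: sentence vector = `normalize(a * image + (1 - a) * noise)` with
  alignment level `a` in \([0, 1]\).

Boundary/special tokens never enter the similarity or perplexity sums.
Providers return raw vectors; cosine handles normalization, clips to
\([-1, 1]\) against rounding overshoot, and short-circuits identical
vectors to exactly 1.

## The synthetic cohort generator

Real dementia speech corpora are access-restricted, so the statistical
stage is exercised on synthetic cohorts with known ground truth. The
defaults emulate the descriptive structure of the published English (143
NC / 148 pAD) and Greek (28 / 26) picture-description datasets: age
\(\approx\) 66/69 (en) and 67/73 (el), education 14/12 and 12/9.5 years,
MMSE 29/17.8 and 28.8/21 (integer, truncated to \([0, 30]\)), female
proportion \(\approx\) 0.65/0.71, and transcripts of roughly 30–60 words.

Group effects enter through five knobs, each with a monotone, tested link
to its measure:

| knob | default (NC, pAD) | controls |
|---|---|---|
| concentration `kappa` | 2.00, 2.16 | embedding cloud tightness → GSim/LSim ↑ |
| `entropy_bits` | 5.0, 4.6 | mean surprisal → PPL (≈ \(2^h\)) |
| `alignment` | 0.45, 0.38 | picture-speech cosine |
| `arc_mean` | 2.3, 2.0 | mean dependency arc length → ADD |
| `lexicon_size` | 350, 220 | Zipf-weighted vocabulary → TTR ↓ in pAD |

Embedding clouds are drawn as `normalize(centroid + noise / kappa_subject)`
with isotropic Gaussian noise — a pragmatic stand-in for a von Mises–Fisher
draw; only the monotone link between concentration and expected pairwise
cosine is relied upon, never the exact density. Each subject's
concentration, entropy and alignment get mild log-normal/Gaussian
between-subject jitter (`kappa_cv = 0.12`, `entropy_subject_sd = 0.15`,
`alignment_subject_sd = 0.05`), which creates realistic between-subject
variance in the measures. The concentration pair (2.00, 2.16) was chosen so
the injected standardized group effect on static-track GSim is
approximately 0.5 — a moderate effect of the size the recovery analyses
are designed around — and then frozen. The entropy pair makes *raw*
perplexity slightly lower in patients (driven down alongside lexical
diversity), mirroring the counter-intuitive raw direction reported for
real cohorts.

One master seed fans out into per-subject substreams via hashed keys, so
cohorts are bitwise reproducible and independent of generation order.
Generated cohorts can be written to disk (metadata CSV, per-subject UTF-8
transcripts, CoNLL-U parses) and read back through the same I/O path real
data would use.

What the generator does **not** emulate: linguistically coherent text, the
vocabulary of real picture descriptions, topic structure, disfluencies,
or any coupling between MMSE and the semantic knobs within a group.
Passing recovery tests therefore demonstrate that the pipeline detects the
effects it is pointed at under realistic sample sizes and noise — not that
the fixtures behave like a real language model.

## The statistical stage

**Missing data.** Missing education or MMSE is imputed with the mean of
the non-missing values among NC subjects of the same language (the donor
pool that keeps patient pathology out of the imputation); the rule is
idempotent and errors hard when a language has no NC donors. Models use
row-wise deletion per measure beyond that.

**Covariate screening.** Candidates (age, sex, education, word TTR, word
count) are screened against each measure by Spearman partial correlation —
rank-transform everything, project the ranks of candidate and measure on
the rank covariates (language and group, pooled across both datasets),
correlate the residuals, t-approximation with \(n - k - 2\) df. All
measure × candidate p-values are FDR-adjusted jointly
(Benjamini–Hochberg) and candidates with \(q < 0.05\) enter that measure's
models. No installed R package provides partial Spearman correlation, so
it is implemented directly and cross-checked in the tests against an
explicit projection-matrix oracle.

**Group and MMSE GLMs.** Per dataset and measure:
`measure ~ group + covariates` (and, within patients,
`measure ~ mmse + covariates`). Every model is first fit
Gaussian/identity; the deviance goodness-of-fit test (residual deviance vs
\(\chi^2\) on the residual df) then gates the family: rejection at
\(\alpha = 0.05\) with a strictly positive response triggers a Gamma/log
refit. On unit-scale similarity outcomes the Gaussian fit passes; on
positively skewed perplexity it fails and the Gamma/log model takes over —
exactly the division of labour observed in practice. \(\alpha = 0.05\)
follows the general significance convention since no other level is
stated anywhere. Inference is Wald throughout (z, normal p, normal-quantile
95% CI) for every family, matching the GLM convention of the Python
statistical stack this mirrors. Perplexity models always receive subword
TTR as an additional covariate: the lexical diversity of subwords strongly
drives raw perplexity, and the adjusted group effect is the quantity of
interest. Group is coded pAD = 1, sex female = 1, language el = 1, MMSE
raw; group/MMSE p-values are FDR-corrected across measures within each
dataset.

**Replication.** An effect from the larger English dataset is *replicated*
in the smaller Greek dataset when the coefficients share a sign and the
English coefficient lies inside the Greek 95% CI. A coefficient of exactly
zero matches either sign (non-strict; unreachable with continuous data).
All four sign × containment combinations are enumerated in the tests.

## Numerical choices and degenerate inputs

* Transcripts with fewer than two content words (or subwords) yield missing
  similarity/perplexity values, not errors: the statistical stage handles
  incomplete rows, and a single bad transcript must never abort a cohort.
* Constant predictors, singular designs and non-positive responses under
  Gamma/log are hard errors naming the offending terms; batch drivers
  record them per measure and continue.
* TTR of an empty token list is missing; of any list it is
  order-invariant.
* The deviance gate's \(\chi^2\) reference makes the Gaussian test
  scale-dependent; that scale dependence is what lets it separate
  unit-interval similarity outcomes from unbounded skewed perplexity, and
  is documented rather than hidden.
* Both TTR variants (over all words and over content words) are computed
  and labelled explicitly, since either convention is defensible for the
  word-level figure.

## Problem sizes used in the checks

Oracle-equivalence suites run on 1000 random fixtures of up to 12 tokens
(similarities), p-vectors up to length 50 (FDR), and 8–30-point designs
(GLM vs normal equations, partial correlation vs projection oracle).
Recovery analyses use 100 seed-controlled cohorts of 300 + 300 subjects at
the default effect sizes, and 100 null cohorts of 80 + 80 with all group
knobs equalized; monotonicity grids use five knob values with 100 subjects
per point. These sizes give stable Monte-Carlo margins while keeping a
full check run comfortably interactive.

## Known limitations

* Fixture embeddings are hash-seeded noise with controlled geometry; they
  carry no lexical semantics, so absolute similarity levels are not
  comparable to real embedding models — only contrasts and recoveries are
  meaningful.
* The generator produces dependency trees by attaching each word a
  geometric distance back; these are valid trees with controlled mean arc
  length but not linguistically plausible structures.
* MMSE is generated independently of the semantic knobs within each group,
  so within-group MMSE slopes are null by construction; MMSE-recovery
  tests inject their own slopes directly.
* The crosslingual verdict inherits the asymmetry of its definition: with
  a small replication cohort, wide CIs make containment easy — sign
  agreement carries most of the information.
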