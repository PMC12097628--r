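# semspace

Semantic impairment is one of the earliest and most measurable linguistic
signatures of Alzheimer's disease. `semspace` scores spontaneous speech
from picture-description tasks along the axes where that impairment shows,
and runs the inferential pipeline that turns per-subject scores into group
findings — for researchers in clinical NLP and speech-based digital
biomarkers who need the whole chain testable offline.

Per transcript it computes:

- **LSim / GSim** — local and global semantic similarity: the mean cosine
  over consecutive (`LSim = 1/(n-1) Σ cos(e_i, e_{i+1})`) and all unordered
  (`GSim = 2/(n(n-1)) Σ_{i<j} cos(e_i, e_j)`) token-embedding pairs, on a
  *conceptual* track (static embeddings over content words) and a
  *referential* track (contextual embeddings over the full subword
  sequence). A contracted semantic space raises GSim.
- **PPL** — perplexity: `2^H` with cross-entropy
  `H = -(1/n) Σ log2 p(t_i | t_1..i-1)` bits under an autoregressive model;
  the effective number of equally likely outcomes (a fair die: H ≈ 2.585
  bits, PPL = 6).
- **Picture-speech alignment** — mean cosine between each sentence and the
  stimulus picture in a shared vision-language space.
- **ADD** — averaged dependency distance: mean absolute position difference
  across all non-punctuation head–dependent arcs, a formal
  syntactic-complexity index.

The statistical stage screens covariates by Spearman partial correlation
with joint FDR, fits `measure ~ group + covariates` GLMs whose family is
gated by a deviance goodness-of-fit test (Gaussian/identity normally;
Gamma/log for positively skewed perplexity), regresses measures on MMSE
within patients, corrects within dataset by Benjamini–Hochberg, and issues
a crosslingual replication verdict (same sign + English coefficient inside
the Greek 95% CI).

Embedding backends are pluggable provider contracts; deterministic fixtures
and a synthetic cohort generator with controllable group effects
(concentration, entropy, alignment, arc length, lexical diversity) make
every stage runnable and testable with no model downloads and no restricted
data.

## Worked example

```r
library(semspace)

# simulate the two-language study at its default conditions
cohort <- generate_cohort(cohort_spec("en", seed = 42))
feats  <- cohort_features(cohort)

res <- run_group_analysis(feats)
tab <- glm_results_table(res)
tab[tab$term %in% "group", c("measure", "family", "estimate", "z", "p", "q")]
```

With the English defaults (143 NC / 148 pAD) this prints:

```
     measure            family estimate      z        p        q
     ft_lsim gaussian_identity   0.0241   5.23 1.73e-07 2.02e-07
     ft_gsim gaussian_identity   0.0221   5.51 3.62e-08 6.34e-08
   bert_lsim gaussian_identity   0.0207   5.45 4.93e-08 6.90e-08
   bert_gsim gaussian_identity   0.0206   5.98 2.18e-09 5.08e-09
         ppl         gamma_log  -0.2574  -3.44 5.79e-04 5.79e-04
 bimodal_sim gaussian_identity  -0.1027 -10.57 4.14e-26 2.90e-25
         add gaussian_identity  -0.1512  -8.64 5.83e-18 2.04e-17
```

Read: both similarity tracks are higher in the patient group (the injected
semantic-space contraction, recovered with FDR-significant positive group
coefficients), picture-speech alignment and dependency distance are lower,
and perplexity — the one positively skewed outcome — is the model the
goodness-of-fit gate refits with Gamma/log. The worked-example fixtures are
available directly:

```r
ex <- generate_worked_examples()
perplexity(ex$die_logprobs)   # $cross_entropy 2.585 bits, $ppl 6
arc_distances(ex$parse)       # contains 5: the verb-object arc of
                              # "Mary ate the juicy red sweet apple"
```

The full narrative workflow lives under `analysis/` as numbered drivers
(`01_simulate.R` … `05_replication.R`); each writes its tables under
`results/` and prints what it found. `run_pipeline(pipeline_config(...))`
runs the same sequence end to end from one configuration.

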