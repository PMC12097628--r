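Package: semspace
Title: Semantic-Space Analysis of Spontaneous Speech in Neurodegeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes conceptual and referential semantic-space measures from
    picture-description transcripts (local and global embedding similarity,
    language-model perplexity, image-speech alignment, averaged dependency
    distance) and runs the associated inferential pipeline: covariate screening
    by Spearman partial correlation with false-discovery-rate control,
    generalized linear model group comparisons with a deviance goodness-of-fit
    family gate, MMSE regressions within the patient group, and a crosslingual
    replication verdict. Ships deterministic fixture embedding providers and a
    synthetic cohort generator with controllable group effects so the whole
    pipeline is testable offline against recoverable ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
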