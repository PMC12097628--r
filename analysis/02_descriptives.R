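#!/usr/bin/env Rscript
# Group descriptives per dataset: demographics plus text measures, with
# Mann-Whitney / chi-square tests and their effect sizes (rank-biserial,
# contingency coefficient).

library(semspace)

desc <- do.call(rbind, lapply(c("en", "el"), function(lg) {
  f <- read.csv(sprintf("results/features_%s.csv", lg))
  cbind(dataset = lg,
        describe_groups(f, f[c("word_count", "subword_count",
                               "word_ttr", "subword_ttr")]))
}))
write.csv(desc, "results/descriptives.csv", row.names = FALSE, na = "")
print(desc, digits = 3)
cat("\nNote: MMSE separates the groups sharply by construction;",
    "word counts and TTR differ modestly, as in real picture-description cohorts.\n")
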