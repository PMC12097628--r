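# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# mean cosine over consecutive pairs, plain double loop
oracle_lsim <- function(m) {
  cosv <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  n <- nrow(m)
  mean(sapply(seq_len(n - 1), function(i) cosv(m[i, ], m[i + 1, ])))
}

# mean cosine over all unordered pairs, O(n^2) double loop
oracle_gsim <- function(m) {
  cosv <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  n <- nrow(m)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) s <- s + cosv(m[i, ], m[j, ])
  s / (n * (n - 1) / 2)
}

# Benjamini-Hochberg step-up applied literally to sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# rank-biserial via exhaustive pair comparison: (#x>y - #x<y) / (n1*n2)
oracle_rank_biserial <- function(x, y) {
  fav <- 0; unfav <- 0
  for (a in x) for (b in y) {
    if (a > b) fav <- fav + 1
    if (a < b) unfav <- unfav + 1
  }
  (fav - unfav) / (length(x) * length(y))
}

# gaussian-identity GLM coefficients via the normal equations
oracle_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# partial Spearman via explicit projection matrices on ranks
oracle_partial_spearman <- function(x, y, C) {
  rx <- rank(x); ry <- rank(y)
  Z <- cbind(1, apply(as.matrix(C), 2, rank))
  P <- diag(length(x)) - Z %*% solve(t(Z) %*% Z) %*% t(Z)
  ex <- P %*% rx; ey <- P %*% ry
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# minimal stand-in regression_result for verdict-logic tests
make_result <- function(estimate, ci_low = NA, ci_high = NA,
                        term = "group", measure = "m") {
  structure(list(
    measure = measure, family = "gaussian_identity",
    terms = data.frame(term = term, estimate = estimate, se = 0.1,
                       z = estimate / 0.1, p = 0.05,
                       ci_low = ci_low, ci_high = ci_high),
    gof_p = 0.5, n = 100, predictor = term),
    class = "regression_result")
}

random_sequence <- function(n, d) {
  embedded_sequence(matrix(rnorm(n * d), n, d), paste0("t", seq_len(n)))
}

# small on-disk cohort for I/O tests
write_tiny_cohort <- function(dir, rows, transcripts) {
  dir.create(file.path(dir, "tx"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, file.path(dir, "meta.csv"), row.names = FALSE,
                   na = "")
  for (id in names(transcripts))
    writeLines(transcripts[[id]], file.path(dir, "tx", paste0(id, ".txt")))
  list(meta = file.path(dir, "meta.csv"), tx = file.path(dir, "tx"))
}
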