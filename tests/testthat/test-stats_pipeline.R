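test_that("BH q-values equal the step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.5, 10)), rep(0.5, 10))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("partial Spearman matches the projection oracle and handles edge cases", {
  set.seed(17)
  # 12-row fixture against the explicit projection-matrix oracle
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12); C <- matrix(rnorm(24), 12, 2)
    got <- partial_spearman(x, y, C)
    expect_equal(got$rho, oracle_partial_spearman(x, y, C),
                 tolerance = 1e-10)
  }

  # perfect monotone relation without covariates
  x <- sort(rnorm(20)); y <- exp(x)
  expect_equal(partial_spearman(x, y)$rho, 1)

  # y independent of x, covariate duplicates x: null rho on average
  rhos <- replicate(1000, {
    x <- rnorm(15); y <- rnorm(15)
    partial_spearman(x, y, cbind(x))$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)

  # constant input after ranking -> missing-marker
  expect_true(is.na(partial_spearman(rep(1, 10), rnorm(10))$rho))
  expect_error(partial_spearman(rnorm(3), rnorm(3), matrix(rnorm(6), 3)),
               "covariates")
})

test_that("gaussian GLM equals the normal-equations solution", {
  set.seed(19)
  for (i in 1:10) {
    n <- 8
    df <- data.frame(y = rnorm(n), group = rep(0:1, 4), a = rnorm(n))
    r <- fit_glm(df, "y", "group", "a", family = "gaussian")
    X <- cbind(1, df$group, df$a)
    beta <- oracle_normal_equations(X, df$y)
    expect_equal(r$terms$estimate, unname(beta), tolerance = 1e-10)
  }

  # exact noiseless recovery
  df <- data.frame(group = rep(0:1, 10))
  df$y <- 2 + 3 * df$group
  r <- fit_glm(df, "y", "group", family = "gaussian")
  expect_equal(r$terms$estimate[r$terms$term == "group"], 3,
               tolerance = 1e-8)
})

test_that("gamma-log GLM inverts a noiseless exponential relationship", {
  set.seed(23)
  df <- data.frame(x = runif(40, -1, 1))
  df$y <- exp(1 + 0.5 * df$x)
  # perfect fit drives the dispersion to 0; the AIC NaN warning is expected
  r <- suppressWarnings(fit_glm(df, "y", "x", family = "gamma_log"))
  expect_equal(r$terms$estimate, c(1, 0.5), tolerance = 1e-6)
  expect_equal(r$family, "gamma_log")

  df$y[1] <- -1
  expect_error(fit_glm(df, "y", "x", family = "gamma_log"), "positive")
})

test_that("deviance gate keeps unit-scale outcomes gaussian and sends skewed PPL to gamma", {
  set.seed(29)
  n <- 200
  df <- data.frame(group = rep(0:1, n / 2))
  df$gsim <- 0.3 + 0.02 * df$group + rnorm(n, 0, 0.05)
  df$ppl <- exp(rnorm(n, log(30), 0.4))
  r1 <- fit_glm(df, "gsim", "group", family = "auto")
  expect_equal(r1$family, "gaussian_identity")
  r2 <- fit_glm(df, "ppl", "group", family = "auto")
  expect_equal(r2$family, "gamma_log")
  # CI always contains the estimate
  expect_true(all(r1$terms$ci_low <= r1$terms$estimate &
                    r1$terms$estimate <= r1$terms$ci_high))
})

test_that("degenerate and collinear designs fail with informative errors", {
  df <- data.frame(y = rnorm(20), group = 1, a = rnorm(20))
  expect_error(fit_glm(df, "y", "group", "a"), "constant")
  df2 <- data.frame(y = rnorm(20), group = rep(0:1, 10))
  df2$a <- rnorm(20); df2$b <- df2$a
  expect_error(fit_glm(df2, "y", "group", c("a", "b")), "collinear|b")
})

test_that("covariate screening selects strong correlates and little noise", {
  set.seed(31)
  n <- 200
  feats <- data.frame(
    group = rep(c("NC", "pAD"), n / 2),
    language = rep(c("en", "el"), each = n / 2),
    age = rnorm(n, 70, 6), sex = sample(c("female", "male"), n, TRUE),
    education = rnorm(n, 12, 3),
    word_count = round(runif(n, 20, 80)))
  feats$word_ttr <- runif(n, 0.6, 0.95)
  # engineer a strong candidate-measure association (rho ~ 0.9)
  feats$ft_gsim <- scale(feats$word_ttr)[, 1] +
    rnorm(n, 0, 0.45)
  feats$ppl <- exp(rnorm(n, 3, 0.3))
  sc <- screen_covariates(feats, measures = c("ft_gsim", "ppl"))
  expect_true("word_ttr" %in% sc$selected$ft_gsim)
  expect_true(all(sc$table$q >= sc$table$p - 1e-12, na.rm = TRUE))

  # empty selection path: no covariate survives, GLM runs with group only
  res <- run_group_analysis(feats, covariate_sets = list(),
                            measures = "ft_gsim")
  expect_s3_class(res$ft_gsim, "regression_result")
  expect_setequal(res$ft_gsim$terms$term, c("(Intercept)", "group"))
})

test_that("screening controls false selections under the global null", {
  set.seed(37)
  n <- 50
  any_selected <- replicate(100, {
    feats <- data.frame(
      group = rep(c("NC", "pAD"), n / 2),
      language = rep(c("en", "el"), each = n / 2),
      age = rnorm(n), sex = sample(c("female", "male"), n, TRUE),
      education = rnorm(n), word_ttr = runif(n), word_count = runif(n))
    for (m in c("m1", "m2", "m3", "m4")) feats[[m]] <- rnorm(n)
    sc <- screen_covariates(feats, measures = c("m1", "m2", "m3", "m4"))
    any(lengths(sc$selected) > 0)
  })
  # BH under the global null: P(any discovery) <= alpha; allow MC slack
  expect_lte(mean(any_selected), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("MMSE models recover an injected negative slope; CIs shrink with n", {
  set.seed(41)
  gen <- function(n) {
    df <- data.frame(group = "pAD", language = "en",
                     mmse = round(runif(n, 5, 28)),
                     subword_ttr = runif(n, 0.4, 0.6))
    df$ft_gsim <- 0.6 - 0.004 * df$mmse + rnorm(n, 0, 0.02)
    df
  }
  big <- run_mmse_analysis(gen(300), covariate_sets = list(),
                           measures = "ft_gsim")
  expect_lt(big$ft_gsim$terms$estimate[big$ft_gsim$terms$term == "mmse"], 0)
  expect_lt(big$ft_gsim$terms$q[big$ft_gsim$terms$term == "mmse"], 0.05)

  small <- run_mmse_analysis(gen(10), covariate_sets = list(),
                             measures = "ft_gsim")
  wider <- function(r) diff(unlist(
    r$ft_gsim$terms[r$ft_gsim$terms$term == "mmse", c("ci_low", "ci_high")]))
  expect_gt(wider(small), wider(big))

  # constant MMSE: every model flagged as an error, batch not aborted
  const <- gen(50); const$mmse <- 20
  res <- run_mmse_analysis(const, covariate_sets = list(),
                           measures = c("ft_gsim"))
  expect_s3_class(res$ft_gsim, "regression_error")
})

test_that("per-measure failures do not abort the batch", {
  set.seed(43)
  n <- 60
  feats <- data.frame(group = rep(c("NC", "pAD"), n / 2), language = "en",
                      subword_ttr = runif(n, 0.4, 0.6))
  feats$ft_gsim <- 0.3 + rnorm(n, 0, 0.05)
  feats$add <- NA_real_                    # all-missing measure
  res <- run_group_analysis(feats, covariate_sets = list(),
                            measures = c("ft_gsim", "add"))
  expect_s3_class(res$ft_gsim, "regression_result")
  expect_s3_class(res$add, "regression_error")
  tab <- glm_results_table(res)
  expect_true("add" %in% tab$measure[!is.na(tab$error)])
})

test_that("replication verdict enumerates the full sign/containment truth table", {
  en <- make_result(0.5)
  verdict <- function(gr_est, lo, hi)
    assess_replication(en, make_result(gr_est, lo, hi), "group")

  v1 <- verdict(0.3, 0.1, 0.9)     # same sign, contained -> replicated
  expect_true(v1$sign_match && v1$ci_containment && v1$replicated)

  v2 <- verdict(-0.2, -0.6, 0.7)   # sign mismatch despite containment
  expect_false(v2$sign_match); expect_true(v2$ci_containment)
  expect_false(v2$replicated)

  v3 <- verdict(0.1, 0.05, 0.15)   # same sign, containment fails
  expect_true(v3$sign_match); expect_false(v3$ci_containment)
  expect_false(v3$replicated)

  v4 <- verdict(-0.2, -0.3, -0.1)  # neither condition holds
  expect_false(v4$sign_match); expect_false(v4$ci_containment)
  expect_false(v4$replicated)

  expect_error(assess_replication(en, make_result(0.3, 0, 1, term = "mmse")),
               "absent")
})
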