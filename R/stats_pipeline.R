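# Inferential stage: covariate screening by Spearman partial correlation
# with FDR control, GLM group comparisons with a deviance goodness-of-fit
# family gate, MMSE regressions within the patient group, and the
# crosslingual replication verdict.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: sort ascending, `q(i) = min_{j >= i} p(j) * m / j`
#' clipped at 1, returned in input order. Delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return q-values in input order.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Spearman partial correlation
#'
#' Rank-transforms `x`, `y` and every covariate column, then correlates the
#' residuals of the rank variables after linear projection on the rank
#' covariates (with intercept). The p-value uses the t-approximation with
#' `n - k - 2` degrees of freedom, `k` the number of covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data.frame of covariates;
#'   constant columns are dropped.
#' @return List with `rho`, `p`, `n`, `df`; `rho` is `NA` if `x` or `y` is
#'   constant after ranking (missing-marker, not an error).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(cm)) keep <- keep & stats::complete.cases(cm)
  x <- x[keep]; y <- y[keep]
  if (!is.null(cm)) {
    cm <- cm[keep, , drop = FALSE]
    cm <- cm[, apply(cm, 2, function(col) length(unique(col)) > 1),
             drop = FALSE]
    if (ncol(cm) == 0) cm <- NULL
  }
  n <- length(x)
  k <- if (is.null(cm)) 0L else ncol(cm)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- rank(x); ry <- rank(y)
  if (length(unique(rx)) < 2 || length(unique(ry)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n, df = n - k - 2))
  if (!is.null(cm)) {
    rc <- apply(cm, 2, rank)
    qx <- stats::lm.fit(cbind(1, rc), rx)$residuals
    qy <- stats::lm.fit(cbind(1, rc), ry)$residuals
    if (stats::sd(qx) == 0 || stats::sd(qy) == 0)
      return(list(rho = NA_real_, p = NA_real_, n = n, df = n - k - 2))
    rho <- stats::cor(qx, qy)
  } else {
    rho <- stats::cor(rx, ry)
  }
  df <- n - k - 2
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = p, n = n, df = df)
}

# numeric codings used throughout the GLM stage:
# group pAD = 1, NC = 0; sex female = 1, male = 0; language el = 1, en = 0
.code_numeric <- function(features) {
  out <- features
  if (is.character(out$group) || is.factor(out$group))
    out$group <- as.numeric(out$group == "pAD")
  if ("sex" %in% names(out) && (is.character(out$sex) || is.factor(out$sex)))
    out$sex <- as.numeric(out$sex == "female")
  if ("language" %in% names(out) &&
      (is.character(out$language) || is.factor(out$language)))
    out$language <- as.numeric(out$language == "el")
  out
}

#' Default measure set of the pipeline
#' @return Character vector of feature-column names treated as outcomes.
#' @export
semantic_measures <- function() {
  c("ft_lsim", "ft_gsim", "bert_lsim", "bert_gsim", "ppl", "bimodal_sim", "add")
}

#' Screen covariates by Spearman partial correlation with joint FDR
#'
#' For every (measure, candidate) pair, computes the Spearman partial
#' correlation between the candidate and the measure controlling for
#' language and group on the pooled table, adjusts all pairs jointly by
#' Benjamini-Hochberg, and keeps candidates with `q < alpha` for that
#' measure.
#'
#' @param features Pooled feature table (both languages) with `group` and
#'   `language` columns.
#' @param measures Outcome columns (default [semantic_measures()]).
#' @param candidates Candidate covariate columns.
#' @param alpha FDR significance level for selection.
#' @return List with `selected` (named list: measure -> character vector of
#'   kept candidates) and `table` (all pairs with rho, p, q).
#' @export
screen_covariates <- function(features,
                              measures = semantic_measures(),
                              candidates = c("age", "sex", "education",
                                             "word_ttr", "word_count"),
                              alpha = 0.05) {
  df <- .code_numeric(features)
  measures <- intersect(measures, names(df))
  candidates <- intersect(candidates, names(df))
  ctrl <- as.matrix(df[, intersect(c("language", "group"), names(df)),
                       drop = FALSE])
  grid <- expand.grid(measure = measures, candidate = candidates,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- tryCatch(
      partial_spearman(df[[grid$candidate[i]]], df[[grid$measure[i]]], ctrl),
      error = function(e) list(rho = NA_real_, p = NA_real_, n = NA, df = NA))
    data.frame(measure = grid$measure[i], candidate = grid$candidate[i],
               rho = ps$rho, p = ps$p, n = ps$n)
  })
  tab <- do.call(rbind, res)
  tab$q <- fdr_adjust(tab$p)
  selected <- lapply(stats::setNames(measures, measures), function(m) {
    sub <- tab[tab$measure == m & !is.na(tab$q) & tab$q < alpha, ]
    sub$candidate
  })
  list(selected = selected, table = tab)
}

#' Fit one generalized linear model with the family gate
#'
#' With `family = "auto"` the model is first fit with Gaussian errors and
#' identity link (ordinary least squares); the deviance goodness-of-fit test
#' (residual deviance vs the chi-square distribution on the residual degrees
#' of freedom) then decides the family: if the test rejects at `gof_alpha`
#' *and* the response is strictly positive, the model is refit with Gamma
#' errors and log link. Inference per coefficient is Wald: `z = beta / se`,
#' normal p-values and 95% CIs.
#'
#' @param data Data frame holding all columns, already numerically coded.
#' @param response Name of the outcome column.
#' @param predictor Name of the predictor of interest (e.g. `"group"` or
#'   `"mmse"`).
#' @param covariates Character vector of additional covariate columns.
#' @param family `"auto"`, `"gaussian"` (identity) or `"gamma_log"`.
#' @param gof_alpha Significance level of the deviance gate.
#' @return A `regression_result`: list with `measure`, `family`, `terms`
#'   (data.frame: term, estimate, se, z, p, ci_low, ci_high), `gof_p`, `n`.
#' @export
fit_glm <- function(data, response, predictor, covariates = character(0),
                    family = c("auto", "gaussian", "gamma_log"),
                    gof_alpha = 0.05) {
  family <- match.arg(family)
  cols <- c(response, predictor, covariates)
  stopifnot(all(cols %in% names(data)))
  df <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(df)
  if (n <= length(cols)) stop("too few complete rows to fit '", response, "'")
  const <- vapply(df[-1], function(col) length(unique(col)) < 2, logical(1))
  if (any(const))
    stop("degenerate (constant) predictor term(s) for '", response, "': ",
         paste(names(df[-1])[const], collapse = ", "))
  fml <- stats::as.formula(paste(response, "~",
                                 paste(c(predictor, covariates), collapse = " + ")))

  fit_family <- function(fam_obj, fam_label) {
    fit <- stats::glm(fml, data = df, family = fam_obj)
    if (any(is.na(stats::coef(fit))))
      stop("singular design for '", response, "'; collinear term(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    gof_p <- stats::pchisq(stats::deviance(fit), stats::df.residual(fit),
                           lower.tail = FALSE)
    list(fit = fit, label = fam_label, gof_p = gof_p)
  }

  f <- switch(family,
    gaussian = fit_family(stats::gaussian(), "gaussian_identity"),
    gamma_log = {
      if (any(df[[response]] <= 0))
        stop("gamma_log requires a strictly positive response")
      fit_family(stats::Gamma(link = "log"), "gamma_log")
    },
    auto = {
      g <- fit_family(stats::gaussian(), "gaussian_identity")
      if (g$gof_p < gof_alpha && all(df[[response]] > 0))
        fit_family(stats::Gamma(link = "log"), "gamma_log")
      else g
    })

  sm <- summary(f$fit)$coefficients
  est <- sm[, 1]; se <- sm[, 2]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- qnorm_ci(est, se)
  terms <- data.frame(term = rownames(sm), estimate = unname(est),
                      se = unname(se), z = unname(z), p = unname(p),
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      row.names = NULL)
  structure(list(measure = response, family = f$label, terms = terms,
                 gof_p = f$gof_p, n = n, predictor = predictor),
            class = "regression_result")
}

qnorm_ci <- function(est, se, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  cbind(est - zq * se, est + zq * se)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("GLM %s ~ %s  [%s, n = %d, GOF p = %.3g]\n",
              x$measure, x$predictor, x$family, x$n, x$gof_p))
  print(x$terms, digits = 4)
  invisible(x)
}

# shared driver for the group and MMSE analyses
.run_measure_models <- function(features, predictor, covariate_sets,
                                measures, gof_alpha, extra_ppl_cov) {
  df <- .code_numeric(features)
  results <- list()
  for (m in intersect(measures, names(df))) {
    covs <- covariate_sets[[m]] %||% character(0)
    if (m == "ppl") covs <- union(covs, extra_ppl_cov)
    covs <- setdiff(intersect(covs, names(df)), c(m, predictor))
    res <- tryCatch(
      fit_glm(df, m, predictor, covs, family = "auto", gof_alpha = gof_alpha),
      error = function(e)
        structure(list(measure = m, error = conditionMessage(e)),
                  class = "regression_error"))
    results[[m]] <- res
  }
  ok <- vapply(results, inherits, logical(1), "regression_result")
  pvals <- vapply(results[ok], function(r)
    r$terms$p[r$terms$term == predictor], numeric(1))
  qvals <- fdr_adjust(pvals)
  for (i in seq_along(qvals)) {
    m <- names(qvals)[i]
    results[[m]]$terms$q <- NA_real_
    results[[m]]$terms$q[results[[m]]$terms$term == predictor] <- qvals[i]
  }
  results
}

#' Group-difference GLMs for every measure (one dataset)
#'
#' Fits `measure ~ group + covariates` for each semantic measure, using that
#' measure's screened covariate set, with the family gate of [fit_glm()].
#' Perplexity additionally receives subword TTR as a covariate (lexical
#' diversity of subwords strongly drives raw perplexity). The group-term
#' p-values are FDR-corrected across measures within the dataset; a
#' per-measure fit error is recorded, not fatal.
#'
#' @param features Feature table for one language (group column present).
#' @param covariate_sets Named list measure -> covariates, e.g.
#'   `screen_covariates(...)$selected`. `NULL` screens on `features` itself.
#' @param measures Outcome columns.
#' @param gof_alpha Deviance-gate level.
#' @return Named list of `regression_result` (or `regression_error`) per
#'   measure; the group term carries a `q` column.
#' @export
run_group_analysis <- function(features, covariate_sets = NULL,
                               measures = semantic_measures(),
                               gof_alpha = 0.05) {
  if (is.null(covariate_sets))
    covariate_sets <- screen_covariates(features, measures = measures)$selected
  .run_measure_models(features, "group", covariate_sets, measures,
                      gof_alpha, extra_ppl_cov = "subword_ttr")
}

#' MMSE GLMs within the patient group (one dataset)
#'
#' As [run_group_analysis()] with MMSE replacing group as the predictor of
#' interest, restricted to pAD rows; FDR within the dataset.
#'
#' @inheritParams run_group_analysis
#' @export
run_mmse_analysis <- function(features, covariate_sets = NULL,
                              measures = semantic_measures(),
                              gof_alpha = 0.05) {
  pad <- features[features$group == "pAD" |
                    (is.numeric(features$group) & features$group == 1), ]
  if (is.null(covariate_sets))
    covariate_sets <- screen_covariates(features, measures = measures)$selected
  .run_measure_models(pad, "mmse", covariate_sets, measures,
                      gof_alpha, extra_ppl_cov = "subword_ttr")
}

#' Flatten regression results to a table
#'
#' @param results Named list from [run_group_analysis()] /
#'   [run_mmse_analysis()].
#' @return Data frame: measure, family, term, estimate, se, z, p, q, CI, n;
#'   failed fits appear with an `error` column.
#' @export
glm_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    if (inherits(r, "regression_error"))
      return(data.frame(measure = r$measure, family = NA, term = NA,
                        estimate = NA, se = NA, z = NA, p = NA, q = NA,
                        ci_low = NA, ci_high = NA, n = NA, gof_p = NA,
                        error = r$error))
    cbind(data.frame(measure = r$measure, family = r$family), r$terms,
          data.frame(n = r$n, gof_p = r$gof_p, error = NA_character_))
  })
  out <- do.call(rbind, lapply(rows, function(x) {
    if (!"q" %in% names(x)) x$q <- NA_real_
    x[c("measure", "family", "term", "estimate", "se", "z", "p", "q",
        "ci_low", "ci_high", "n", "gof_p", "error")]
  }))
  rownames(out) <- NULL
  out
}

#' Crosslingual replication verdict for one term
#'
#' A result from the larger (English) dataset counts as replicated in the
#' smaller (Greek) dataset when the coefficients share the same sign *and*
#' the English coefficient lies inside the Greek 95% confidence interval.
#' A coefficient of exactly zero matches either sign (non-strict).
#'
#' @param english,greek `regression_result` objects for the same measure.
#' @param term Coefficient name to compare (e.g. `"group"`).
#' @return List: measure, beta_en, beta_gr, Greek CI, `sign_match`,
#'   `ci_containment`, `replicated` (= both).
#' @export
assess_replication <- function(english, greek, term = "group") {
  get_row <- function(r) {
    row <- r$terms[r$terms$term == term, ]
    if (nrow(row) != 1) stop("term '", term, "' absent from model for ",
                             r$measure)
    row
  }
  en <- get_row(english); gr <- get_row(greek)
  sign_match <- en$estimate == 0 || gr$estimate == 0 ||
    sign(en$estimate) == sign(gr$estimate)
  containment <- en$estimate >= gr$ci_low && en$estimate <= gr$ci_high
  list(measure = english$measure, term = term,
       beta_en = en$estimate, beta_gr = gr$estimate,
       ci_gr_low = gr$ci_low, ci_gr_high = gr$ci_high,
       sign_match = sign_match, ci_containment = containment,
       replicated = sign_match && containment)
}
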