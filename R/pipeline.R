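#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run over the
#' two language datasets. Cohorts are either simulated (a [cohort_spec()]
#' per language) or loaded from disk (a directory in [write_cohort()]
#' layout).
#'
#' @param out_dir Output directory for all result files.
#' @param seed Master seed (overrides the seeds inside cohort specs).
#' @param cohorts Named list `en`/`el`: each a `cohort_spec` or a path.
#' @param fdr_alpha FDR level used for covariate screening.
#' @param gof_alpha Deviance goodness-of-fit gate level.
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            cohorts = list(en = cohort_spec("en"),
                                           el = cohort_spec("el")),
                            fdr_alpha = 0.05, gof_alpha = 0.05) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, gof_alpha > 0, gof_alpha < 1,
            length(cohorts) >= 1, !is.null(names(cohorts)))
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    if (is.character(co)) {
      if (!dir.exists(co)) stop("cohort directory does not exist: ", co)
    } else if (inherits(co, "cohort_spec")) {
      co$seed <- substream_seed(seed, paste0("cohort:", nm))
      cohorts[[nm]] <- co
    } else stop("cohorts entries must be cohort_spec objects or paths")
  }
  structure(list(out_dir = out_dir, seed = seed, cohorts = cohorts,
                 fdr_alpha = fdr_alpha, gof_alpha = gof_alpha),
            class = "pipeline_config")
}

.load_disk_cohort <- function(dir) {
  records <- load_cohort(file.path(dir, "metadata.csv"),
                         file.path(dir, "transcripts"))
  records <- impute_missing(records)
  parse_dir <- file.path(dir, "parses")
  parses <- if (dir.exists(parse_dir)) {
    stats::setNames(lapply(records$subject_id, function(id) {
      f <- file.path(parse_dir, paste0(id, ".conllu"))
      if (file.exists(f)) read_conllu(f) else NULL
    }), records$subject_id)
  } else NULL
  list(records = records, parses = parses)
}

# feature extraction through the provider route (fixture providers), for
# cohorts loaded from disk
.features_from_disk <- function(dc, language, seed) {
  providers <- list(
    static = static_embedder(seed = substream_seed(seed, "static")),
    contextual = contextual_embedder(seed = substream_seed(seed, "ctx")),
    logprob = logprob_provider("entropy", seed = substream_seed(seed, "lp")),
    bimodal = bimodal_encoder(seed = substream_seed(seed, "bim")))
  feats <- do.call(rbind, lapply(seq_len(nrow(dc$records)), function(i) {
    rec <- dc$records[i, ]
    tok <- tokenize(rec$transcript, language)
    cbind(rec[c("subject_id", "group", "language", "age", "sex",
                "education", "mmse")],
          extract_features(tok, providers,
                           image_id = paste0("stimulus:", language),
                           parses = dc$parses[[rec$subject_id]]))
  }))
  rownames(feats) <- NULL
  feats
}

#' Run the full analysis end to end
#'
#' Sequences the whole study: cohort acquisition (simulation or disk load
#' plus imputation), feature extraction, Table-1-style descriptives,
#' covariate screening on the pooled table, group GLMs and MMSE GLMs per
#' dataset with within-dataset FDR, and the crosslingual replication
#' verdicts for the group and MMSE terms. Writes one CSV per product plus a
#' JSON run manifest; identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  langs <- names(config$cohorts)

  features <- list()
  for (lg in langs) {
    co <- config$cohorts[[lg]]
    features[[lg]] <- if (is.character(co)) {
      .features_from_disk(.load_disk_cohort(co), lg,
                          substream_seed(config$seed, paste0("prov:", lg)))
    } else {
      cohort_features(generate_cohort(co))
    }
    utils::write.csv(features[[lg]],
                     file.path(config$out_dir,
                               paste0("features_", lg, ".csv")),
                     row.names = FALSE, na = "")
  }

  pooled <- do.call(rbind, features)
  desc <- do.call(rbind, lapply(langs, function(lg) {
    f <- features[[lg]]
    cbind(dataset = lg,
          describe_groups(f, f[c("word_count", "subword_count",
                                 "word_ttr", "subword_ttr")]))
  }))
  utils::write.csv(desc, file.path(config$out_dir, "descriptives.csv"),
                   row.names = FALSE, na = "")

  screening <- screen_covariates(pooled, alpha = config$fdr_alpha)
  utils::write.csv(screening$table,
                   file.path(config$out_dir, "covariate_screening.csv"),
                   row.names = FALSE, na = "")

  group_results <- mmse_results <- list()
  for (lg in langs) {
    group_results[[lg]] <- run_group_analysis(
      features[[lg]], covariate_sets = screening$selected,
      gof_alpha = config$gof_alpha)
    utils::write.csv(glm_results_table(group_results[[lg]]),
                     file.path(config$out_dir,
                               paste0("group_results_", lg, ".csv")),
                     row.names = FALSE, na = "")
    mmse_results[[lg]] <- run_mmse_analysis(
      features[[lg]], covariate_sets = screening$selected,
      gof_alpha = config$gof_alpha)
    utils::write.csv(glm_results_table(mmse_results[[lg]]),
                     file.path(config$out_dir,
                               paste0("mmse_results_", lg, ".csv")),
                     row.names = FALSE, na = "")
  }

  replication <- NULL
  if (all(c("en", "el") %in% langs)) {
    rep_rows <- list()
    for (set in list(list(res = group_results, term = "group"),
                     list(res = mmse_results, term = "mmse"))) {
      for (m in semantic_measures()) {
        en <- set$res$en[[m]]; el <- set$res$el[[m]]
        if (inherits(en, "regression_result") &&
            inherits(el, "regression_result")) {
          v <- assess_replication(en, el, set$term)
          rep_rows[[paste(set$term, m)]] <- as.data.frame(v)
        }
      }
    }
    replication <- do.call(rbind, rep_rows)
    rownames(replication) <- NULL
    utils::write.csv(replication,
                     file.path(config$out_dir, "replication.csv"),
                     row.names = FALSE, na = "")
  }

  manifest <- list(
    seed = config$seed, languages = langs,
    fdr_alpha = config$fdr_alpha, gof_alpha = config$gof_alpha,
    n_subjects = vapply(features, nrow, integer(1)),
    package_version = as.character(utils::packageVersion("semspace")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(features = features, descriptives = desc,
                 screening = screening, group_results = group_results,
                 mmse_results = mmse_results, replication = replication,
                 out_dir = config$out_dir))
}
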