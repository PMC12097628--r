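# Synthetic cohort generator.
#
# Real picture-description corpora for dementia research are
# access-restricted, so the pipeline is exercised on synthetic cohorts whose
# every generating parameter is known: group-structured demographics,
# transcripts of realistic length, embedding clouds whose within-transcript
# pairwise cosine is controlled by a concentration parameter (higher in
# pAD = contracted semantic space), token surprisals with controlled mean
# cross-entropy, dependency trees with controlled mean arc length, and
# sentence/image pairs with controlled alignment. Ground truth travels with
# the cohort, so parameter-recovery tests are possible at every stage.

#' Cohort specification
#'
#' Defaults emulate the descriptive structure of the published English and
#' Greek picture-description datasets (sample sizes, age, education, MMSE,
#' female proportion, words per transcript). Dispersion is parameterized as
#' concentration `kappa`: embedding noise has scale `1/kappa`, so higher
#' `kappa` gives a tighter (more contracted) cloud and a *higher* expected
#' pairwise cosine. Group-level knobs are length-2 vectors `c(NC, pAD)`.
#'
#' @param language `"en"` or `"el"` (selects the demographic preset).
#' @param seed Integer master seed; expands into per-subject substreams.
#' @param n_nc,n_pad Group sizes.
#' @param age_mean,age_sd,edu_mean,edu_sd,mmse_mean,mmse_sd Demographic
#'   parameters per group (`c(NC, pAD)`); MMSE is truncated to `[0, 30]`.
#' @param female_prop Proportion of female subjects per group.
#' @param words_mean,words_sd,words_min Transcript length (words) per group.
#' @param lexicon_size Content lexicon size per group (smaller = lower TTR).
#' @param kappa Embedding concentration per group; `kappa_cv` is the
#'   between-subject log-scale spread of the individual concentration.
#' @param entropy_bits Target mean token surprisal per group (bits);
#'   `entropy_subject_sd` its between-subject log-scale spread.
#' @param alignment Picture-speech alignment level per group, in `[0, 1]`;
#'   `alignment_subject_sd` its between-subject spread.
#' @param arc_mean Mean dependency arc length per group (>= 1).
#' @param embed_dim,bimodal_dim Embedding dimensionalities.
#' @param sentence_len Target words per sentence.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(language = c("en", "el"), seed = 1,
                        n_nc = NULL, n_pad = NULL,
                        age_mean = NULL, age_sd = NULL,
                        female_prop = NULL,
                        edu_mean = NULL, edu_sd = NULL,
                        mmse_mean = NULL, mmse_sd = NULL,
                        words_mean = NULL, words_sd = NULL, words_min = 10,
                        lexicon_size = c(350, 220),
                        kappa = c(2.0, 2.16), kappa_cv = 0.12,
                        entropy_bits = c(5.0, 4.6), entropy_subject_sd = 0.15,
                        alignment = c(0.45, 0.38), alignment_subject_sd = 0.05,
                        arc_mean = c(2.3, 2.0),
                        embed_dim = 32, bimodal_dim = 64, sentence_len = 7) {
  language <- match.arg(language)
  preset <- if (language == "en") list(
    n_nc = 143, n_pad = 148,
    age_mean = c(66.06, 69.38), age_sd = c(6.31, 6.88),
    female_prop = c(0.652, 0.648),
    edu_mean = c(13.98, 11.97), edu_sd = c(2.38, 2.64),
    mmse_mean = c(28.97, 17.84), mmse_sd = c(1.17, 5.48),
    words_mean = c(57.7, 51.5), words_sd = c(27.7, 28.1)
  ) else list(
    n_nc = 28, n_pad = 26,
    age_mean = c(66.57, 72.74), age_sd = c(7.28, 6.83),
    female_prop = c(0.714, 0.731),
    edu_mean = c(12.0, 9.5), edu_sd = c(4.03, 3.92),
    mmse_mean = c(28.82, 20.96), mmse_sd = c(1.16, 4.57),
    words_mean = c(29.4, 30.2), words_sd = c(15.5, 14.7)
  )
  spec <- list(language = language, seed = seed,
               n_nc = n_nc %||% preset$n_nc, n_pad = n_pad %||% preset$n_pad,
               age_mean = age_mean %||% preset$age_mean,
               age_sd = age_sd %||% preset$age_sd,
               female_prop = female_prop %||% preset$female_prop,
               edu_mean = edu_mean %||% preset$edu_mean,
               edu_sd = edu_sd %||% preset$edu_sd,
               mmse_mean = mmse_mean %||% preset$mmse_mean,
               mmse_sd = mmse_sd %||% preset$mmse_sd,
               words_mean = words_mean %||% preset$words_mean,
               words_sd = words_sd %||% preset$words_sd,
               words_min = words_min, lexicon_size = lexicon_size,
               kappa = kappa, kappa_cv = kappa_cv,
               entropy_bits = entropy_bits,
               entropy_subject_sd = entropy_subject_sd,
               alignment = alignment,
               alignment_subject_sd = alignment_subject_sd,
               arc_mean = arc_mean, embed_dim = embed_dim,
               bimodal_dim = bimodal_dim, sentence_len = sentence_len)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  stopifnot(s$n_nc >= 1, s$n_pad >= 1,
            all(s$kappa > 0), all(s$entropy_bits >= 0),
            all(s$alignment >= 0), all(s$alignment <= 1),
            all(s$arc_mean >= 1), s$embed_dim >= 2, s$bimodal_dim >= 2,
            s$words_min >= 2, all(s$words_mean >= s$words_min),
            all(s$lexicon_size >= 2), s$sentence_len >= 2,
            all(s$female_prop >= 0), all(s$female_prop <= 1),
            all(s$mmse_sd >= 0))
  invisible(s)
}

# truncated-normal integer MMSE in [0, 30] by rejection
.draw_mmse <- function(mu, sd) {
  for (i in 1:1000) {
    x <- round(stats::rnorm(1, mu, sd))
    if (x >= 0 && x <= 30) return(as.integer(x))
  }
  as.integer(min(30, max(0, round(mu))))
}

# one sentence's dependency parse: m words + final period; token 1 is the
# root, every later word attaches d tokens back (shifted geometric, mean
# `arc_mean`), clipped at the sentence start
.gen_parse <- function(words, arc_mean) {
  m <- length(words)
  pos <- seq_len(m + 1L)
  head <- integer(m + 1L)
  head[1] <- 0L
  if (m >= 2) {
    d <- 1L + stats::rgeom(m - 1L, prob = 1 / arc_mean)
    head[2:m] <- pmax(1L, (2:m) - d)
  }
  head[m + 1L] <- 1L                       # final period hangs off the root
  # cheap data.frame construction: this runs once per sentence
  tk <- structure(list(position = pos, form = c(words, "."), head = head,
                       punct = c(rep(FALSE, m), TRUE)),
                  class = "data.frame", row.names = c(NA, -(m + 1L)))
  dependency_parse(tk)
}

.split_subwords <- function(words, chunk = 3L) {
  unlist(lapply(words, function(w) {
    n <- nchar(w)
    starts <- seq(1L, n, by = chunk)
    substring(w, starts, pmin(starts + chunk - 1L, n))
  }), use.names = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Produces, for every subject: a metadata record, a transcript (content
#' words interleaved with language-appropriate stopwords, chunked into
#' sentences), a static-track embedding cloud over the content words and a
#' contextual-track cloud over the subwords (both drawn as
#' `normalize(centroid + noise / kappa_subject)`, so higher `kappa` gives
#' higher expected pairwise cosine), token surprisals with subject-level
#' mean cross-entropy around the group target, one dependency parse per
#' sentence with the group's mean arc length, and sentence/image vectors at
#' the group's alignment level. The `truth` element records every generating
#' parameter, including the per-subject draws.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (data.frame), `tokens`, `ft_seqs`,
#'   `bert_seqs`, `logprobs`, `parses`, `bimodal` (per-subject lists) and
#'   `truth`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  stop_words <- stopword_list(spec$language)
  n_total <- spec$n_nc + spec$n_pad
  groups <- rep(c("NC", "pAD"), c(spec$n_nc, spec$n_pad))
  ids <- sprintf("%s%03d", ifelse(groups == "NC", "C", "P"),
                 stats::ave(seq_len(n_total), groups, FUN = seq_along))
  ids <- paste0(spec$language, "_", ids)
  image_vec <- seeded_unit_vector(
    substream_seed(spec$seed, paste0("image:", spec$language)),
    spec$bimodal_dim)

  records <- vector("list", n_total)
  tokens <- ft_seqs <- bert_seqs <- logprobs <- parses <- bimodal <-
    stats::setNames(vector("list", n_total), ids)
  subj_truth <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    g <- if (groups[i] == "NC") 1L else 2L
    res <- withr::with_seed(substream_seed(spec$seed, paste0("subj:", ids[i])), {
      age <- stats::rnorm(1, spec$age_mean[g], spec$age_sd[g])
      sex <- if (stats::runif(1) < spec$female_prop[g]) "female" else "male"
      edu <- max(0, stats::rnorm(1, spec$edu_mean[g], spec$edu_sd[g]))
      mmse <- .draw_mmse(spec$mmse_mean[g], spec$mmse_sd[g])
      n_words <- max(spec$words_min,
                     round(stats::rnorm(1, spec$words_mean[g], spec$words_sd[g])))

      lex <- spec$lexicon_size[g]
      # Zipf-weighted draw from the group lexicon: frequent types recur,
      # so TTR falls with shrinking lexicon, as in patient speech
      content <- sprintf("w%04d",
                         sample.int(lex, n_words, replace = TRUE,
                                    prob = 1 / seq_len(lex)))
      with_stops <- unlist(lapply(content, function(w) {
        if (stats::runif(1) < 0.35) c(sample(stop_words, 1), w) else w
      }), use.names = FALSE)
      sent_sizes <- diff(unique(c(
        seq(0, length(with_stops), by = spec$sentence_len),
        length(with_stops))))
      sent_words <- split(with_stops,
                          rep(seq_along(sent_sizes), sent_sizes))
      sentences <- vapply(sent_words, function(ws)
        paste0(paste(ws, collapse = " "), "."), character(1))
      transcript <- paste(sentences, collapse = " ")
      subwords <- .split_subwords(with_stops)

      kap <- spec$kappa[g] * exp(stats::rnorm(1, 0, spec$kappa_cv))
      sigma <- 1 / kap
      mk_cloud <- function(toks, tag) {
        d <- spec$embed_dim
        centroid <- unit_vector(stats::rnorm(d))
        noise <- matrix(stats::rnorm(length(toks) * d, 0, sigma),
                        length(toks), d)
        embedded_sequence(unit_rows(sweep(noise, 2, centroid, "+")), toks)
      }
      ft <- mk_cloud(content, "ft")
      bert <- mk_cloud(subwords, "bert")

      h <- spec$entropy_bits[g] * exp(stats::rnorm(1, 0, spec$entropy_subject_sd))
      m_pred <- length(subwords) - 1L
      lp <- token_logprobs(-stats::rgamma(m_pred, shape = 4, rate = 4 / h),
                           base = "2")

      prs <- lapply(sent_words, .gen_parse, arc_mean = spec$arc_mean[g])

      a <- min(1, max(0, spec$alignment[g] +
                        stats::rnorm(1, 0, spec$alignment_subject_sd)))
      sv <- t(vapply(seq_along(sentences), function(k)
        unit_vector(a * image_vec +
                      (1 - a) * unit_vector(stats::rnorm(spec$bimodal_dim))),
        numeric(spec$bimodal_dim)))
      bp <- bimodal_pair(sv, image_vec)

      list(rec = list(subject_id = ids[i], group = groups[i],
                      language = spec$language, age = age, sex = sex,
                      education = edu, mmse = mmse,
                      transcript = transcript),
           tok = list(content_words = content, all_words = with_stops,
                      subwords = subwords, sentences = sentences),
           ft = ft, bert = bert, lp = lp, prs = prs, bp = bp,
           truth = list(kappa = kap, entropy_bits = h, alignment = a))
    })
    records[[i]] <- res$rec
    tokens[[i]] <- res$tok
    ft_seqs[[i]] <- res$ft
    bert_seqs[[i]] <- res$bert
    logprobs[[i]] <- res$lp
    parses[[i]] <- res$prs
    bimodal[[i]] <- res$bp
    subj_truth[[i]] <- res$truth
  }

  records <- do.call(rbind, lapply(records, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(records = records, tokens = tokens, ft_seqs = ft_seqs,
       bert_seqs = bert_seqs, logprobs = logprobs, parses = parses,
       bimodal = bimodal,
       truth = list(spec = spec,
                    subjects = stats::setNames(subj_truth, ids)))
}

#' Feature table of a synthetic cohort
#'
#' Runs every metric operation on the cohort's generated objects and returns
#' the per-subject feature table the statistical stage consumes (metadata
#' columns plus counts, TTRs and the seven semantic measures).
#'
#' @param cohort Output of [generate_cohort()].
#' @return Data frame, one row per subject.
#' @export
cohort_features <- function(cohort) {
  ids <- cohort$records$subject_id
  num <- function(f) vapply(ids, f, numeric(1), USE.NAMES = FALSE)
  feats <- data.frame(
    word_count = num(function(id) length(cohort$tokens[[id]]$all_words)),
    content_word_count =
      num(function(id) length(cohort$tokens[[id]]$content_words)),
    subword_count = num(function(id) length(cohort$tokens[[id]]$subwords)),
    word_ttr = num(function(id) compute_ttr(cohort$tokens[[id]]$all_words)),
    content_ttr =
      num(function(id) compute_ttr(cohort$tokens[[id]]$content_words)),
    subword_ttr = num(function(id) compute_ttr(cohort$tokens[[id]]$subwords)),
    ft_lsim = num(function(id) local_similarity(cohort$ft_seqs[[id]])),
    ft_gsim = num(function(id) global_similarity(cohort$ft_seqs[[id]])),
    bert_lsim = num(function(id) local_similarity(cohort$bert_seqs[[id]])),
    bert_gsim = num(function(id) global_similarity(cohort$bert_seqs[[id]])),
    ppl = num(function(id) perplexity(cohort$logprobs[[id]])$ppl),
    bimodal_sim = num(function(id) bimodal_alignment(cohort$bimodal[[id]])),
    add = num(function(id)
      averaged_dependency_distance(cohort$parses[[id]])))
  meta_cols <- c("subject_id", "group", "language", "age", "sex",
                 "education", "mmse")
  cbind(cohort$records[meta_cols], feats)
}

#' Write a cohort in the pipeline's on-disk formats
#'
#' Emits `metadata.csv`, one UTF-8 transcript per subject under
#' `transcripts/`, and one CoNLL-U parse file per subject under `parses/`,
#' so generated cohorts exercise the same I/O path as real data.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "parses"), showWarnings = FALSE)
  meta <- cohort$records[c("subject_id", "group", "language", "age", "sex",
                           "education", "mmse")]
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE,
                   na = "")
  for (id in cohort$records$subject_id) {
    writeLines(cohort$records$transcript[cohort$records$subject_id == id],
               file.path(dir, "transcripts", paste0(id, ".txt")),
               useBytes = TRUE)
    write_conllu(cohort$parses[[id]],
                 file.path(dir, "parses", paste0(id, ".conllu")))
  }
  invisible(dir)
}

#' Worked-example fixture bundle
#'
#' The deterministic in-text computable fixtures: the fair-die
#' log-probability sequence (uniform over six outcomes, so cross-entropy is
#' `log2(6) = 2.585` bits and perplexity is exactly 6), the 7-token "Mary
#' ate the juicy red sweet apple" dependency parse (where the *ate*-*apple*
#' arc spans 5 positions), and a 2-sentence picture/speech pair in which one
#' sentence vector equals the picture vector and the other is orthogonal to
#' it (mean alignment 0.5).
#'
#' @param n_tokens Length of the die log-probability sequence.
#' @return List with `die_logprobs`, `parse`, `bimodal`.
#' @export
generate_worked_examples <- function(n_tokens = 12) {
  stopifnot(n_tokens >= 1)
  die <- token_logprobs(rep(-log2(6), n_tokens), base = "2")
  mary <- dependency_parse(data.frame(
    position = 1:7,
    form = c("Mary", "ate", "the", "juicy", "red", "sweet", "apple"),
    head = c(2L, 0L, 7L, 7L, 7L, 7L, 2L),
    punct = rep(FALSE, 7)))
  img <- c(1, 0, 0, 0)
  bp <- bimodal_pair(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), img)
  list(die_logprobs = die, parse = mary, bimodal = bp)
}
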