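#' Load a cohort of transcripts plus metadata
#'
#' Reads a metadata CSV (columns `subject_id, group, language, age, sex,
#' education, mmse`; missing values as empty cells) and pairs each row with a
#' UTF-8 transcript file named `<subject_id>.txt` in `transcript_dir`.
#' Missing `education`/`mmse` values are kept as `NA` and flagged, not yet
#' imputed — see [impute_missing()].
#'
#' @param metadata_table Path to the metadata CSV.
#' @param transcript_dir Directory holding one `.txt` file per subject.
#' @return A `data.frame` of subject records with a `transcript` column.
#' @export
load_cohort <- function(metadata_table, transcript_dir) {
  meta <- utils::read.csv(metadata_table, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), encoding = "UTF-8")
  required <- c("subject_id", "group", "language", "age", "sex", "education", "mmse")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata table is missing columns: ", paste(missing_cols, collapse = ", "))

  bad_group <- setdiff(unique(meta$group), c("NC", "pAD"))
  if (length(bad_group) > 0)
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  bad_lang <- setdiff(unique(meta$language), c("en", "el"))
  if (length(bad_lang) > 0)
    stop("unknown language label(s): ", paste(bad_lang, collapse = ", "))
  if (anyNA(meta$group) || anyNA(meta$language))
    stop("group and language must be present for every subject")
  ok_mmse <- is.na(meta$mmse) | (meta$mmse >= 0 & meta$mmse <= 30)
  if (!all(ok_mmse))
    stop("mmse out of [0, 30] for subject(s): ",
         paste(meta$subject_id[!ok_mmse], collapse = ", "))

  paths <- file.path(transcript_dir, paste0(meta$subject_id, ".txt"))
  absent <- !file.exists(paths)
  if (any(absent))
    stop("missing transcript file for subject(s): ",
         paste(meta$subject_id[absent], collapse = ", "))
  meta$transcript <- vapply(paths, function(p)
    paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = " "),
    character(1), USE.NAMES = FALSE)
  meta <- meta[c(required, "transcript")]
  class(meta) <- c("subject_cohort", "data.frame")
  meta
}

#' Impute missing education and MMSE from same-language NC means
#'
#' Each missing `education` or `mmse` value is replaced by the mean of the
#' non-missing values among normal-control (NC) records of the *same
#' language*. Non-missing values are never touched, so the operation is
#' idempotent. A missing value with no NC donors in its language is a hard
#' error.
#'
#' @param records Cohort data frame as returned by [load_cohort()].
#' @return The cohort with `education` and `mmse` complete.
#' @export
impute_missing <- function(records) {
  for (var in c("education", "mmse")) {
    for (lang in unique(records$language)) {
      in_lang <- records$language == lang
      need <- in_lang & is.na(records[[var]])
      if (!any(need)) next
      donors <- records[[var]][in_lang & records$group == "NC"]
      donors <- donors[!is.na(donors)]
      if (length(donors) == 0)
        stop("no NC donor values for '", var, "' in language '", lang, "'")
      records[[var]][need] <- mean(donors)
    }
  }
  records
}

#' Per-language stopword list
#'
#' Frozen word lists shipped with the package (seeded from the standard
#' English and Greek function-word lists), so tokenization does not drift
#' with an external resource.
#'
#' @param language `"en"` or `"el"`.
#' @return Character vector of lowercased stopwords.
#' @export
stopword_list <- function(language = c("en", "el")) {
  language <- match.arg(language)
  path <- system.file("extdata", paste0("stopwords_", language, ".txt"),
                      package = "semspace", mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Frozen fixture subword vocabulary
#'
#' Small vocabulary (single letters of both alphabets plus common English and
#' Greek word pieces) used by the greedy longest-match segmenter. Real
#' WordPiece-style tokenizers plug in behind the same contract.
#'
#' @return Character vector of subword pieces.
#' @export
default_subword_vocab <- function() {
  path <- system.file("extdata", "subword_vocab.txt",
                      package = "semspace", mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# Greedy longest-match segmentation of one lowercased word against a
# vocabulary; characters not covered by the vocabulary pass through as
# single-character tokens.
segment_word <- function(word, vocab_by_len) {
  out <- character(0)
  i <- 1L
  n <- nchar(word)
  lens <- as.integer(names(vocab_by_len))
  while (i <= n) {
    hit <- NA_character_
    for (L in lens) {             # lens sorted decreasing
      if (i + L - 1L > n) next
      piece <- substr(word, i, i + L - 1L)
      if (piece %in% vocab_by_len[[as.character(L)]]) { hit <- piece; break }
    }
    if (is.na(hit)) hit <- substr(word, i, i)
    out <- c(out, hit)
    i <- i + nchar(hit)
  }
  out
}

#' Tokenize a transcript into the conceptual and referential tracks
#'
#' Lowercases the text, splits sentences at sentence-final punctuation
#' (`.`, `!`, `?`, `;` followed by whitespace), strips punctuation-only
#' tokens to form `all_words`, removes stopwords to form `content_words`
#' (the conceptual track, fed to static word embeddings), and segments every
#' word into subwords by greedy longest match against `subword_vocab` (the
#' referential track, fed to contextual embeddings — no words are removed
#' there, since they jointly form the context).
#'
#' @param transcript Non-empty text.
#' @param language `"en"` or `"el"`; selects the default stopword list.
#' @param stopwords Optional explicit stopword vector (overrides the default).
#' @param subword_vocab Optional subword vocabulary (defaults to the frozen
#'   fixture vocabulary).
#' @return A list with `content_words`, `all_words`, `subwords`, `sentences`.
#' @export
tokenize <- function(transcript, language = c("en", "el"),
                     stopwords = NULL, subword_vocab = NULL) {
  language <- match.arg(language)
  stopifnot(is.character(transcript), length(transcript) == 1L)
  if (is.null(stopwords)) stopwords <- stopword_list(language)
  if (is.null(subword_vocab)) subword_vocab <- default_subword_vocab()

  txt <- trimws(transcript)
  sentences <- if (nzchar(txt)) {
    trimws(strsplit(txt, "(?<=[.!?;])\\s+", perl = TRUE)[[1]])
  } else character(0)
  sentences <- sentences[nzchar(sentences)]

  raw <- strsplit(tolower(txt), "\\s+", perl = TRUE)[[1]]
  # strip leading/trailing punctuation; drop tokens that were punctuation only
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw)
  words <- words[nzchar(words)]
  content <- words[!(words %in% tolower(stopwords))]

  vocab <- unique(subword_vocab)
  vocab_by_len <- split(vocab, nchar(vocab))
  vocab_by_len <- vocab_by_len[order(as.integer(names(vocab_by_len)),
                                     decreasing = TRUE)]
  subwords <- unlist(lapply(words, segment_word, vocab_by_len = vocab_by_len),
                     use.names = FALSE)
  if (is.null(subwords)) subwords <- character(0)

  list(content_words = content, all_words = words,
       subwords = subwords, sentences = sentences)
}

#' Type-token ratio
#'
#' Unique tokens divided by total tokens; `NA` for an empty list.
#'
#' @param tokens Character vector of tokens.
#' @return Ratio in (0, 1], or `NA_real_` for empty input.
#' @export
compute_ttr <- function(tokens) {
  if (length(tokens) == 0) return(NA_real_)
  length(unique(tokens)) / length(tokens)
}

#' Group descriptives table (demographics and text measures)
#'
#' For continuous variables: two-sided Mann–Whitney test with the
#' rank-biserial correlation as effect size, computed as the signed
#' proportion of pairs, `r = (#NC-greater - #pAD-greater)/(n1*n2)`
#' (equivalently `2U/(n1*n2) - 1` with `U` the NC-group statistic), so a
#' positive value means the NC group tends to be larger. For sex: 2x2 chi-square
#' test (no continuity correction) with the contingency coefficient
#' `C = sqrt(chi2 / (chi2 + N))`. A variable constant in both groups is
#' reported with `p = 1` and effect size 0.
#'
#' @param records Cohort data frame (must contain `group` and `sex`).
#' @param features Optional data frame of extra per-subject numeric columns,
#'   row-aligned with `records`, to describe alongside the demographics.
#' @return A data.frame with one row per variable: group means/sds (or female
#'   proportions), test name, p, effect size.
#' @export
describe_groups <- function(records, features = NULL) {
  stopifnot(all(c("NC", "pAD") %in% records$group))
  nc <- records$group == "NC"
  pad <- records$group == "pAD"

  numeric_vars <- list()
  for (v in c("age", "education", "mmse"))
    if (v %in% names(records)) numeric_vars[[v]] <- records[[v]]
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(records))
    for (v in names(features))
      if (is.numeric(features[[v]])) numeric_vars[[v]] <- features[[v]]
  }

  rows <- list()
  if ("sex" %in% names(records)) {
    f_nc <- mean(records$sex[nc] == "female")
    f_pad <- mean(records$sex[pad] == "female")
    tab <- table(factor(records$group, c("NC", "pAD")),
                 factor(records$sex, c("female", "male")))
    if (length(unique(records$sex)) < 2) {
      p <- 1; eff <- 0
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic)
      p <- ct$p.value
      eff <- sqrt(chi2 / (chi2 + sum(tab)))
    }
    rows[["sex"]] <- data.frame(
      variable = "sex", nc_mean = f_nc, nc_sd = NA_real_,
      pad_mean = f_pad, pad_sd = NA_real_,
      test = "chi-square", p = p, effect_size = eff)
  }

  for (v in names(numeric_vars)) {
    x <- numeric_vars[[v]][nc]; y <- numeric_vars[[v]][pad]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(unique(c(x, y))) < 2) {
      p <- 1; rb <- 0
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      u <- unname(wt$statistic)            # U for the first-listed group (NC)
      p <- wt$p.value
      # rank-biserial = (#NC-greater pairs - #pAD-greater pairs)/(n1*n2)
      rb <- 2 * u / (length(x) * length(y)) - 1
    }
    rows[[v]] <- data.frame(
      variable = v, nc_mean = mean(x), nc_sd = stats::sd(x),
      pad_mean = mean(y), pad_sd = stats::sd(y),
      test = "mann-whitney", p = p, effect_size = rb)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
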