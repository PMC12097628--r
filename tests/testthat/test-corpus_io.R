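test_that("load_cohort pairs metadata rows with transcript files", {
  dir <- withr::local_tempdir()
  rows <- data.frame(subject_id = c("S1", "S2"), group = c("NC", "pAD"),
                     language = "en", age = c(70, 72),
                     sex = c("female", "male"),
                     education = c(12, NA), mmse = c(29, 20))
  paths <- write_tiny_cohort(dir, rows,
                             list(S1 = "the boy ate a cookie.",
                                  S2 = "she fell. he ran."))
  cohort <- load_cohort(paths$meta, paths$tx)
  expect_equal(nrow(cohort), 2)
  expect_equal(cohort$transcript[1], "the boy ate a cookie.")
  expect_true(is.na(cohort$education[2]))   # flagged missing, not imputed
})

test_that("load_cohort fails hard on missing files and bad labels", {
  dir <- withr::local_tempdir()
  rows <- data.frame(subject_id = c("S1", "S3"), group = c("NC", "pAD"),
                     language = "en", age = 70, sex = "female",
                     education = 12, mmse = 29)
  paths <- write_tiny_cohort(dir, rows, list(S1 = "hello there."))
  expect_error(load_cohort(paths$meta, paths$tx), "S3")

  rows2 <- data.frame(subject_id = "S1", group = "MCI", language = "en",
                      age = 70, sex = "female", education = 12, mmse = 29)
  utils::write.csv(rows2, file.path(dir, "meta2.csv"), row.names = FALSE)
  expect_error(load_cohort(file.path(dir, "meta2.csv"), paths$tx),
               "group")
})

test_that("imputation uses same-language NC means and is idempotent", {
  rec <- data.frame(
    subject_id = paste0("S", 1:6),
    group = c("NC", "NC", "pAD", "NC", "NC", "pAD"),
    language = c("en", "en", "en", "el", "el", "el"),
    age = 70, sex = "female",
    education = c(12, 14, NA, 10, NA, 8),
    mmse = c(29, 28, NA, 30, 29, NA))
  out <- impute_missing(rec)
  expect_equal(out$education[3], 13)       # mean of en NC {12, 14}
  expect_equal(out$education[5], 10)       # el NC donor pool is just {10}
  expect_equal(out$mmse[3], 28.5)          # pAD missingness still NC-imputed
  expect_equal(out$mmse[6], 29.5)
  expect_identical(impute_missing(out), out)

  # untouched where complete
  full <- rec; full$education <- 12; full$mmse <- 25
  expect_identical(impute_missing(full), full)

  # no NC donors in the language -> hard error
  bad <- data.frame(subject_id = "X", group = "pAD", language = "el",
                    age = 70, sex = "male", education = NA, mmse = 20)
  expect_error(impute_missing(bad), "donor")
})

test_that("tokenize separates tracks and splits sentences", {
  tok <- tokenize("The boy ate the cookie.", "en",
                  stopwords = c("the"),
                  subword_vocab = c(letters))
  expect_equal(tok$content_words, c("boy", "ate", "cookie"))
  expect_equal(tok$all_words, c("the", "boy", "ate", "the", "cookie"))
  # content_words is a subsequence of all_words
  expect_true(all(tok$content_words %in% tok$all_words))

  tok2 <- tokenize("He ran. She fell.", "en")
  expect_equal(tok2$sentences, c("He ran.", "She fell."))

  # longest-match segmentation prefers the whole-word piece
  tok3 <- tokenize("cookie", "en", stopwords = character(0),
                   subword_vocab = c("coo", "kie", "cookie"))
  expect_equal(tok3$subwords, "cookie")
  tok4 <- tokenize("cookie", "en", stopwords = character(0),
                   subword_vocab = c("coo", "kie"))
  expect_equal(tok4$subwords, c("coo", "kie"))

  # all stopwords -> empty content track, no error
  tok5 <- tokenize("the the the.", "en")
  expect_length(tok5$content_words, 0)
  # subword count >= word count whenever the vocabulary splits words
  expect_gte(length(tok4$subwords), length(tok4$all_words))
})

test_that("type-token ratio matches its definition and ignores order", {
  expect_equal(compute_ttr(c("a", "b", "c")), 1)
  expect_equal(compute_ttr(rep("a", 4)), 0.25)
  expect_equal(compute_ttr(c("a", "b", "a", "c")), 0.75)
  expect_true(is.na(compute_ttr(character(0))))
  for (i in 1:20) {
    toks <- sample(letters[1:5], sample(2:30, 1), replace = TRUE)
    expect_equal(compute_ttr(toks), compute_ttr(rev(toks)))
  }
})

test_that("group descriptives: Mann-Whitney effect equals pairwise oracle", {
  # separated groups: all 9 pairs favour NC
  rec <- data.frame(subject_id = paste0("S", 1:6),
                    group = rep(c("NC", "pAD"), each = 3),
                    language = "en", sex = rep(c("female", "male"), 3),
                    age = c(4, 5, 6, 1, 2, 3), education = 12, mmse = 25)
  d <- describe_groups(rec)
  expect_equal(d$effect_size[d$variable == "age"], 1)

  # identical distributions -> rank-biserial 0
  rec$age <- rep(c(1, 2, 3), 2)
  d2 <- describe_groups(rec)
  expect_equal(d2$effect_size[d2$variable == "age"], 0)

  # random fixtures up to n1 = n2 = 8 against the exhaustive pair oracle
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:10, n1, replace = TRUE)
    y <- sample(1:10, n2, replace = TRUE)
    r <- data.frame(subject_id = seq_len(n1 + n2),
                    group = rep(c("NC", "pAD"), c(n1, n2)),
                    language = "en", sex = "female",
                    age = c(x, y), education = 12, mmse = 25)
    d3 <- describe_groups(r)
    expect_equal(d3$effect_size[d3$variable == "age"],
                 oracle_rank_biserial(x, y), tolerance = 1e-12)
  }
})

test_that("sex descriptive: balanced 2x2 table gives chi2 = 0, C = 0", {
  rec <- data.frame(subject_id = 1:40,
                    group = rep(c("NC", "pAD"), each = 20),
                    language = "en",
                    sex = rep(rep(c("female", "male"), each = 10), 2),
                    age = rnorm(40, 70), education = 12, mmse = 25)
  d <- describe_groups(rec)
  expect_equal(d$p[d$variable == "sex"], 1)
  expect_equal(d$effect_size[d$variable == "sex"], 0)
  expect_equal(d$nc_mean[d$variable == "sex"], 0.5)
})

test_that("constant variables are reported with p = 1 and zero effect", {
  rec <- data.frame(subject_id = 1:6, group = rep(c("NC", "pAD"), 3),
                    language = "en", sex = "female",
                    age = 70, education = 12, mmse = 25)
  d <- describe_groups(rec)
  expect_true(all(d$p == 1))
  expect_true(all(d$effect_size == 0))
})
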