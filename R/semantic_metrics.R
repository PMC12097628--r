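#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`, clipped to `[-1, 1]` against floating-point
#' overshoot. Identical vectors short-circuit to exactly 1.
#'
#' @param u,v Numeric vectors of equal dimensionality, both non-zero.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must share dimensionality")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for a zero vector")
  if (identical(u, v)) return(1)
  clip_cosine(sum(u * v) / (nu * nv))
}

#' Local semantic similarity (mean over consecutive pairs)
#'
#' The mean cosine similarity over the `n - 1` consecutive token pairs of an
#' embedded transcript. With static word embeddings over content words this
#' tracks conceptual coherence between neighbours; with contextual subword
#' embeddings it tracks referential coherence.
#'
#' @param seq An [embedded_sequence()].
#' @return The mean consecutive cosine, or `NA_real_` when fewer than 2
#'   vectors are available (recorded as a missing feature, not an error).
#' @export
local_similarity <- function(seq) {
  m <- seq$vectors
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  u <- unit_rows(m)
  sims <- rowSums(u[-n, , drop = FALSE] * u[-1, , drop = FALSE])
  mean(clip_cosine(sims))
}

#' Global semantic similarity (mean over all unordered pairs)
#'
#' The mean cosine similarity over all `n(n-1)/2` unordered token pairs
#' `i < j`. Self-pairs are excluded and each unordered pair is counted once,
#' matching the `2/(n(n-1))` normalizer. A contracted semantic space (tokens
#' crowded together) raises this value.
#'
#' @param seq An [embedded_sequence()].
#' @return The mean pairwise cosine, or `NA_real_` when `n < 2`.
#' @export
global_similarity <- function(seq) {
  m <- seq$vectors
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  u <- unit_rows(m)
  s <- tcrossprod(u)
  clip_cosine((sum(s) - sum(diag(s))) / (n * (n - 1)))
}

#' Cross-entropy and perplexity of a token log-probability sequence
#'
#' Cross-entropy `H = -(1/n) * sum(log2 p(t_i | t_1..i-1))` in bits (natural-
#' log entries are converted by dividing by `ln 2`), and perplexity
#' `PPL = 2^H` — the effective number of equally likely outcomes. The
#' computation asserts base-invariance internally: `exp(H_nats)` must equal
#' `2^(H_bits)` to within 1e-10 relative.
#'
#' @param lp A [token_logprobs()] object with at least one entry.
#' @return A list with `cross_entropy` (bits, >= 0) and `ppl` (>= 1).
#' @export
perplexity <- function(lp) {
  stopifnot(inherits(lp, "token_logprobs"))
  x <- lp$logprobs
  if (length(x) == 0) stop("at least one log-probability entry is required")
  if (any(x > 0)) stop("log-probabilities must be <= 0")
  bits <- if (lp$base == "e") x / log(2) else x
  h <- -mean(bits)
  ppl <- 2^h
  h_nats <- h * log(2)
  if (abs(exp(h_nats) - ppl) > 1e-10 * max(ppl, 1))
    stop("base-invariance violated")        # unreachable unless arithmetic breaks
  list(cross_entropy = h, ppl = ppl)
}

#' Picture-speech alignment
#'
#' Mean cosine similarity between each sentence vector and the stimulus
#' picture vector in the shared bimodal space.
#'
#' @param pair A [bimodal_pair()].
#' @return Mean cosine in `[-1, 1]`, or `NA_real_` for zero sentences.
#' @export
bimodal_alignment <- function(pair) {
  stopifnot(inherits(pair, "bimodal_pair"))
  sv <- pair$sentence_vectors
  if (nrow(sv) == 0) return(NA_real_)
  img <- pair$image_vector
  sims <- vapply(seq_len(nrow(sv)), function(i)
    cosine_similarity(sv[i, ], img), numeric(1))
  mean(sims)
}

#' Extract the full semantic feature row for one transcript
#'
#' Composes the metric operations: conceptual similarities (static
#' embeddings) are computed on content words only; referential similarities,
#' and perplexity, on the full subword sequence (no words removed there);
#' picture alignment on the sentence list; averaged dependency distance on
#' the supplied parses. Degenerate inputs yield missing markers per field —
#' a cohort run never aborts for one bad transcript.
#'
#' @param tok Tokenized transcript from [tokenize()].
#' @param providers List with elements `static`, `contextual`, `logprob`,
#'   `bimodal` (any may be `NULL` to skip its metrics).
#' @param image_id Stimulus key for the bimodal track.
#' @param parses Optional list of dependency parses for the transcript.
#' @return One-row data.frame of counts, TTRs and semantic measures.
#' @export
extract_features <- function(tok, providers, image_id = "stimulus",
                             parses = NULL) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  ft_lsim <- ft_gsim <- bert_lsim <- bert_gsim <- NA_real_
  ppl <- NA_real_; bim <- NA_real_
  if (!is.null(providers$static) && length(tok$content_words) >= 2) {
    seq_ft <- embed_static(tok$content_words, providers$static)
    ft_lsim <- safe(local_similarity(seq_ft))
    ft_gsim <- safe(global_similarity(seq_ft))
  }
  if (!is.null(providers$contextual) && length(tok$subwords) >= 2) {
    seq_bert <- embed_contextual(tok$subwords, providers$contextual)
    bert_lsim <- safe(local_similarity(seq_bert))
    bert_gsim <- safe(global_similarity(seq_bert))
  }
  if (!is.null(providers$logprob) && length(tok$subwords) >= 2)
    ppl <- safe(perplexity(score_token_logprobs(tok$subwords,
                                                providers$logprob))$ppl)
  if (!is.null(providers$bimodal) && length(tok$sentences) >= 1)
    bim <- safe(bimodal_alignment(encode_bimodal(tok$sentences, image_id,
                                                 providers$bimodal)))
  add <- if (!is.null(parses) && length(parses) > 0)
    safe(averaged_dependency_distance(parses)) else NA_real_

  data.frame(
    word_count = length(tok$all_words),
    content_word_count = length(tok$content_words),
    subword_count = length(tok$subwords),
    word_ttr = compute_ttr(tok$all_words),
    content_ttr = compute_ttr(tok$content_words),
    subword_ttr = compute_ttr(tok$subwords),
    ft_lsim = ft_lsim, ft_gsim = ft_gsim,
    bert_lsim = bert_lsim, bert_gsim = bert_gsim,
    ppl = ppl, bimodal_sim = bim, add = add)
}
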