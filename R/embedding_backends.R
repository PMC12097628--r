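# Provider contracts for the four embedding backends, plus deterministic
# fixture implementations so the whole pipeline runs offline.
#
# A provider is a plain list with a `type` field; the embed_*/score_*/encode_*
# operations dispatch on it. Adapters for real models (fastText vectors,
# transformer checkpoints, vision-language encoders) satisfy the same
# contract: they only need to produce the same container types.

#' Ordered embedding sequence container
#'
#' Holds one vector per token of a transcript, all of one dimensionality.
#'
#' @param vectors Numeric matrix, one row per token (0 rows allowed).
#' @param tokens Character vector parallel to the rows.
#' @return An `embedded_sequence` object.
#' @export
embedded_sequence <- function(vectors, tokens) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(tokens))
    stop("vectors and tokens must have equal length")
  if (nrow(vectors) > 0 && ncol(vectors) < 2)
    stop("embedding dimensionality must be >= 2")
  structure(list(vectors = vectors, tokens = tokens),
            class = "embedded_sequence")
}

#' @export
length.embedded_sequence <- function(x) nrow(x$vectors)

#' Per-token conditional log-probability container
#'
#' One entry per *predicted* token (the first token of a sequence has no
#' preceding context and is excluded). All entries must be <= 0.
#'
#' @param logprobs Numeric vector of log-probabilities.
#' @param base `"2"` or `"e"` — the logarithm base of the entries.
#' @return A `token_logprobs` object.
#' @export
token_logprobs <- function(logprobs, base = c("2", "e")) {
  base <- match.arg(base)
  if (any(logprobs > 0)) stop("log-probabilities must be <= 0")
  structure(list(logprobs = as.numeric(logprobs), base = base),
            class = "token_logprobs")
}

#' Sentence/image embedding pair container
#'
#' @param sentence_vectors Numeric matrix, one row per sentence.
#' @param image_vector Numeric vector of the same dimensionality.
#' @return A `bimodal_pair` object.
#' @export
bimodal_pair <- function(sentence_vectors, image_vector) {
  sentence_vectors <- as.matrix(sentence_vectors)
  if (ncol(sentence_vectors) != length(image_vector))
    stop("sentence vectors and image vector must share dimensionality")
  structure(list(sentence_vectors = sentence_vectors,
                 image_vector = as.numeric(image_vector)),
            class = "bimodal_pair")
}

#' Deterministic static-embedder fixture
#'
#' Maps every word to a pseudo-random unit vector seeded by a hash of the
#' word, so identical words always receive identical vectors regardless of
#' position or call order — the defining property of a static embedding.
#'
#' @param d Embedding dimensionality (>= 2).
#' @param seed Provider seed; different seeds give unrelated embeddings.
#' @export
static_embedder <- function(d = 32, seed = 1) {
  stopifnot(d >= 2)
  structure(list(type = "static_fixture", d = d, seed = seed),
            class = "semspace_provider")
}

#' Embed words with a static provider
#'
#' @param words Character vector (possibly empty).
#' @param provider A static-embedder provider.
#' @return An [embedded_sequence()] with one vector per word, order preserved.
#' @export
embed_static <- function(words, provider) {
  d <- provider$d
  if (length(words) == 0)
    return(embedded_sequence(matrix(numeric(0), 0, d), character(0)))
  uniq <- unique(words)
  vecs <- t(vapply(uniq, function(w)
    seeded_unit_vector(substream_seed(provider$seed, paste0("w:", w)), d),
    numeric(d)))
  embedded_sequence(vecs[match(words, uniq), , drop = FALSE], words)
}

#' Deterministic contextual-embedder fixture
#'
#' Each token's vector is its hash-seeded base vector blended with the base
#' vectors of its immediate neighbours, so the same token in different
#' contexts yields different vectors (contextuality), while the whole map
#' stays a pure function of the input sequence. Sequences longer than
#' `context_limit` are encoded in overlapping windows (50% overlap); a token
#' covered by several windows keeps the vector from the window where it is
#' most central, preserving one vector per token.
#'
#' @param d Embedding dimensionality.
#' @param seed Provider seed.
#' @param context_limit Maximum tokens encoded jointly.
#' @param neighbor_weight Weight of each neighbour base vector in the blend.
#' @export
contextual_embedder <- function(d = 32, seed = 1, context_limit = 512,
                                neighbor_weight = 0.5) {
  stopifnot(d >= 2, context_limit >= 2)
  structure(list(type = "contextual_fixture", d = d, seed = seed,
                 context_limit = context_limit,
                 neighbor_weight = neighbor_weight),
            class = "semspace_provider")
}

# blend base vectors within one window [lo, hi] (1-based, inclusive)
.ctx_window <- function(base, lo, hi, w) {
  n <- hi - lo + 1L
  out <- base[lo:hi, , drop = FALSE]
  if (n > 1) {
    prev <- rbind(0, base[lo:(hi - 1L), , drop = FALSE])
    nxt <- rbind(base[(lo + 1L):hi, , drop = FALSE], 0)
    out <- out + w * prev + w * nxt
  }
  unit_rows(out)
}

#' Embed subwords with a contextual provider
#'
#' @param subwords Character vector of tokens.
#' @param provider A contextual-embedder provider.
#' @return An [embedded_sequence()], one vector per input token.
#' @export
embed_contextual <- function(subwords, provider) {
  d <- provider$d
  n <- length(subwords)
  if (n == 0)
    return(embedded_sequence(matrix(numeric(0), 0, d), character(0)))
  uniq <- unique(subwords)
  base_u <- t(vapply(uniq, function(w)
    seeded_unit_vector(substream_seed(provider$seed, paste0("c:", w)), d),
    numeric(d)))
  base <- base_u[match(subwords, uniq), , drop = FALSE]

  L <- provider$context_limit
  w <- provider$neighbor_weight
  if (n <= L) {
    vecs <- .ctx_window(base, 1L, n, w)
  } else {
    stride <- max(1L, L %/% 2L)
    starts <- unique(c(seq(1L, n - L + 1L, by = stride), n - L + 1L))
    vecs <- matrix(NA_real_, n, d)
    best <- rep(Inf, n)          # distance of token to its window centre
    for (s in starts) {
      e <- s + L - 1L
      wm <- .ctx_window(base, s, e, w)
      centre <- (s + e) / 2
      idx <- s:e
      dist <- abs(idx - centre)
      take <- dist < best[idx]
      vecs[idx[take], ] <- wm[take, , drop = FALSE]
      best[idx[take]] <- dist[take]
    }
  }
  embedded_sequence(vecs, subwords)
}

#' Autoregressive token-probability fixture
#'
#' Three fixture behaviours:
#' * `"uniform"` — every conditional probability is `1/k` (cross-entropy
#'   `log2(k)` bits exactly);
#' * `"deterministic"` — probability 1 on every true token (cross-entropy 0);
#' * `"entropy"` — per-token surprisal drawn from a Gamma distribution with
#'   mean `entropy_bits`, so the expected cross-entropy is a controlled
#'   constant (variance `entropy_bits^2 / shape`).
#'
#' @param kind Fixture behaviour (see above).
#' @param entropy_bits Target mean surprisal, bits/token (`"entropy"` kind).
#' @param k Alphabet size (`"uniform"` kind).
#' @param shape Gamma shape for the surprisal draw.
#' @param seed Provider seed.
#' @export
logprob_provider <- function(kind = c("entropy", "uniform", "deterministic"),
                             entropy_bits = 5, k = 6, shape = 4, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(entropy_bits >= 0, k >= 1, shape > 0)
  structure(list(type = paste0("logprob_", kind), kind = kind,
                 entropy_bits = entropy_bits, k = k, shape = shape,
                 seed = seed),
            class = "semspace_provider")
}

#' Score a token sequence with an autoregressive provider
#'
#' Entry `i` of the result is the log-probability of token `i + 1` given
#' tokens `1..i`: the first token has no preceding context and is excluded,
#' so a sequence of `n` tokens yields `n - 1` predictions.
#'
#' @param subwords Character vector, length >= 2.
#' @param provider A log-probability provider.
#' @return A [token_logprobs()] object (base 2).
#' @export
score_token_logprobs <- function(subwords, provider) {
  n <- length(subwords)
  if (n < 2) stop("at least 2 tokens are required for a conditional prediction")
  m <- n - 1L
  lp <- switch(provider$kind,
    uniform = rep(-log2(provider$k), m),
    deterministic = rep(0, m),
    entropy = {
      if (provider$entropy_bits == 0) rep(0, m) else {
        s <- substream_seed(provider$seed,
                            paste0("lp:", paste(subwords, collapse = "\u1f")))
        withr::with_seed(s,
          -stats::rgamma(m, shape = provider$shape,
                         rate = provider$shape / provider$entropy_bits))
      }
    })
  token_logprobs(lp, base = "2")
}

#' Bimodal (image/sentence) encoder fixture
#'
#' The image vector is a fixed seeded unit vector per `image_id`; each
#' sentence vector is the image vector mixed with hash-seeded unit noise at a
#' configurable alignment level `a`:
#' `normalize(a * image + (1 - a) * noise)`. At `a = 1` every sentence vector
#' equals the image vector; at `a = 0` sentence vectors are independent of it
#' (expected cosine ~ 0 at large `d`).
#'
#' @param d Shared embedding dimensionality.
#' @param alignment Mixing level in `[0, 1]`.
#' @param seed Provider seed.
#' @export
bimodal_encoder <- function(d = 64, alignment = 0.5, seed = 1) {
  stopifnot(d >= 2, alignment >= 0, alignment <= 1)
  structure(list(type = "bimodal_fixture", d = d, alignment = alignment,
                 seed = seed),
            class = "semspace_provider")
}

#' Encode sentences and a picture into a shared space
#'
#' @param sentences Non-empty character vector.
#' @param image_id Opaque key identifying the stimulus picture.
#' @param provider A bimodal provider.
#' @return A [bimodal_pair()].
#' @export
encode_bimodal <- function(sentences, image_id, provider) {
  if (length(sentences) == 0) stop("at least one sentence is required")
  d <- provider$d
  a <- provider$alignment
  img <- seeded_unit_vector(substream_seed(provider$seed,
                                           paste0("img:", image_id)), d)
  sv <- t(vapply(seq_along(sentences), function(i) {
    noise <- seeded_unit_vector(
      substream_seed(provider$seed, paste0("s:", i, ":", sentences[i])), d)
    unit_vector(a * img + (1 - a) * noise)
  }, numeric(d)))
  bimodal_pair(sv, img)
}
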