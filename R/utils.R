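# Internal deterministic hashing and seed-substream helpers.
#
# Fixture providers and the cohort generator need reproducible, input-keyed
# randomness that is independent of call order. Strings are hashed with a
# polynomial rolling hash kept below 2^31 (double-precision arithmetic stays
# exact well below 2^53 with a multiplier of 31), and per-item seeds are
# derived by hashing "<seed>/<key>" so one global seed fans out into
# order-independent substreams.

.HASH_MOD <- 2147483587  # largest prime below 2^31 minus a margin

str_hash <- function(s, salt = 0L) {
  stopifnot(is.character(s), length(s) == 1L)
  x <- utf8ToInt(enc2utf8(s))
  h <- (2166136 + salt) %% .HASH_MOD
  for (cc in x) h <- (h * 31 + cc) %% .HASH_MOD
  as.integer(h)
}

substream_seed <- function(seed, key) {
  str_hash(paste(seed, key, sep = "/"))
}

# Unit-normalize rows of a matrix; errors on zero rows.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero vector cannot be normalized")
  m / nrm
}

unit_vector <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero vector cannot be normalized")
  v / nrm
}

# Random unit vector keyed by an integer seed (RNG state is restored).
seeded_unit_vector <- function(seed, d) {
  withr::with_seed(seed, unit_vector(stats::rnorm(d)))
}

clip_cosine <- function(x) pmin(1, pmax(-1, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
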