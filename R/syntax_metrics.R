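#' Dependency parse container for one sentence
#'
#' @param tokens Data frame with columns `position` (1-based linear
#'   position), `form` (surface string), `head` (position of the head, 0 for
#'   the sentence root), `punct` (logical punctuation flag).
#' @return A `dependency_parse` object.
#' @export
dependency_parse <- function(tokens) {
  tokens <- as.data.frame(tokens)
  stopifnot(all(c("position", "form", "head", "punct") %in% names(tokens)))
  if (sum(tokens$head == 0) != 1) stop("exactly one ROOT per sentence")
  nonroot <- tokens$head != 0
  if (!all(tokens$head[nonroot] %in% tokens$position))
    stop("head positions must reference existing tokens")
  if (any(tokens$head == tokens$position)) stop("self-loop in parse")
  structure(list(tokens = tokens), class = "dependency_parse")
}

#' Dependency arc distances of one sentence
#'
#' For every non-ROOT token whose own punctuation flag is off and whose
#' head's flag is off, emits the absolute difference of the two 1-based
#' linear positions (`|position(token) - position(head)|`), computed on the
#' *original* positions — arcs touching punctuation are skipped but the
#' remaining words are not renumbered. In "Mary ate the juicy red sweet
#' apple", where *apple* (position 7) depends on *ate* (position 2), the
#' distance is 5.
#'
#' The non-default `style = "words_between"` variant instead counts the
#' number of words strictly between the two dependents (distance minus one).
#'
#' @param parse A [dependency_parse()].
#' @param style `"positions"` (default) or `"words_between"`.
#' @return Integer vector of arc distances (possibly empty).
#' @export
arc_distances <- function(parse, style = c("positions", "words_between")) {
  style <- match.arg(style)
  tk <- parse$tokens
  punct_at <- tk$punct[match(tk$head, tk$position)]   # head's punct flag
  keep <- tk$head != 0 & !tk$punct & !punct_at
  d <- abs(tk$position[keep] - tk$head[keep])
  if (style == "words_between") d <- d - 1L
  as.integer(d)
}

#' Averaged dependency distance (ADD) of a transcript
#'
#' Pools the arc distances of every sentence and returns their mean — a
#' formal syntactic-complexity index (longer arcs = deeper, more demanding
#' structure).
#'
#' @param parses List of [dependency_parse()] objects (>= 1).
#' @param style Passed to [arc_distances()].
#' @return Mean arc distance (>= 1 for the default style), or `NA_real_`
#'   when no arcs survive punctuation exclusion.
#' @export
averaged_dependency_distance <- function(parses,
                                         style = c("positions", "words_between")) {
  style <- match.arg(style)
  if (inherits(parses, "dependency_parse")) parses <- list(parses)
  stopifnot(length(parses) >= 1)
  d <- unlist(lapply(parses, arc_distances, style = style), use.names = FALSE)
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Read dependency parses from a CoNLL-U file
#'
#' Parses the standard 10-column format; sentences are separated by blank
#' lines, comment lines start with `#`, and multiword/empty-node lines
#' (ids containing `-` or `.`) are skipped. The punctuation flag is derived
#' from the UPOS column (`PUNCT`).
#'
#' @param path Path to a `.conllu` file.
#' @return List of [dependency_parse()] objects, one per sentence.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parses <- list()
  buf <- list()
  flush <- function() {
    if (length(buf) == 0) return(invisible())
    df <- do.call(rbind, buf)
    parses[[length(parses) + 1]] <<- dependency_parse(df)
    buf <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed CoNLL-U line: ", ln)
    if (grepl("[-.]", f[1])) next
    buf[[length(buf) + 1]] <- data.frame(
      position = as.integer(f[1]), form = f[2],
      head = as.integer(f[7]), punct = identical(f[4], "PUNCT"))
  }
  flush()
  parses
}

#' Write dependency parses to a CoNLL-U file
#'
#' Inverse of [read_conllu()] for the columns this package uses; the
#' remaining columns are filled with `_` (and UPOS with `PUNCT`/`X`).
#'
#' @param parses List of [dependency_parse()] objects.
#' @param path Output path.
#' @export
write_conllu <- function(parses, path) {
  if (inherits(parses, "dependency_parse")) parses <- list(parses)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in parses) {
    tk <- p$tokens
    for (i in seq_len(nrow(tk))) {
      upos <- if (tk$punct[i]) "PUNCT" else "X"
      rel <- if (tk$head[i] == 0) "root" else "dep"
      writeLines(paste(tk$position[i], tk$form[i], "_", upos, "_", "_",
                       tk$head[i], rel, "_", "_", sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
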