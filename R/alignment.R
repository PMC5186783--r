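# Exact pairwise alignment and local-alignment statistics.
#
# The survey's reference search path is optimal Smith-Waterman local
# alignment with affine gaps (BLOSUM62, gap existence 11, extension 1 --
# the familiar BLASTp defaults), not a heuristic seed-and-extend search,
# so that every score is deterministic and checkable against enumeration.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Alignment scoring parameters
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul constants used to convert local-alignment scores to
#' e-values. Defaults are BLOSUM62 with gap open 11 / extend 1 and the
#' published ungapped BLOSUM62 constants K = 0.041, lambda = 0.267.
#' The ambiguity residue X scores 0 against everything.
#'
#' @param substitution_matrix Square integer matrix with row/column names
#'   covering the 20 canonical residues plus `X`. Default: BLOSUM62 with
#'   the X row/column zeroed.
#' @param gap_open,gap_extend Positive integer penalties; a gap of length
#'   L costs `gap_open + L * gap_extend`. `gap_extend` must not exceed
#'   `gap_open`.
#' @param K,lambda Karlin-Altschul prefactor and scale (lambda per score
#'   unit); both must be positive.
#' @return A list of class `alignment_params`.
#' @export
#' @examples
#' p <- alignment_params()
#' p$gap_open
alignment_params <- function(substitution_matrix = NULL,
                             gap_open = 11L, gap_extend = 1L,
                             K = 0.041, lambda = 0.267) {
  if (is.null(substitution_matrix)) substitution_matrix <- default_submat()
  m <- substitution_matrix[AA_ALPHABET, AA_ALPHABET, drop = FALSE]
  storage.mode(m) <- "integer"
  if (!isTRUE(all.equal(m, t(m)))) abort("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (gap_open <= 0L || gap_extend <= 0L) abort("gap penalties must be positive")
  if (gap_extend > gap_open) abort("gap_extend must not exceed gap_open")
  if (K <= 0 || lambda <= 0) abort("K and lambda must be positive")
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda),
            class = "alignment_params")
}

# BLOSUM62 restricted to the 21-letter alphabet, X neutralised to 0.
default_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
      m["X", ] <- 0L
      m[, "X"] <- 0L
      storage.mode(m) <- "integer"
      cache <<- m
    }
    cache
  }
})

encode_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    abort("sequence must be a non-empty string")
  }
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(strsplit(x, "", fixed = TRUE)[[1]][is.na(idx)])
    abort(paste0("sequence contains residues outside the 20+X alphabet: ",
                 paste(bad, collapse = ", ")))
  }
  idx
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment with affine gap penalties. The score is the
#' maximum over all local alignments (0 when no pair of segments scores
#' positively). Traceback tie-breaking is fixed (diagonal over gap, gap in
#' the second sequence over gap in the first) so output is deterministic.
#'
#' @param a,b Amino-acid strings over the 20 canonical residues plus X.
#' @param params An [alignment_params()] object.
#' @return A list with `score` (integer) and `alignment`, a two-element
#'   character vector of gapped aligned segments (empty strings when the
#'   optimal local alignment is empty).
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "HEAGAWGHEE")$score
local_align <- function(a, b, params = alignment_params()) {
  ia <- encode_seq(a); ib <- encode_seq(b)
  res <- .sw_align(ia, ib, params$substitution_matrix,
                   params$gap_open, params$gap_extend)
  ops <- strsplit(res$ops, "", fixed = TRUE)[[1]]
  if (res$score <= 0L || length(ops) == 0L) {
    return(list(score = as.integer(res$score),
                alignment = c(a = "", b = "")))
  }
  ach <- strsplit(a, "", fixed = TRUE)[[1]]
  bch <- strsplit(b, "", fixed = TRUE)[[1]]
  ai <- res$a_start; bi <- res$b_start
  arow <- character(length(ops)); brow <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      arow[k] <- ach[ai]; brow[k] <- bch[bi]; ai <- ai + 1L; bi <- bi + 1L
    } else if (ops[k] == "D") {
      arow[k] <- ach[ai]; brow[k] <- "-"; ai <- ai + 1L
    } else {
      arow[k] <- "-"; brow[k] <- bch[bi]; bi <- bi + 1L
    }
  }
  list(score = as.integer(res$score),
       alignment = c(a = paste(arow, collapse = ""),
                     b = paste(brow, collapse = "")))
}

#' Local alignment score only
#'
#' @inheritParams local_align
#' @return Integer score.
#' @export
local_align_score <- function(a, b, params = alignment_params()) {
  .sw_score(encode_seq(a), encode_seq(b), params$substitution_matrix,
            params$gap_open, params$gap_extend)
}

#' Optimal global alignment score
#'
#' Needleman-Wunsch with affine gaps; end gaps are penalised (true global
#' alignment).
#'
#' @inheritParams local_align
#' @return Integer score.
#' @export
global_align_score <- function(a, b, params = alignment_params()) {
  .nw_score(encode_seq(a), encode_seq(b), params$substitution_matrix,
            params$gap_open, params$gap_extend)
}

#' Karlin-Altschul e-value for a local alignment score
#'
#' E = K * m * n * exp(-lambda * S), with m the query length and n the
#' searched database size in residues. Valid for comparing hits within one
#' run under one parameter set; the constants default to the published
#' ungapped BLOSUM62 values.
#'
#' @param score Non-negative alignment score.
#' @param query_len Query length in residues (positive).
#' @param db_residues Total residues searched (positive).
#' @param params An [alignment_params()] object supplying K and lambda.
#' @return The expected number of chance hits at or above `score`.
#' @export
#' @examples
#' karlin_altschul_evalue(100, 100, 10000)
karlin_altschul_evalue <- function(score, query_len, db_residues,
                                   params = alignment_params()) {
  if (any(query_len <= 0) || any(db_residues <= 0)) {
    abort("query_len and db_residues must be positive")
  }
  if (any(score < 0)) abort("score must be non-negative")
  params$K * query_len * db_residues * exp(-params$lambda * score)
}
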