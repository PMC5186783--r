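# Brute-force alignment oracles: exhaustive enumeration over all
# affine-gap alignments, independent of the dynamic-programming path.
# Gap cost definition shared with the implementation (open + L * extend);
# the enumeration itself shares nothing with the DP.

oracle_global <- function(a, b, params = alignment_params()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  sm <- params$substitution_matrix
  go <- params$gap_open
  ge <- params$gap_extend
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, 0L, score + sm[A[i], B[j]])
    }
    if (i <= length(A)) {
      rec(i + 1L, j, 1L, score - (if (state == 1L) ge else go + ge))
    }
    if (j <= length(B)) {
      rec(i, j + 1L, 2L, score - (if (state == 2L) ge else go + ge))
    }
  }
  rec(1L, 1L, 0L, 0)
  best
}

# Optimal local score: the best alignment of any substring pair (an
# optimal local alignment never starts or ends in a gap, so maximising
# oracle_global over all substring pairs covers it), or 0 for the empty
# alignment.
oracle_local <- function(a, b, params = alignment_params()) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      best <- max(best, oracle_global(sa, substr(b, j1, j2), params))
    }
  }
  best
}

# all sequences of the given lengths over an alphabet
enumerate_peptides <- function(lengths, alphabet = c("A", "R", "N", "D")) {
  unlist(lapply(lengths, function(l) {
    apply(do.call(expand.grid, rep(list(alphabet), l)), 1, paste,
          collapse = "")
  }), use.names = FALSE)
}

random_peptide <- function(len, alphabet = c("A", "R", "N", "D")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
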