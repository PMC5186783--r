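# Thresholded family search and reciprocal-best-hit confirmation.
#
# Search is exact local alignment of every query against every target
# protein; a target is a hit for a family when its e-value against the
# family's best-scoring query passes the family threshold. RBH
# confirmation then requires full reciprocity: the hit protein's best
# partner in the reference proteome must be the query, and the query's
# best partner in the genome must be the hit protein. Ties break by
# higher score, then lower e-value, then lexicographically smallest
# protein id.

encode_all <- function(seqs) lapply(seqs, encode_seq)

score_matrix <- function(query_seqs, target_seqs, params) {
  .sw_score_matrix(encode_all(query_seqs), encode_all(target_seqs),
                   params$substitution_matrix, params$gap_open,
                   params$gap_extend)
}

# index of the best column per the tie-break (max value, then smallest id)
best_by_tiebreak <- function(scores, ids) {
  top <- max(scores)
  cand <- which(scores == top)
  cand[order(ids[cand])][1L]
}

#' Search one family's queries against a genome
#'
#' @param family Family name present in `panel`.
#' @param genome A `genome` object.
#' @param panel Query panel tibble (one or more query rows per family).
#' @param params [alignment_params()].
#' @return Hits tibble (`family`, `genome_id`, `protein_id`,
#'   `best_query_id`, `score`, `evalue`, `rbh`) sorted by ascending
#'   e-value then protein id; `rbh` is `NA` until confirmed. Empty tibble
#'   when nothing passes the family threshold.
#' @export
search_family <- function(family, genome, panel = default_query_panel(),
                          params = alignment_params()) {
  fam <- panel[panel$family == family, , drop = FALSE]
  if (nrow(fam) == 0L) abort(paste0("family not in panel: ", family))
  if (nrow(genome$proteins) == 0L) abort("genome has an empty proteome")
  sm <- score_matrix(fam$sequence, genome$proteins$sequence, params)
  db_res <- sum(nchar(genome$proteins$sequence))
  hits <- purrr::map(seq_len(ncol(sm)), function(t) {
    qi <- best_by_tiebreak(sm[, t], fam$protein_id)
    ev <- karlin_altschul_evalue(sm[qi, t], nchar(fam$sequence[qi]),
                                 db_res, params)
    tibble(family = family, genome_id = genome$genome_id,
           protein_id = genome$proteins$protein_id[t],
           best_query_id = fam$protein_id[qi],
           score = sm[qi, t], evalue = ev)
  }) |> list_rbind()
  hits <- hits[hits$evalue <= fam$threshold[1L], , drop = FALSE]
  hits$rbh <- rep(NA, nrow(hits))
  arrange(hits, .data$evalue, .data$protein_id)
}

#' Confirm a hit by full reciprocal-best-hit
#'
#' True iff the hit protein's best-scoring partner in the reference
#' proteome is the original query AND the query's best-scoring partner in
#' the genome proteome is the hit protein. The relation is symmetric in
#' the two proteomes.
#'
#' @param hit One-row hits tibble (or list) with `protein_id` and
#'   `best_query_id`.
#' @param genome The searched `genome`.
#' @param reference_proteome Tibble with `protein_id`, `sequence` — the
#'   proteome the queries came from (see
#'   [default_reference_proteome()]).
#' @param params [alignment_params()].
#' @return Logical scalar.
#' @export
confirm_rbh <- function(hit, genome, reference_proteome,
                        params = alignment_params()) {
  pid <- hit$protein_id
  qid <- hit$best_query_id
  prot <- genome$proteins$sequence[genome$proteins$protein_id == pid]
  if (length(prot) != 1L) abort(paste0("hit protein not in genome: ", pid))
  qseq <- reference_proteome$sequence[reference_proteome$protein_id == qid]
  if (length(qseq) != 1L) abort(paste0("query not in reference proteome: ", qid))
  back <- score_matrix(list(prot), reference_proteome$sequence, params)[1L, ]
  best_ref <- reference_proteome$protein_id[
    best_by_tiebreak(back, reference_proteome$protein_id)]
  if (!identical(best_ref, qid)) return(FALSE)
  fwd <- score_matrix(list(qseq), genome$proteins$sequence, params)[1L, ]
  best_tgt <- genome$proteins$protein_id[
    best_by_tiebreak(fwd, genome$proteins$protein_id)]
  identical(best_tgt, pid)
}

#' Scan a genome against the whole query panel
#'
#' Runs [search_family()] for every family and confirms reciprocal best
#' hits in one pass (score matrices are computed once and reused). Each
#' hit also records `back_family`: the family of the hit protein's best
#' reference-proteome partner (`NA` when that partner is a shadow
#' relative outside the searched panel), which downstream presence
#' calling uses to count family copies.
#'
#' @param genome A `genome` object.
#' @param panel Query panel tibble.
#' @param reference_proteome RBH back-search proteome; defaults to
#'   [default_reference_proteome()] of the panel.
#' @param params [alignment_params()].
#' @return Hits tibble with columns `family`, `genome_id`, `protein_id`,
#'   `best_query_id`, `score`, `evalue`, `rbh`, `back_family`.
#' @export
scan_genome <- function(genome, panel = default_query_panel(),
                        reference_proteome = default_reference_proteome(panel),
                        params = alignment_params()) {
  if (nrow(genome$proteins) == 0L) abort("genome has an empty proteome")
  prot_ids <- genome$proteins$protein_id
  prot_seqs <- genome$proteins$sequence
  db_res <- sum(nchar(prot_seqs))
  sm <- score_matrix(panel$sequence, prot_seqs, params)   # queries x targets

  # per family, best query per target and threshold filter
  hits <- purrr::map(unique(panel$family), function(fam) {
    rows <- which(panel$family == fam)
    sub <- sm[rows, , drop = FALSE]
    per_t <- purrr::map(seq_along(prot_ids), function(t) {
      qi <- best_by_tiebreak(sub[, t], panel$protein_id[rows])
      qrow <- rows[qi]
      tibble(family = fam, genome_id = genome$genome_id,
             protein_id = prot_ids[t],
             best_query_id = panel$protein_id[qrow],
             score = sm[qrow, t],
             evalue = karlin_altschul_evalue(
               sm[qrow, t], nchar(panel$sequence[qrow]), db_res, params))
    }) |> list_rbind()
    per_t[per_t$evalue <= panel$threshold[rows[1L]], , drop = FALSE]
  }) |> list_rbind()
  if (nrow(hits) == 0L) {
    return(tibble(family = character(), genome_id = character(),
                  protein_id = character(), best_query_id = character(),
                  score = integer(), evalue = double(), rbh = logical(),
                  back_family = character()))
  }

  # back-search: candidate hit proteins against the reference proteome
  cand <- unique(hits$protein_id)
  back <- score_matrix(prot_seqs[match(cand, prot_ids)],
                       reference_proteome$sequence, params)
  best_ref <- vapply(seq_along(cand), function(i) {
    reference_proteome$protein_id[
      best_by_tiebreak(back[i, ], reference_proteome$protein_id)]
  }, character(1))
  names(best_ref) <- cand
  ref_fam <- setNames(reference_proteome$family, reference_proteome$protein_id)

  # forward best target per panel query (reuse the forward matrix)
  best_tgt <- vapply(seq_len(nrow(panel)), function(q) {
    prot_ids[best_by_tiebreak(sm[q, ], prot_ids)]
  }, character(1))
  names(best_tgt) <- panel$protein_id

  hits$back_family <- unname(ref_fam[best_ref[hits$protein_id]])
  hits$rbh <- best_ref[hits$protein_id] == hits$best_query_id &
    best_tgt[hits$best_query_id] == hits$protein_id
  arrange(hits, .data$family, .data$evalue, .data$protein_id)
}
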