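# Fixture builders: tiny genomes assembled in code.

# a genome from named protein sequences laid out left to right on one
# replicon; gaps of `spacing` bp between genes
toy_genome <- function(seqs, genome_id = "toy", strand = NULL,
                       spacing = 150L, habitat = "other",
                       subsection = "unknown") {
  ids <- names(seqs)
  strand <- strand %||% rep("+", length(seqs))
  pos <- 100L
  feats <- list()
  for (i in seq_along(seqs)) {
    nt <- nchar(seqs[[i]]) * 3L + 3L
    feats[[i]] <- tibble::tibble(
      gene_id = ids[i], genome_id = genome_id, replicon_id = "chr",
      start = pos, end = pos + nt, strand = strand[i], protein_id = ids[i])
    pos <- pos + nt + spacing
  }
  genome(genome_id,
         tibble::tibble(protein_id = ids, genome_id = genome_id,
                        sequence = unname(unlist(seqs))),
         purrr::list_rbind(feats),
         habitat = habitat, subsection = subsection)
}

# presence tibble from a named status vector (families not listed are
# absent); members default to "<genome>_<family>"
toy_presence <- function(status, genome_id = "toy",
                         panel = default_query_panel()) {
  fams <- unique(panel$family)
  planted <- fams %in% names(status)
  members <- purrr::map(fams, function(f) {
    if (f %in% names(status)) paste0(genome_id, "_", f) else character()
  })
  tibble::tibble(
    genome_id = genome_id, family = fams,
    status = ifelse(planted, unname(status[fams]), "absent"),
    copy_number = ifelse(planted, 1L, 0L),
    member_protein_ids = members)
}

# conserved/degenerate motif report rows for a family
toy_motif_report <- function(family, verdict = "conserved",
                             genome_id = "toy") {
  tibble::tibble(
    motif_id = paste0(family, "_m"), family = family,
    target_protein_id = paste0(genome_id, "_", family),
    reference_position = 1L, target_position = 1L,
    observed_residue = "C", conserved = verdict == "conserved",
    verdict = verdict)
}
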