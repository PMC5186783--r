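# Reference-anchored motif verification. Each motif is a set of 1-based
# residue positions on a reference anchor protein with an allowed residue
# set per position. A target protein is aligned globally to the anchor
# (Needleman-Wunsch, end gaps penalised) and each anchor position is
# transferred through the alignment; a site mapped to a gap, or to a
# residue outside the allowed set (including X), is not conserved.

#' Map reference positions onto a target by global alignment
#'
#' @param reference,target Amino-acid strings.
#' @param params [alignment_params()].
#' @return Integer vector of length `nchar(reference)`: the 1-based
#'   target position aligned to each reference position, or `NA` where
#'   the reference residue aligns to a gap. Strictly increasing over
#'   non-gap entries.
#' @export
global_align_map <- function(reference, target, params = alignment_params()) {
  m <- .nw_map(encode_seq(reference), encode_seq(target),
               params$substitution_matrix, params$gap_open, params$gap_extend)
  m[m == 0L] <- NA_integer_
  m
}

#' Construct a motif definition
#'
#' @param motif_id Identifier.
#' @param family Gene family the motif belongs to.
#' @param reference_id,reference_seq The anchor protein.
#' @param sites Tibble (or data frame) with `position` (1-based index on
#'   the anchor) and `allowed` (string of allowed residues). The anchor's
#'   own residue must be allowed at each site.
#' @param description Free-text description.
#' @return A list of class `motif_definition`.
#' @export
motif_definition <- function(motif_id, family, reference_id, reference_seq,
                             sites, description = "") {
  sites <- as_tibble(sites)
  sites$position <- as.integer(sites$position)
  if (nrow(sites) == 0L) abort(paste0(motif_id, ": motif has no sites"))
  if (any(!nzchar(sites$allowed))) {
    abort(paste0(motif_id, ": empty allowed-residue set"))
  }
  n <- nchar(reference_seq)
  if (any(sites$position < 1L | sites$position > n)) {
    bad <- sites$position[sites$position < 1L | sites$position > n]
    abort(paste0(motif_id, ": site position beyond reference length: ",
                 paste(bad, collapse = ", ")))
  }
  ref_res <- substring(reference_seq, sites$position, sites$position)
  ok <- mapply(grepl, ref_res, paste0("[", sites$allowed, "]"))
  if (!all(ok)) {
    abort(paste0(motif_id, ": reference residue not in allowed set at position ",
                 paste(sites$position[!ok], collapse = ", ")))
  }
  structure(list(motif_id = motif_id, family = family,
                 reference_id = reference_id, reference_seq = reference_seq,
                 sites = sites, description = description),
            class = "motif_definition")
}

#' Check one motif against a target protein
#'
#' @param defn A [motif_definition()].
#' @param target_id,target_seq The protein to check.
#' @param params [alignment_params()].
#' @return Tibble with one row per site: `motif_id`, `family`,
#'   `target_protein_id`, `reference_position`, `target_position` (`NA`
#'   when gapped), `observed_residue` (`-` when gapped), `conserved`, and
#'   the per-protein `verdict` (`conserved` iff every site conserved,
#'   else `degenerate`).
#' @export
check_motif <- function(defn, target_id, target_seq,
                        params = alignment_params()) {
  map <- global_align_map(defn$reference_seq, target_seq, params)
  tpos <- map[defn$sites$position]
  obs <- ifelse(is.na(tpos), "-", substring(target_seq, tpos, tpos))
  conserved <- !is.na(tpos) & obs != "X" &
    mapply(grepl, obs, paste0("[", defn$sites$allowed, "]"))
  tibble(motif_id = defn$motif_id, family = defn$family,
         target_protein_id = target_id,
         reference_position = defn$sites$position,
         target_position = tpos,
         observed_residue = obs,
         conserved = as.logical(conserved),
         verdict = if (all(conserved)) "conserved" else "degenerate")
}

#' Default motif panel anchored to the synthetic query panel
#'
#' Covers the HoxH L1/L2 motifs with the Ni-ligand cysteines (group 3d),
#' HoxY and HoxE/F/U FeS cysteines, HupL L1/L2 (group 2a), HupS FeS
#' cysteines, the O2-tolerant MBH proximal [4Fe3S] signature (six
#' cysteines at anchor positions 17/19/20/115/120/149 plus proline 242)
#' and the group 3b small-subunit 4-cysteine set.
#'
#' @param panel Query panel tibble supplying the anchor sequences.
#' @return List of [motif_definition()] objects.
#' @export
default_motif_panel <- function(panel = default_query_panel()) {
  purrr::imap(default_motif_sites(), function(m, id) {
    ref <- panel[panel$family == m$family, ][1L, ]
    motif_definition(
      motif_id = id, family = m$family,
      reference_id = ref$protein_id, reference_seq = ref$sequence,
      sites = tibble(position = as.integer(names(m$sites)),
                     allowed = unname(m$sites)),
      description = m$description)
  }) |> unname()
}

#' Load a motif panel from a YAML config
#'
#' The config maps each motif id to a reference FASTA path + record id
#' and a list of `"position:allowed"` site entries; every definition is
#' validated against the motif-definition invariants.
#'
#' @param config_path YAML file path; FASTA paths are resolved relative
#'   to its directory.
#' @return List of [motif_definition()] objects.
#' @export
load_motif_panel <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  purrr::imap(cfg$motifs, function(m, id) {
    fa <- read_fasta(file.path(base, m$fasta), genome_id = "panel")
    ref <- fa[fa$protein_id == m$reference_id, ]
    if (nrow(ref) != 1L) {
      abort(paste0(id, ": reference id not found in ", m$fasta))
    }
    parts <- strsplit(unlist(m$sites), ":", fixed = TRUE)
    motif_definition(
      motif_id = id, family = m$family,
      reference_id = ref$protein_id, reference_seq = ref$sequence,
      sites = tibble(position = as.integer(vapply(parts, `[[`, "", 1L)),
                     allowed = vapply(parts, `[[`, "", 2L)),
      description = m$description %||% "")
  }) |> unname()
}

#' Write a motif panel to a YAML config + anchor FASTA
#'
#' @param motifs List of [motif_definition()] objects.
#' @param dir Output directory.
#' @return The config path, invisibly.
#' @export
write_motif_panel <- function(motifs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anchors <- purrr::map(motifs, function(m) {
    tibble(protein_id = m$reference_id, sequence = m$reference_seq)
  }) |> list_rbind() |> distinct()
  write_fasta(anchors, file.path(dir, "motif_anchors_synthetic.faa"))
  cfg <- list(motifs = setNames(purrr::map(motifs, function(m) {
    list(family = m$family, fasta = "motif_anchors_synthetic.faa",
         reference_id = m$reference_id,
         sites = paste0(m$sites$position, ":", m$sites$allowed),
         description = m$description)
  }), purrr::map_chr(motifs, "motif_id")))
  path <- file.path(dir, "motifs.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run every applicable motif check for a genome's confirmed families
#'
#' @param presence Presence tibble from [call_presence()].
#' @param genome The `genome` object.
#' @param motifs Motif panel (list of definitions).
#' @param params [alignment_params()].
#' @return Motif report tibble (site-level rows; empty when no present
#'   family has a motif).
#' @export
check_motif_panel <- function(presence, genome, motifs = default_motif_panel(),
                              params = alignment_params()) {
  seqs <- setNames(genome$proteins$sequence, genome$proteins$protein_id)
  out <- purrr::map(motifs, function(m) {
    row <- presence[presence$family == m$family, , drop = FALSE]
    if (nrow(row) == 0L || row$status[1L] == "absent") return(NULL)
    members <- row$member_protein_ids[[1L]]
    purrr::map(members, function(pid) {
      check_motif(m, pid, seqs[[pid]], params)
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0L) empty_motif_report() else out
}

empty_motif_report <- function() {
  tibble(motif_id = character(), family = character(),
         target_protein_id = character(), reference_position = integer(),
         target_position = integer(), observed_residue = character(),
         conserved = logical(), verdict = character())
}
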