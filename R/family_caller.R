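# From confirmed hits to per-genome family presence and the survey's
# three-criteria capability calls.
#
# The three minimal criteria for a functional hydrogenase: (1) the
# complete structural gene set including the specific endopeptidase,
# (2) the complete hypABCDEF maturation set, (3) conserved catalytic
# residues in the structural subunits.

# structural subunits whose presence requires a motif report
MOTIF_CHECKED_FAMILIES <- c(HOX_STRUCTURAL, "hupS", "hupL",
                            "mbh1_small", "sh3b_delta")

#' Call family presence from confirmed hits
#'
#' A family is `present` when it has at least one RBH-confirmed hit; its
#' copy number counts the distinct hit proteins whose reference-proteome
#' best partner belongs to the family. Families with hits that all fail
#' RBH confirmation are called `absent` (copy number 0) with a logged
#' note — the paralog-rejection path.
#'
#' @param hits Hits tibble from [scan_genome()] (RBH-confirmed).
#' @param genome The scanned `genome`.
#' @param panel Query panel tibble (defines the family universe).
#' @return Presence tibble: `genome_id`, `family`, `status`
#'   (`present`/`absent`; see [apply_motif_downgrade()] for
#'   `present_degenerate`), `copy_number`, `member_protein_ids`
#'   (list-column).
#' @export
call_presence <- function(hits, genome, panel = default_query_panel()) {
  if (nrow(hits) > 0 && any(hits$genome_id != genome$genome_id)) {
    abort("hits reference a different genome")
  }
  fams <- unique(panel$family)
  purrr::map(fams, function(fam) {
    h <- hits[hits$family == fam, , drop = FALSE]
    confirmed <- h[!is.na(h$rbh) & h$rbh, , drop = FALSE]
    in_family <- h[!is.na(h$back_family) & h$back_family == fam, , drop = FALSE]
    if (nrow(confirmed) > 0L) {
      members <- sort(unique(in_family$protein_id))
      tibble(genome_id = genome$genome_id, family = fam, status = "present",
             copy_number = length(members),
             member_protein_ids = list(members))
    } else {
      if (nrow(h) > 0L) {
        inform(paste0(genome$genome_id, ": ", fam, " has ", nrow(h),
                      " hit(s) but none RBH-confirmed; called absent"))
      }
      tibble(genome_id = genome$genome_id, family = fam, status = "absent",
             copy_number = 0L, member_protein_ids = list(character()))
    }
  }) |> list_rbind()
}

#' Downgrade presence calls with degenerate catalytic motifs
#'
#' A family that is present but whose member proteins carry a degenerate
#' motif verdict becomes `present_degenerate` — displayed separately from
#' absence (the barred-square state), and not counted towards complete
#' gene sets.
#'
#' @param presence Presence tibble from [call_presence()].
#' @param motif_reports Motif report tibble from [check_motif_panel()].
#' @return Presence tibble with updated `status`.
#' @export
apply_motif_downgrade <- function(presence, motif_reports) {
  if (nrow(motif_reports) == 0L) return(presence)
  bad <- motif_reports |>
    group_by(.data$family, .data$target_protein_id) |>
    summarise(degenerate = any(.data$verdict == "degenerate"),
              .groups = "drop") |>
    filter(.data$degenerate)
  presence |>
    mutate(status = ifelse(
      .data$status == "present" &
        purrr::map2_lgl(.data$family, .data$member_protein_ids, function(f, m) {
          any(bad$family == f & bad$target_protein_id %in% m)
        }),
      "present_degenerate", .data$status))
}

presence_of <- function(presence, fams) {
  s <- setNames(presence$status, presence$family)[fams]
  s[is.na(s)] <- "absent"
  s
}

#' Complete hox gene set?
#'
#' True iff hoxE, hoxF, hoxU, hoxY, hoxH and the endopeptidase hoxW are
#' all present (a degenerate call does not count as complete).
#'
#' @param presence One genome's presence tibble.
#' @return Logical scalar.
#' @export
complete_hox <- function(presence) {
  all(presence_of(presence, HOX_SYSTEM) == "present")
}

#' Complete hup gene set (hupS, hupL and the peptidase hupW)?
#' @inheritParams complete_hox
#' @return Logical scalar.
#' @export
complete_hup <- function(presence) {
  all(presence_of(presence, HUP_SYSTEM) == "present")
}

#' Complete hypABCDEF maturation set?
#' @inheritParams complete_hox
#' @return Logical scalar.
#' @export
complete_hyp <- function(presence) {
  all(presence_of(presence, HYP_SYSTEM) == "present")
}

#' Potentially nitrogen-fixing?
#'
#' True iff nifH, nifD, nifK, nifB, nifE and nifN are present. The
#' nifU/nifS/nifV genes are dispensable and ignored.
#'
#' @inheritParams complete_hox
#' @return Logical scalar.
#' @export
call_nitrogen_fixing <- function(presence) {
  all(presence_of(presence, NIF_ESSENTIAL) == "present")
}

motifs_conserved <- function(presence, motif_reports, fams) {
  pres <- presence[presence$family %in% fams &
                     presence$status != "absent", , drop = FALSE]
  checked <- intersect(pres$family, MOTIF_CHECKED_FAMILIES)
  for (fam in checked) {
    members <- pres$member_protein_ids[pres$family == fam][[1]]
    rep_fam <- motif_reports[motif_reports$family == fam &
                               motif_reports$target_protein_id %in% members, ,
                             drop = FALSE]
    if (nrow(rep_fam) == 0L) {
      abort(paste0("missing motif report for present subunit: ", fam))
    }
    if (any(rep_fam$verdict == "degenerate")) return(FALSE)
  }
  TRUE
}

#' Call functional capability from presence and motif evidence
#'
#' Applies the three minimal criteria per enzyme system and screens the
#' oxygen-tolerant candidate groups (1, 3b, 3d). Every `FALSE` verdict
#' carries at least one reason naming the failed criterion. Group 1 (MBH)
#' candidacy requires, beyond the structural pair and a conserved
#' proximal-cluster signature, at least hoxZ and hoxM; the full accessory
#' set (hoxZMLOQ + hoxRTV) elevates the verdict from `questionable` to
#' `candidate`. Group 3b requires all four subunits plus the complete hyp
#' set; group 3d follows the hox rules.
#'
#' @param presence One genome's presence tibble (after
#'   [apply_motif_downgrade()]).
#' @param motif_reports Motif reports for this genome's proteins.
#' @return One-row tibble: `genome_id`, `hox_functional`,
#'   `hup_functional`, `nitrogen_fixing`, `reasons` (semicolon-joined),
#'   `o2_tolerant` (list-column tibble with `group`, `verdict`,
#'   `reasons`).
#' @export
call_capability <- function(presence, motif_reports) {
  gid <- presence$genome_id[1L]
  reasons <- character()

  hox_set <- complete_hox(presence)
  hyp_set <- complete_hyp(presence)
  hox_motifs <- if (hox_set) {
    motifs_conserved(presence, motif_reports, HOX_SYSTEM)
  } else TRUE
  hox_fun <- hox_set && hyp_set && hox_motifs
  if (!hox_fun) {
    if (!hox_set) reasons <- c(reasons, "hox: structural gene set incomplete")
    if (!hyp_set) reasons <- c(reasons, "hox: hyp maturation set incomplete")
    if (hox_set && !hox_motifs) {
      reasons <- c(reasons, "hox: degenerate catalytic residues")
    }
  }

  hup_set <- complete_hup(presence)
  hup_motifs <- if (hup_set) {
    motifs_conserved(presence, motif_reports, HUP_SYSTEM)
  } else TRUE
  hup_fun <- hup_set && hyp_set && hup_motifs
  if (!hup_fun) {
    if (!hup_set) reasons <- c(reasons, "hup: structural gene set incomplete")
    if (!hyp_set) reasons <- c(reasons, "hup: hyp maturation set incomplete")
    if (hup_set && !hup_motifs) {
      reasons <- c(reasons, "hup: degenerate catalytic residues")
    }
  }

  nif_fun <- call_nitrogen_fixing(presence)
  if (!nif_fun) reasons <- c(reasons, "nif: essential gene set incomplete")

  o2 <- o2_tolerant_screen(presence, motif_reports, hox_fun)

  tibble(genome_id = gid, hox_functional = hox_fun,
         hup_functional = hup_fun, nitrogen_fixing = nif_fun,
         reasons = paste(reasons, collapse = "; "),
         o2_tolerant = list(o2))
}

o2_tolerant_screen <- function(presence, motif_reports, hox_functional) {
  out <- list()
  st <- function(f) presence_of(presence, f)

  # Group 1: membrane-bound uptake hydrogenase
  mbh <- st(c("mbh1_large", "mbh1_small"))
  if (all(mbh != "absent")) {
    rs <- character()
    sig_ok <- motifs_conserved(presence, motif_reports, "mbh1_small")
    if (!sig_ok) rs <- c(rs, "proximal [4Fe3S] signature degenerate")
    core <- st(MBH_ACCESSORY_CORE)
    full <- st(MBH_ACCESSORY_FULL)
    missing_core <- MBH_ACCESSORY_CORE[core != "present"]
    missing_full <- MBH_ACCESSORY_FULL[full != "present"]
    if (length(missing_core)) {
      rs <- c(rs, paste0("missing accessory genes: ",
                         paste(missing_core, collapse = ",")))
      verdict <- "rejected"
    } else if (!sig_ok) {
      verdict <- "rejected"
    } else if (length(missing_full)) {
      rs <- c(rs, paste0("accessory set incomplete: ",
                         paste(missing_full, collapse = ",")))
      verdict <- "questionable"
    } else {
      verdict <- "candidate"
    }
    out[[length(out) + 1L]] <- tibble(group = "1", verdict = verdict,
                                      reasons = paste(rs, collapse = "; "))
  }

  # Group 3b: tetrameric bifunctional hydrogenase
  sh <- st(SH3B_SUBUNITS)
  if (all(sh != "absent")) {
    rs <- character()
    sig_ok <- motifs_conserved(presence, motif_reports, "sh3b_delta")
    if (!sig_ok) rs <- c(rs, "small-subunit [4Fe4S] cysteines degenerate")
    hyp_ok <- complete_hyp(presence)
    if (!hyp_ok) rs <- c(rs, "hyp maturation set incomplete")
    verdict <- if (sig_ok && hyp_ok && all(sh == "present")) {
      "candidate"
    } else {
      if (any(sh == "present_degenerate")) {
        rs <- c(rs, "subunit with degenerate residues")
      }
      "rejected"
    }
    out[[length(out) + 1L]] <- tibble(group = "3b", verdict = verdict,
                                      reasons = paste(rs, collapse = "; "))
  }

  # Group 3d: the bidirectional Hox enzyme itself
  if (all(st(HOX_SYSTEM) != "absent")) {
    verdict <- if (hox_functional) "candidate" else "rejected"
    rs <- if (hox_functional) "" else "hox three-criteria call failed"
    out[[length(out) + 1L]] <- tibble(group = "3d", verdict = verdict,
                                      reasons = rs)
  }

  if (length(out) == 0L) {
    return(tibble(group = character(), verdict = character(),
                  reasons = character()))
  }
  list_rbind(out)
}
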