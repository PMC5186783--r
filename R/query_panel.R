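# The query panel: one reference protein per searched family plus the
# per-family e-value threshold, and the motif definitions anchored to
# those references.
#
# The shipped panel is fully synthetic: reference sequences are drawn
# from a seeded uniform residue model with catalytic-motif residues
# forced at their anchor positions, and paralogous families (e.g. the
# group 3d and group 2a large subunits) are derived from one another at
# intermediate identity so that reciprocal-best-hit discrimination is
# exercised exactly as it would be on real proteomes. Swap in a real
# panel via write_query_panel()/read_query_panel() for production runs.

AA20 <- AA_ALPHABET[1:20]
PANEL_SEED <- 104729L  # fixed: the default panel is a constant, not a dial

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Mutate a protein sequence to a target identity
#'
#' Substitutes residues at randomly chosen positions (never to the
#' original residue) until the requested fraction of positions differs.
#' Positions in `protect` are never touched; no indels are introduced, so
#' residue coordinates are preserved.
#'
#' @param sequence Amino-acid string.
#' @param identity Target fractional identity in (0, 1].
#' @param protect Integer positions exempt from mutation.
#' @return Mutated sequence string.
#' @export
mutate_protein <- function(sequence, identity, protect = integer()) {
  if (identity <= 0 || identity > 1) abort("identity must be in (0, 1]")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n_mut <- round((1 - identity) * length(ch))
  eligible <- setdiff(seq_along(ch), protect)
  if (n_mut > length(eligible)) n_mut <- length(eligible)
  if (n_mut > 0) {
    pos <- sample(eligible, n_mut)
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

force_residues <- function(sequence, sites) {
  if (length(sites) == 0L) return(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_along(sites)) {
    ch[as.integer(names(sites)[i])] <- sites[[i]]
  }
  paste(ch, collapse = "")
}

# family -> reference length (aa), loosely matched to the real proteins
FAMILY_LENGTHS <- c(
  hoxE = 160, hoxF = 520, hoxU = 230, hoxY = 180, hoxH = 480, hoxW = 160,
  hupS = 320, hupL = 530, hupW = 170,
  hypA = 110, hypB = 250, hypC = 90, hypD = 370, hypE = 340, hypF = 380,
  nifH = 290, nifD = 480, nifK = 520, nifB = 300, nifE = 330, nifN = 310,
  nifU = 180, nifS = 280, nifV = 240, xisC = 250,
  hoxZ = 230, hoxM = 180, hoxL = 120, hoxO = 110, hoxQ = 140,
  hoxR = 100, hoxT = 130, hoxV = 220,
  mbh1_large = 480, mbh1_small = 280,
  sh3b_alpha = 420, sh3b_beta = 280, sh3b_gamma = 230, sh3b_delta = 160
)

STRUCTURAL_FAMILIES <- c(HOX_STRUCTURAL, "hupS", "hupL",
                         "nifH", "nifD", "nifK", O2_PROBES)

# Derivation map: family -> (source family, identity). Encodes real
# paralogy: the group 2a, group 1 and group 3b subunits are homologous to
# their group 3d counterparts at intermediate identity.
PARALOG_DERIVATION <- list(
  hupL = list(source = "hoxH", identity = 0.50),
  hupS = list(source = "hoxY", identity = 0.50),
  hupW = list(source = "hoxW", identity = 0.50),
  mbh1_large = list(source = "hoxH", identity = 0.45),
  mbh1_small = list(source = "hoxY", identity = 0.45),
  sh3b_alpha = list(source = "hoxF", identity = 0.45),
  sh3b_delta = list(source = "hoxY", identity = 0.45),
  nifK = list(source = "nifD", identity = 0.45),
  nifN = list(source = "nifE", identity = 0.45)
)

# Shadow relatives: present in the RBH reference proteome but never
# searched as families; paralog decoys in synthetic genomes derive from
# these, so the back-search maps decoys away from every query family.
SHADOW_DERIVATION <- list(
  shadow_lsu = list(source = "hoxH", identity = 0.55),
  shadow_ssu = list(source = "hoxY", identity = 0.55),
  shadow_nuoF = list(source = "hoxF", identity = 0.55),
  shadow_nifH_rel = list(source = "nifH", identity = 0.55),
  shadow_maturase = list(source = "hypD", identity = 0.55)
)

# family -> shadow relative used for its paralog decoys
paralog_source <- function(family) {
  switch(family,
    hoxH = , hupL = , mbh1_large = , sh3b_alpha = "shadow_lsu",
    hoxY = , hupS = , mbh1_small = , sh3b_delta = "shadow_ssu",
    hoxF = , hoxU = , hoxE = "shadow_nuoF",
    nifH = "shadow_nifH_rel",
    "shadow_maturase")
}

# Motif sites per motif id: family, anchor positions and the forced
# residues. Consensus residue sets beyond the anchor residue are left to
# user config; the defaults accept exactly the anchor residue.
default_motif_sites <- function() {
  list(
    hoxH_L1 = list(family = "hoxH",
                   sites = c(`60` = "R", `62` = "C", `65` = "C", `67` = "G"),
                   description = "group 3d large-subunit L1 motif incl. Ni-ligand cysteines"),
    hoxH_L2 = list(family = "hoxH",
                   sites = c(`440` = "D", `443` = "C", `446` = "C"),
                   description = "group 3d large-subunit L2 motif incl. Ni-ligand cysteines"),
    hoxY_FeS = list(family = "hoxY",
                    sites = c(`40` = "C", `43` = "C", `105` = "C", `140` = "C"),
                    description = "small-subunit FeS-cluster cysteines"),
    hoxE_FeS = list(family = "hoxE",
                    sites = c(`35` = "C", `40` = "C", `75` = "C", `79` = "C"),
                    description = "diaphorase [2Fe2S] cysteines"),
    hoxF_FeS = list(family = "hoxF",
                    sites = c(`100` = "C", `103` = "C", `106` = "C", `146` = "C"),
                    description = "diaphorase [4Fe4S] cysteines"),
    hoxU_FeS = list(family = "hoxU",
                    sites = c(`30` = "C", `33` = "C", `60` = "C", `64` = "C"),
                    description = "diaphorase [4Fe4S] cysteines"),
    hupL_L1 = list(family = "hupL",
                   sites = c(`70` = "R", `72` = "C", `75` = "C", `78` = "G"),
                   description = "group 2a large-subunit L1 motif"),
    hupL_L2 = list(family = "hupL",
                   sites = c(`430` = "D", `433` = "C", `436` = "C"),
                   description = "group 2a large-subunit L2 motif"),
    hupS_FeS = list(family = "hupS",
                    sites = c(`45` = "C", `48` = "C", `85` = "C", `120` = "C"),
                    description = "uptake small-subunit FeS cysteines"),
    mbh1_small_proximal = list(
      family = "mbh1_small",
      sites = c(`17` = "C", `19` = "C", `20` = "C", `115` = "C",
                `120` = "C", `149` = "C", `242` = "P"),
      description = "O2-tolerant MBH proximal [4Fe3S] signature: six cysteines plus proline"),
    sh3b_delta_FeS = list(
      family = "sh3b_delta",
      sites = c(`50` = "C", `53` = "C", `90` = "C", `94` = "C"),
      description = "group 3b small-subunit [4Fe4S] cysteines")
  )
}

#' Default query panel of synthetic reference proteins
#'
#' One reference protein per searched family at a realistic length, with
#' every default motif residue forced at its anchor position, plus the
#' per-family e-value thresholds (1e-10 for structural subunits, 1e-6 for
#' accessory and maturation proteins). Deterministic: the panel is a fixed
#' constant of the package.
#'
#' @return Tibble with columns `family`, `protein_id`, `sequence`,
#'   `threshold`, `class`.
#' @export
#' @examples
#' nrow(default_query_panel())
default_query_panel <- function() {
  with_seed(PANEL_SEED, {
    fams <- names(FAMILY_LENGTHS)
    seqs <- setNames(vector("list", length(fams)), fams)
    for (f in fams) {
      drv <- PARALOG_DERIVATION[[f]]
      if (is.null(drv)) {
        seqs[[f]] <- random_protein(FAMILY_LENGTHS[[f]])
      } else {
        base <- seqs[[drv$source]]
        need <- FAMILY_LENGTHS[[f]]
        if (nchar(base) < need) {
          base <- paste0(base, random_protein(need - nchar(base)))
        } else if (nchar(base) > need) {
          base <- substr(base, 1L, need)
        }
        seqs[[f]] <- mutate_protein(base, drv$identity)
      }
    }
    # stamp motif residues onto their anchors
    for (m in default_motif_sites()) {
      seqs[[m$family]] <- force_residues(seqs[[m$family]], m$sites)
    }
    tibble(
      family = fams,
      protein_id = paste0(fams, "_ref"),
      sequence = unname(unlist(seqs)),
      class = ifelse(fams %in% STRUCTURAL_FAMILIES, "structural", "accessory"),
      threshold = ifelse(fams %in% STRUCTURAL_FAMILIES, 1e-10, 1e-6)
    )
  })
}

#' Reference proteome used for reciprocal-best-hit confirmation
#'
#' The query panel sequences plus "shadow relative" sequences: paralogous
#' proteins that are not themselves searched but live in the back-search
#' space, so that paralog decoys map back to them and are rejected. This
#' mirrors running the reciprocal search against the query's full source
#' proteome rather than the query set alone.
#'
#' @param panel A query panel tibble (default: [default_query_panel()]).
#' @return Tibble with `protein_id`, `sequence`, `family` (`NA` for
#'   shadow relatives).
#' @export
default_reference_proteome <- function(panel = default_query_panel()) {
  shadows <- with_seed(PANEL_SEED + 1L, {
    purrr::imap(SHADOW_DERIVATION, function(drv, id) {
      src <- panel$sequence[panel$family == drv$source]
      tibble(protein_id = id, sequence = mutate_protein(src, drv$identity),
             family = NA_character_)
    }) |> list_rbind()
  })
  bind_rows(
    tibble(protein_id = panel$protein_id, sequence = panel$sequence,
           family = panel$family),
    shadows
  )
}

#' Write a query panel to disk
#'
#' Emits one FASTA per family plus a `panel.yaml` mapping each family to
#' its FASTA file and e-value threshold — the layout [read_query_panel()]
#' consumes.
#'
#' @param panel Query panel tibble.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_query_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(families = list())
  for (i in seq_len(nrow(panel))) {
    fam <- panel$family[i]
    fa <- paste0(fam, ".faa")
    write_fasta(panel[i, ], file.path(dir, fa))
    cfg$families[[fam]] <- list(fasta = fa, threshold = panel$threshold[i],
                                class = panel$class[i])
  }
  yaml::write_yaml(cfg, file.path(dir, "panel.yaml"))
  invisible(dir)
}

#' Read a query panel directory
#'
#' @param dir Directory written by [write_query_panel()] (or hand-built
#'   in the same layout).
#' @return Query panel tibble.
#' @export
read_query_panel <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "panel.yaml"))
  purrr::imap(cfg$families, function(entry, fam) {
    fa <- read_fasta(file.path(dir, entry$fasta), genome_id = "panel")
    tibble(family = fam, protein_id = fa$protein_id, sequence = fa$sequence,
           class = entry$class %||% "structural",
           threshold = as.numeric(entry$threshold))
  }) |> list_rbind()
}
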