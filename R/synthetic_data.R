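# Synthetic annotated genomes with planted truth.
#
# Each genome is generated from a plant specification: which gene
# systems to plant, in which cluster arrangement, with which catalytic
# mutations, plus background decoy genes and paralog decoys. The
# matching truth table (expected presence, motif verdicts, arrangement
# labels, capability calls) is derived from the specification alone,
# never by running the pipeline.
#
# Statistical structure emulated: true homologs are near-identical
# copies of the panel queries (<= 2% substitutions, catalytic sites
# protected), paralog decoys sit at intermediate identity to shadow
# relatives of the reference proteome, and background genes are drawn
# from a seeded uniform residue model at 150-600 aa.

PLANT_SYSTEM_ORDER <- c("hox", "hup", "hyp", "nif", "mbh1", "accessory",
                        "sh3b")

SYSTEM_DEFAULT_FAMILIES <- list(
  hox = HOX_SYSTEM, hup = HUP_SYSTEM, hyp = HYP_SYSTEM,
  nif = c(NIF_ESSENTIAL, NIF_DISPENSABLE),
  mbh1 = c("mbh1_large", "mbh1_small"),
  accessory = MBH_ACCESSORY_CORE,
  sh3b = SH3B_SUBUNITS
)

# arrangement label -> cluster plan (list of family vectors; first
# element of attr "interrupt" names the subunit carrying a nested xisC)
hox_cluster_plan <- function(label) {
  switch(label,
    G1 = list(c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH"), "hoxW"),
    G2 = list(c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH", "hoxW")),
    G3 = list(c("hoxE", "hoxF", "hoxU", "hoxY"), "hoxH", "hoxW"),
    G4 = list(c("hoxE", "hoxF"), c("hoxU", "hoxY"), "hoxH", "hoxW"),
    G5 = list(c("hoxE", "hoxF"), c("hoxU", "hoxY", "hoxH"), "hoxW"),
    G6 = list(c("hoxE", "hoxF"), "hoxU", "hoxY", "hoxH", "hoxW"),
    G7 = list(c("hoxF", "hoxU", "hoxY", "hoxH", "hoxW"), "hoxE"),
    abort(paste0("unsupported hox arrangement: ", label))
  )
}

hup_cluster_plan <- function(label) {
  plan <- switch(label,
    G1 = list(c("hupS", "hupL", "hupW")),
    G2 = list(c("hupS", "hupL"), "hupW"),
    G3 = list(c("hupS", "hupL", "hupW")),
    G4 = list(c("hupS", "hupL"), "hupW"),
    G5 = list(c("hupS", "hupL", "hupW")),
    abort(paste0("unsupported hup arrangement: ", label))
  )
  attr(plan, "interrupt") <- switch(label, G3 = "hupL", G4 = "hupL",
                                    G5 = "hupS", NULL)
  plan
}

hyp_cluster_plan <- function(label) {
  sizes <- if (label == "1") 6L
  else if (label == "2") c(5L, 1L)
  else as.integer(strsplit(label, "+", fixed = TRUE)[[1]])
  if (any(is.na(sizes)) || sum(sizes) != 6L) {
    abort(paste0("unrealizable hyp arrangement: ", label))
  }
  fams <- HYP_SYSTEM
  plan <- list()
  at <- 1L
  for (s in sizes) {
    plan[[length(plan) + 1L]] <- fams[at:(at + s - 1L)]
    at <- at + s
  }
  plan
}

#' Specify a synthetic genome to plant
#'
#' @param genome_id Identifier.
#' @param habitat,subsection Metadata labels.
#' @param systems Named list of system requests. Names among `hox`,
#'   `hup`, `hyp`, `nif`, `mbh1`, `accessory`, `sh3b`; each entry a list
#'   with optional `families` (subset to plant; default the full system
#'   set), `arrangement` (canonical label; requires the full set) and
#'   `orientation` (`"uniform"` or `"mixed"`).
#' @param mutations List of planted-mutation requests:
#'   `list(family=, site=, to=)` substitutes residue `to` at reference
#'   position `site`, or `list(family=, truncate_fraction=)` removes
#'   that C-terminal fraction.
#' @param decoys Number of random background genes (at least the spacer
#'   requirement is always planted).
#' @param paralog_decoys List of `list(family=, identity=)`: decoy genes
#'   derived from the family's shadow relative at the given identity.
#' @param extra_copies Named integer vector of additional gene copies
#'   planted distally (e.g. `c(hoxW = 2)` for a two-copy genome).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(genome_id, habitat = "other", subsection = "unknown",
                       systems = list(), mutations = list(), decoys = 8L,
                       paralog_decoys = list(), extra_copies = integer(),
                       seed = 1L) {
  for (nm in names(systems)) {
    if (!nm %in% PLANT_SYSTEM_ORDER) {
      abort(paste0("unknown system in plant spec: ", nm))
    }
    req <- systems[[nm]]
    fams <- req$families %||% SYSTEM_DEFAULT_FAMILIES[[nm]]
    if (!is.null(req$arrangement) &&
        !setequal(fams, SYSTEM_DEFAULT_FAMILIES[[nm]]) &&
        nm %in% c("hox", "hup", "hyp")) {
      abort(paste0(nm, ": arrangement request requires the full family set"))
    }
    if (!is.null(req$arrangement)) {
      # fail fast on unrealizable labels, before anything is written
      switch(nm, hox = hox_cluster_plan(req$arrangement),
             hup = hup_cluster_plan(req$arrangement),
             hyp = hyp_cluster_plan(req$arrangement))
    }
  }
  for (m in mutations) {
    if (is.null(m$family)) abort("mutation request lacks a family")
  }
  for (p in paralog_decoys) {
    if (is.null(p$identity) || p$identity <= 0 || p$identity >= 1) {
      abort("paralog decoy identity must be in (0, 1)")
    }
  }
  structure(list(genome_id = genome_id, habitat = habitat,
                 subsection = subsection, systems = systems,
                 mutations = mutations, decoys = as.integer(decoys),
                 paralog_decoys = paralog_decoys,
                 extra_copies = extra_copies, seed = as.integer(seed)),
            class = "plant_spec")
}

planted_families <- function(spec) {
  fams <- unlist(purrr::imap(spec$systems, function(req, nm) {
    req$families %||% SYSTEM_DEFAULT_FAMILIES[[nm]]
  }), use.names = FALSE)
  interrupts <- unlist(purrr::map(spec$systems[names(spec$systems) == "hup"],
                                  function(req) {
    if (is.null(req$arrangement)) return(NULL)
    attr(hup_cluster_plan(req$arrangement), "interrupt")
  }))
  if (length(interrupts)) fams <- c(fams, "xisC")
  as.character(unique(fams))
}

motif_positions_for <- function(family) {
  sites <- default_motif_sites()
  unlist(purrr::map(sites, function(m) {
    if (m$family == family) as.integer(names(m$sites)) else integer()
  }), use.names = FALSE)
}

# build the planted protein for one family under the spec's mutations
plant_protein <- function(family, panel, mutations) {
  ref <- panel$sequence[panel$family == family][1L]
  protect <- motif_positions_for(family)
  muts <- purrr::keep(mutations, ~.x$family == family)
  for (m in muts) {
    if (!is.null(m$site)) protect <- union(protect, as.integer(m$site))
  }
  seq <- mutate_protein(ref, identity = 0.98, protect = protect)
  for (m in muts) {
    if (!is.null(m$site)) {
      substr(seq, m$site, m$site) <- m$to
    } else if (!is.null(m$truncate_fraction)) {
      keep <- floor(nchar(seq) * (1 - m$truncate_fraction))
      seq <- substr(seq, 1L, keep)
    }
  }
  seq
}

#' Generate a synthetic genome from a plant specification
#'
#' Planted genes are near-identical copies of the panel queries laid out
#' to realise the requested cluster arrangements (members adjacent;
#' separate clusters and distal genes divided by five background genes,
#' beyond any co-localization threshold up to 4). xisC interruptions are
#' realised as an xisC gene nested inside the span of the interrupted
#' subunit. Deterministic per seed.
#'
#' @param spec A [plant_spec()].
#' @param panel Query panel tibble.
#' @param dir Optional directory: when given, the genome's FASTA + GFF3
#'   are written there.
#' @return List with `genome` (a `genome` object) and `truth` (one-row
#'   truth tibble from [truth_row()]).
#' @export
generate_genome <- function(spec, panel = default_query_panel(), dir = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  g <- with_seed(spec$seed, build_genome(spec, panel))
  if (!is.null(dir)) write_genome(g, dir)
  list(genome = g, truth = truth_row(spec, panel))
}

build_genome <- function(spec, panel) {
  gid <- spec$genome_id
  proteins <- list()
  features <- list()
  pos <- 500L
  gene_no <- 0L

  emit <- function(protein_id, sequence, strand, interrupt_with = NULL) {
    gene_no <<- gene_no + 1L
    nt <- nchar(sequence) * 3L + 3L
    start <- pos
    end <- pos + nt
    xis_rows <- NULL
    if (!is.null(interrupt_with)) {
      xis_nt <- nchar(interrupt_with$sequence) * 3L + 3L
      end <- start + nt + xis_nt + 600L
      xis_start <- start + 300L
      xis_rows <- list(
        protein = tibble(protein_id = interrupt_with$protein_id,
                         genome_id = gid,
                         sequence = interrupt_with$sequence),
        feature = tibble(gene_id = interrupt_with$protein_id,
                         genome_id = gid, replicon_id = "chr",
                         start = xis_start, end = xis_start + xis_nt,
                         strand = strand,
                         protein_id = interrupt_with$protein_id))
    }
    proteins[[length(proteins) + 1L]] <<-
      tibble(protein_id = protein_id, genome_id = gid, sequence = sequence)
    features[[length(features) + 1L]] <<-
      tibble(gene_id = protein_id, genome_id = gid, replicon_id = "chr",
             start = start, end = end, strand = strand,
             protein_id = protein_id)
    if (!is.null(xis_rows)) {
      proteins[[length(proteins) + 1L]] <<- xis_rows$protein
      features[[length(features) + 1L]] <<- xis_rows$feature
    }
    pos <<- end + 150L
  }

  bg_counter <- 0L
  emit_background <- function(n) {
    for (i in seq_len(n)) {
      bg_counter <<- bg_counter + 1L
      emit(sprintf("%s_bg%03d", gid, bg_counter),
           random_protein(sample(150:600, 1L)),
           sample(c("+", "-"), 1L))
    }
  }

  # assemble cluster plans in deterministic system order
  plans <- list()
  for (nm in intersect(PLANT_SYSTEM_ORDER, names(spec$systems))) {
    req <- spec$systems[[nm]]
    fams <- req$families %||% SYSTEM_DEFAULT_FAMILIES[[nm]]
    interrupt <- NULL
    if (!is.null(req$arrangement) && nm %in% c("hox", "hup", "hyp")) {
      plan <- switch(nm, hox = hox_cluster_plan(req$arrangement),
                     hup = hup_cluster_plan(req$arrangement),
                     hyp = hyp_cluster_plan(req$arrangement))
      interrupt <- attr(plan, "interrupt")
    } else {
      plan <- list(fams)
    }
    mixed <- identical(req$orientation, "mixed")
    plans[[length(plans) + 1L]] <- list(system = nm, plan = plan,
                                        interrupt = interrupt, mixed = mixed)
  }

  for (p in plans) {
    for (ci in seq_along(p$plan)) {
      cluster <- p$plan[[ci]]
      for (fi in seq_along(cluster)) {
        fam <- cluster[fi]
        strand <- if (p$mixed && fi %% 2L == 0L) "-" else "+"
        interrupt_with <- NULL
        if (!is.null(p$interrupt) && identical(fam, p$interrupt)) {
          interrupt_with <- list(
            protein_id = paste0(gid, "_xisC"),
            sequence = plant_protein("xisC", panel, spec$mutations))
        }
        emit(paste0(gid, "_", fam),
             plant_protein(fam, panel, spec$mutations),
             strand, interrupt_with = interrupt_with)
      }
      emit_background(5L)
    }
  }

  # extra distal copies (multicopy states)
  for (fam in names(spec$extra_copies)) {
    for (k in seq_len(spec$extra_copies[[fam]] - 1L)) {
      emit(sprintf("%s_%s_copy%d", gid, fam, k + 1L),
           plant_protein(fam, panel, spec$mutations), "+")
      emit_background(5L)
    }
  }

  # paralog decoys: intermediate-identity derivatives of shadow relatives
  if (length(spec$paralog_decoys)) {
    shadows <- default_reference_proteome(panel)
    for (i in seq_along(spec$paralog_decoys)) {
      pd <- spec$paralog_decoys[[i]]
      src_id <- paralog_source(pd$family)
      src <- shadows$sequence[shadows$protein_id == src_id]
      emit(sprintf("%s_dec%02d", gid, i),
           mutate_protein(src, pd$identity),
           sample(c("+", "-"), 1L))
      emit_background(2L)
    }
  }

  # remaining background up to the requested count
  if (spec$decoys > bg_counter) emit_background(spec$decoys - bg_counter)
  if (length(proteins) == 0L) emit_background(max(spec$decoys, 3L))

  genome(gid, list_rbind(proteins), list_rbind(features),
         habitat = spec$habitat, subsection = spec$subsection)
}

# ---------------------------------------------------------------------------
# Truth derivation (from the spec alone)

mutation_degenerates <- function(spec, family) {
  sites <- default_motif_sites()
  fam_sites <- motif_positions_for(family)
  if (length(fam_sites) == 0L) return(FALSE)
  ref_len <- FAMILY_LENGTHS[[family]]
  for (m in purrr::keep(spec$mutations, ~.x$family == family)) {
    if (!is.null(m$site) && as.integer(m$site) %in% fam_sites) return(TRUE)
    if (!is.null(m$truncate_fraction)) {
      keep <- floor(ref_len * (1 - m$truncate_fraction))
      if (any(fam_sites > keep)) return(TRUE)
    }
  }
  FALSE
}

#' Derive the expected truth for a plant specification
#'
#' Expected family presence (with copy numbers and degenerate
#' downgrades), per-family motif verdicts, arrangement labels,
#' co-occurrence states and capability calls — all computed from the
#' specification and the motif site definitions, without running any
#' pipeline stage.
#'
#' @param spec A [plant_spec()].
#' @param panel Query panel tibble.
#' @return One-row tibble with nested `presence`, `motifs`,
#'   `arrangements`, plus flat expected category states and capability
#'   booleans.
#' @export
truth_row <- function(spec, panel = default_query_panel()) {
  fams <- planted_families(spec)
  all_fams <- unique(panel$family)
  status <- setNames(rep("absent", length(all_fams)), all_fams)
  copies <- setNames(rep(0L, length(all_fams)), all_fams)
  for (f in intersect(fams, all_fams)) {
    status[f] <- if (mutation_degenerates(spec, f)) "present_degenerate"
    else "present"
    copies[f] <- 1L
  }
  for (f in names(spec$extra_copies)) {
    if (f %in% all_fams && copies[f] > 0L) {
      copies[f] <- as.integer(spec$extra_copies[[f]])
    }
  }
  presence <- tibble(genome_id = spec$genome_id, family = all_fams,
                     status = unname(status), copy_number = unname(copies))

  checked <- intersect(fams, MOTIF_CHECKED_FAMILIES)
  motifs <- tibble(
    genome_id = rep(spec$genome_id, length(checked)), family = checked,
    verdict = ifelse(vapply(checked, mutation_degenerates, logical(1),
                            spec = spec), "degenerate", "conserved") |>
      as.character())

  arr <- purrr::imap(spec$systems, function(req, nm) {
    if (nm %in% c("hox", "hup", "hyp") && !is.null(req$arrangement)) {
      tibble(genome_id = spec$genome_id, system = nm,
             label = req$arrangement)
    }
  }) |> list_rbind()
  if (is.null(arr) || nrow(arr) == 0L) {
    arr <- tibble(genome_id = character(), system = character(),
                  label = character())
  }

  state_of <- function(set) {
    s <- status[set]
    if (all(s == "present")) "complete"
    else if (all(s == "absent")) "absent" else "incomplete"
  }
  hox_ok <- state_of(HOX_SYSTEM) == "complete"
  hup_ok <- state_of(HUP_SYSTEM) == "complete"
  hyp_ok <- state_of(HYP_SYSTEM) == "complete"
  nif_ok <- all(status[NIF_ESSENTIAL] == "present")
  hox_mot <- !any(motifs$verdict[motifs$family %in% HOX_SYSTEM] == "degenerate")
  hup_mot <- !any(motifs$verdict[motifs$family %in% HUP_SYSTEM] == "degenerate")

  o2 <- list()
  if (all(status[c("mbh1_large", "mbh1_small")] != "absent")) {
    sig_ok <- !mutation_degenerates(spec, "mbh1_small")
    core_ok <- all(status[MBH_ACCESSORY_CORE] == "present")
    full_ok <- all(status[MBH_ACCESSORY_FULL] == "present")
    verdict <- if (!core_ok || !sig_ok) "rejected"
    else if (full_ok) "candidate" else "questionable"
    o2[[length(o2) + 1L]] <- tibble(group = "1", verdict = verdict)
  }
  if (all(status[SH3B_SUBUNITS] != "absent")) {
    sig_ok <- !mutation_degenerates(spec, "sh3b_delta")
    verdict <- if (sig_ok && hyp_ok &&
                   all(status[SH3B_SUBUNITS] == "present")) "candidate"
    else "rejected"
    o2[[length(o2) + 1L]] <- tibble(group = "3b", verdict = verdict)
  }
  if (all(status[HOX_SYSTEM] != "absent")) {
    o2[[length(o2) + 1L]] <- tibble(
      group = "3d",
      verdict = if (hox_ok && hyp_ok && hox_mot) "candidate" else "rejected")
  }
  o2 <- if (length(o2)) list_rbind(o2) else
    tibble(group = character(), verdict = character())

  tibble(
    genome_id = spec$genome_id,
    habitat = spec$habitat, subsection = spec$subsection,
    hox_state = state_of(HOX_SYSTEM), hup_state = state_of(HUP_SYSTEM),
    nif_state = state_of(NIF_ESSENTIAL),
    hox_functional = hox_ok && hyp_ok && hox_mot,
    hup_functional = hup_ok && hyp_ok && hup_mot,
    nitrogen_fixing = nif_ok,
    presence = list(presence), motifs = list(motifs),
    arrangements = list(arr), o2_tolerant = list(o2))
}
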