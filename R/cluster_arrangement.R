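# Physical co-localization of gene-system members and classification of
# cluster arrangements into canonical pattern labels.
#
# Two member genes co-cluster when they lie on the same replicon with at
# most `max_intervening` non-member genes strictly between them
# (transitive closure along the replicon). There is deliberately no
# base-pair distance criterion: a gene-count rule is independent of
# annotation density.

SYSTEM_LETTERS <- list(
  hox = c(hoxE = "E", hoxF = "F", hoxU = "U", hoxY = "Y", hoxH = "H",
          hoxW = "W"),
  hup = c(hupS = "S", hupL = "L", hupW = "W"),
  hyp = c(hypA = "A", hypB = "B", hypC = "C", hypD = "D", hypE = "E",
          hypF = "F")
)

system_families <- function(system) names(SYSTEM_LETTERS[[system]])

member_features <- function(genome, presence, system) {
  fams <- system_families(system)
  pres <- presence[presence$family %in% fams &
                     presence$status != "absent", , drop = FALSE]
  if (nrow(pres) == 0L) {
    return(tibble(family = character(), protein_id = character()))
  }
  members <- tidyr::unnest(
    select(pres, "family", "member_protein_ids"),
    cols = "member_protein_ids") |>
    rename(protein_id = "member_protein_ids")
  feats <- inner_join(genome$features, members, by = "protein_id")
  missing <- setdiff(members$protein_id,
                     genome$features$protein_id[!is.na(genome$features$protein_id)])
  if (length(missing)) {
    abort(paste0("system member without coordinates: ",
                 paste(missing, collapse = ", ")))
  }
  feats
}

#' Find physical clusters of a gene system's members
#'
#' @param genome A `genome` object.
#' @param presence Presence tibble for this genome.
#' @param system `"hox"`, `"hup"` or `"hyp"`.
#' @param max_intervening Maximum number of non-member genes allowed
#'   strictly between consecutive co-clustered members (default 3).
#' @return Tibble with one row per member gene: `cluster_id` (integer,
#'   numbered along each replicon), `replicon_id`, `family`, `gene_id`,
#'   `protein_id`, `start`, `end`, `strand`. Singletons form their own
#'   cluster; every present member appears exactly once.
#' @export
find_clusters <- function(genome, presence, system, max_intervening = 3L) {
  mem <- member_features(genome, presence, system)
  if (nrow(mem) == 0L) {
    return(tibble(cluster_id = integer(), replicon_id = character(),
                  family = character(), gene_id = character(),
                  protein_id = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  other <- anti_join(genome$features, select(mem, "gene_id"), by = "gene_id")
  out <- list()
  next_id <- 0L
  for (rep_id in unique(mem$replicon_id)) {
    m <- mem[mem$replicon_id == rep_id, , drop = FALSE]
    m <- m[order(m$start, m$end, m$gene_id), , drop = FALSE]
    o <- other[other$replicon_id == rep_id, , drop = FALSE]
    cl <- integer(nrow(m))
    for (i in seq_len(nrow(m))) {
      if (i == 1L) {
        next_id <- next_id + 1L
        cl[i] <- next_id
        next
      }
      between <- sum(o$start >= m$end[i - 1L] & o$end <= m$start[i])
      if (between <= max_intervening) {
        cl[i] <- cl[i - 1L]
      } else {
        next_id <- next_id + 1L
        cl[i] <- next_id
      }
    }
    m$cluster_id <- cl
    out[[length(out) + 1L]] <- m
  }
  list_rbind(out) |>
    select("cluster_id", "replicon_id", "family", "gene_id", "protein_id",
           "start", "end", "strand")
}

# canonical partition signature: blocks as concatenated family letters in
# system order; blocks sorted by size (desc) then alphabetically
partition_signature <- function(clusters, system) {
  letters_map <- SYSTEM_LETTERS[[system]]
  blocks <- split(clusters$family, clusters$cluster_id)
  strs <- vapply(blocks, function(fams) {
    lets <- letters_map[sort(match(fams, names(letters_map)))]
    paste(lets, collapse = "")
  }, character(1))
  strs <- strs[order(-nchar(strs), strs)]
  paste(strs, collapse = "+")
}

cluster_orientation_uniform <- function(clusters) {
  all(vapply(split(clusters$strand, clusters$cluster_id),
             function(s) length(unique(s)) == 1L, logical(1)))
}

#' Default arrangement pattern lookups
#'
#' The hox Group 4-6 membership and the hup Group 1-5 numbering are
#' editable data, not code: the canonical descriptions only name the
#' distinguishing axes, so the exact assignments ship as a lookup that a
#' user can replace (see `pattern_lookup.yaml` under `inst/extdata` for
#' the file form). Signatures not in the lookup are `unclassified`.
#'
#' @param path Optional YAML file in the shipped layout; `NULL` uses the
#'   built-in defaults.
#' @return List with elements `hox` (partition signature -> label) and
#'   `hup` (axis combination -> label).
#' @export
default_pattern_lookup <- function(path = NULL) {
  if (!is.null(path)) return(yaml::read_yaml(path))
  list(
    hox = list(`EF+UY+H+W` = "G4", `UYH+EF+W` = "G5", `EF+H+U+W+Y` = "G6"),
    hup = list(`clustered|none` = "G1", `distal|none` = "G2",
               `clustered|hupL` = "G3", `distal|hupL` = "G4",
               `clustered|hupS` = "G5", `distal|hupS` = "G5")
  )
}

#' Classify the hox cluster arrangement
#'
#' Groups follow the canonical hox patterns: G1 = EFUYH in one
#' same-orientation cluster with hoxW elsewhere; G2 = all six clustered
#' in the same orientation; G3 = EFUY same-orientation cluster with hoxH
#' and hoxW elsewhere; G7 = FUYHW clustered with hoxE elsewhere; G4-G6 =
#' hoxE/hoxF co-clustered with the remaining genes distributed per the
#' pattern lookup; anything else is `unclassified`.
#'
#' @param clusters Output of [find_clusters()] for the hox system.
#' @param lookup Pattern lookup from [default_pattern_lookup()].
#' @return One-row tibble: `system`, `label`, `partition_signature`,
#'   `orientation_uniform`, `interrupted_by`.
#' @export
classify_hox <- function(clusters, lookup = default_pattern_lookup()) {
  fams <- unique(clusters$family)
  if (!setequal(fams, system_families("hox")) ||
      nrow(clusters) != length(fams)) {
    abort("classify_hox requires the complete single-copy hox gene set")
  }
  sig <- partition_signature(clusters, "hox")
  uniform <- cluster_orientation_uniform(clusters)
  label <- if (sig == "EFUYH+W" && uniform) "G1"
  else if (sig == "EFUYHW" && uniform) "G2"
  else if (sig == "EFUY+H+W" && uniform) "G3"
  else if (sig == "FUYHW+E" && uniform) "G7"
  else lookup$hox[[sig]] %||% "unclassified"
  tibble(system = "hox", label = label, partition_signature = sig,
         orientation_uniform = uniform, interrupted_by = NA_character_)
}

#' Detect xisC interruption of an uptake-hydrogenase subunit
#'
#' An interruption is called when an xisC-family gene lies strictly
#' within the span of a hupS or hupL gene, or when a subunit is split
#' into two features flanking an xisC gene on the same replicon.
#'
#' @param genome A `genome` object.
#' @param presence Presence tibble.
#' @return `"hupS"`, `"hupL"` or `"none"`.
#' @export
detect_xisc_interruption <- function(genome, presence) {
  xis_row <- presence[presence$family == "xisC" &
                        presence$status != "absent", , drop = FALSE]
  if (nrow(xis_row) == 0L) return("none")
  xis <- genome$features[
    genome$features$protein_id %in% xis_row$member_protein_ids[[1L]], ,
    drop = FALSE]
  if (nrow(xis) == 0L) return("none")
  for (sub in c("hupS", "hupL")) {
    row <- presence[presence$family == sub &
                      presence$status != "absent", , drop = FALSE]
    if (nrow(row) == 0L) next
    feats <- genome$features[
      genome$features$protein_id %in% row$member_protein_ids[[1L]], ,
      drop = FALSE]
    for (i in seq_len(nrow(xis))) {
      inside <- feats$replicon_id == xis$replicon_id[i] &
        feats$start < xis$start[i] & feats$end > xis$end[i]
      if (any(inside)) return(sub)
    }
    # split form: two fragments of the subunit flanking an xisC gene
    if (nrow(feats) >= 2L) {
      feats <- feats[order(feats$start), ]
      for (i in seq_len(nrow(feats) - 1L)) {
        gap_hit <- xis$replicon_id == feats$replicon_id[i] &
          xis$start >= feats$end[i] & xis$end <= feats$start[i + 1L]
        if (feats$replicon_id[i] == feats$replicon_id[i + 1L] &&
            any(gap_hit)) {
          return(sub)
        }
      }
    }
  }
  "none"
}

#' Classify the hup cluster arrangement
#'
#' hupS and hupL must be co-clustered (otherwise `unclassified`); the
#' group label is then read from the lookup on two axes: hupW clustered
#' with hupSL vs distal, and xisC interruption of hupS, hupL or neither.
#'
#' @param clusters Output of [find_clusters()] for the hup system.
#' @param interruption Result of [detect_xisc_interruption()].
#' @param lookup Pattern lookup from [default_pattern_lookup()].
#' @return One-row tibble as for [classify_hox()].
#' @export
classify_hup <- function(clusters, interruption = "none",
                         lookup = default_pattern_lookup()) {
  fams <- unique(clusters$family)
  if (!setequal(fams, system_families("hup"))) {
    abort("classify_hup requires hupS, hupL and hupW present")
  }
  sig <- partition_signature(clusters, "hup")
  uniform <- cluster_orientation_uniform(clusters)
  cl_of <- function(f) unique(clusters$cluster_id[clusters$family == f])
  sl_together <- length(intersect(cl_of("hupS"), cl_of("hupL"))) > 0L
  if (!sl_together) {
    return(tibble(system = "hup", label = "unclassified",
                  partition_signature = sig, orientation_uniform = uniform,
                  interrupted_by = interruption))
  }
  w_loc <- if (length(intersect(cl_of("hupW"), cl_of("hupS"))) > 0L) {
    "clustered"
  } else "distal"
  key <- paste(w_loc, interruption, sep = "|")
  tibble(system = "hup", label = lookup$hup[[key]] %||% "unclassified",
         partition_signature = sig, orientation_uniform = uniform,
         interrupted_by = if (interruption == "none") NA_character_ else "xisC")
}

#' Classify the hyp cluster arrangement
#'
#' Class 1 = all six hyp genes in a single cluster; class 2 = five
#' clustered and one elsewhere; every other partition is labelled by its
#' canonical cluster-size signature (e.g. `"4+2"`, `"1+1+1+1+1+1"`),
#' which enumerates the remaining classes deterministically.
#'
#' @param clusters Output of [find_clusters()] for the hyp system.
#' @return One-row tibble as for [classify_hox()].
#' @export
classify_hyp <- function(clusters) {
  fams <- unique(clusters$family)
  if (!setequal(fams, system_families("hyp"))) {
    abort("classify_hyp requires the complete hypABCDEF set")
  }
  sig <- partition_signature(clusters, "hyp")
  sizes <- sort(vapply(split(clusters$family, clusters$cluster_id),
                       length, integer(1)), decreasing = TRUE)
  size_sig <- paste(sizes, collapse = "+")
  label <- if (size_sig == "6") "1" else if (size_sig == "5+1") "2" else size_sig
  tibble(system = "hyp", label = label, partition_signature = sig,
         orientation_uniform = cluster_orientation_uniform(clusters),
         interrupted_by = NA_character_)
}

#' Classify all gene-system arrangements for one genome
#'
#' Runs [find_clusters()] and the per-system classifiers for every system
#' whose gene set is completely present; systems with incomplete or
#' absent gene sets get no row.
#'
#' @param genome A `genome` object.
#' @param presence Presence tibble.
#' @param max_intervening Co-localization threshold (default 3).
#' @param lookup Pattern lookup.
#' @return Tibble: `genome_id`, `system`, `label`, `partition_signature`,
#'   `orientation_uniform`, `interrupted_by`.
#' @export
classify_arrangements <- function(genome, presence, max_intervening = 3L,
                                  lookup = default_pattern_lookup()) {
  out <- list()
  pres_ok <- function(fams) {
    all(presence_of(presence, fams) %in% c("present", "present_degenerate"))
  }
  if (pres_ok(HOX_SYSTEM)) {
    cl <- find_clusters(genome, presence, "hox", max_intervening)
    if (nrow(cl) == length(HOX_SYSTEM)) {
      out[[length(out) + 1L]] <- classify_hox(cl, lookup)
    }
  }
  if (pres_ok(HUP_SYSTEM)) {
    cl <- find_clusters(genome, presence, "hup", max_intervening)
    out[[length(out) + 1L]] <-
      classify_hup(cl, detect_xisc_interruption(genome, presence), lookup)
  }
  if (pres_ok(HYP_SYSTEM)) {
    cl <- find_clusters(genome, presence, "hyp", max_intervening)
    out[[length(out) + 1L]] <- classify_hyp(cl)
  }
  if (length(out) == 0L) {
    return(tibble(genome_id = character(), system = character(),
                  label = character(), partition_signature = character(),
                  orientation_uniform = logical(),
                  interrupted_by = character()))
  }
  mutate(list_rbind(out), genome_id = genome$genome_id, .before = 1L)
}
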