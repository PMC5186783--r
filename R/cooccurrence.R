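# Stratified co-occurrence accounting of hydrogenase and nitrogenase
# gene sets, and species-tree leaf annotation tables.

#' Three-state gene-set category per genome
#'
#' Each genome is assigned `complete`, `incomplete` (at least one but not
#' all members present) or `absent` (no member) for the hox, hup and nif
#' systems. States derive solely from presence completeness; degenerate
#' presence counts as present for the incomplete/absent distinction but
#' not as complete.
#'
#' @param presence Presence tibble covering one or more genomes.
#' @return Tibble: `genome_id`, `hox_state`, `hup_state`, `nif_state`.
#' @export
categorize_genomes <- function(presence) {
  state_of <- function(p, fams) {
    s <- presence_of(p, fams)
    if (all(s == "present")) "complete"
    else if (all(s == "absent")) "absent"
    else "incomplete"
  }
  presence |>
    group_by(.data$genome_id) |>
    dplyr::group_modify(function(p, key) {
      tibble(hox_state = state_of(p, HOX_SYSTEM),
             hup_state = state_of(p, HUP_SYSTEM),
             nif_state = state_of(p, NIF_ESSENTIAL))
    }) |>
    ungroup()
}

# display rounding: percentages rounded half-up to integers
round_half_up <- function(x) floor(x + 0.5)

#' Summarise category combinations, optionally stratified
#'
#' Counts each (hox, hup, nif) state combination overall or within each
#' habitat / morphological-subsection stratum, with exact and display
#' (half-up integer) percentages of the stratum. Empty strata are
#' omitted; row order is deterministic.
#'
#' @param categories Tibble from [categorize_genomes()].
#' @param metadata Metadata tibble ([read_metadata()]); required for the
#'   stratified axes.
#' @param axis `"overall"`, `"habitat"` or `"subsection"`.
#' @return Tibble: `stratum`, `hox_state`, `hup_state`, `nif_state`,
#'   `count`, `denominator`, `percentage` (exact), `display_percentage`
#'   (integer).
#' @export
summarize_cooccurrence <- function(categories, metadata = NULL,
                                   axis = c("overall", "habitat",
                                            "subsection")) {
  axis <- match.arg(axis)
  if (axis == "overall") {
    d <- mutate(categories, stratum = "overall")
  } else {
    if (is.null(metadata)) abort("metadata required for stratified axes")
    missing <- setdiff(categories$genome_id, metadata$genome_id)
    if (length(missing)) {
      abort(paste0("genomes missing from metadata: ",
                   paste(missing, collapse = ", ")))
    }
    d <- left_join(categories, metadata, by = "genome_id") |>
      mutate(stratum = .data[[axis]])
  }
  d |>
    count(.data$stratum, .data$hox_state, .data$hup_state, .data$nif_state,
          name = "count") |>
    group_by(.data$stratum) |>
    mutate(denominator = sum(.data$count),
           percentage = 100 * .data$count / .data$denominator,
           display_percentage = round_half_up(.data$percentage)) |>
    ungroup() |>
    arrange(.data$stratum, dplyr::desc(.data$count), .data$hox_state,
            .data$hup_state, .data$nif_state)
}

#' Annotate species-tree leaves with survey results
#'
#' One row per tree leaf with three-state marks per system
#' (`complete` / `incomplete` / `absent`), a degenerate flag (any
#' present-degenerate structural gene — the barred-square state),
#' capability calls, and arrangement labels. Leaves with no matching
#' genome are marked `missing` with a warning; the run continues.
#'
#' @param tree `phylo` tree whose tip labels are genome ids.
#' @param categories Tibble from [categorize_genomes()].
#' @param presence Presence tibble (for the degenerate flag).
#' @param capability Capability tibble from [call_capability()] rows.
#' @param arrangements Optional arrangement tibble.
#' @return Tibble keyed by `leaf`.
#' @export
annotate_tree <- function(tree, categories, presence, capability = NULL,
                          arrangements = NULL) {
  if (is.null(tree) || length(tree$tip.label) == 0L) abort("empty tree")
  leaves <- tree$tip.label
  unmatched <- setdiff(leaves, categories$genome_id)
  if (length(unmatched)) {
    warn(paste0("tree leaves without genome data: ",
                paste(unmatched, collapse = ", ")))
  }
  deg <- presence |>
    group_by(.data$genome_id) |>
    summarise(degenerate = any(.data$status == "present_degenerate"),
              .groups = "drop")
  out <- tibble(leaf = leaves) |>
    left_join(categories, by = c(leaf = "genome_id")) |>
    left_join(deg, by = c(leaf = "genome_id")) |>
    mutate(across(all_of(c("hox_state", "hup_state", "nif_state")),
                  ~ifelse(is.na(.x), "missing", .x)),
           degenerate = ifelse(is.na(.data$degenerate), NA, .data$degenerate))
  if (!is.null(capability)) {
    out <- left_join(out,
                     select(capability, "genome_id", "hox_functional",
                            "hup_functional", "nitrogen_fixing"),
                     by = c(leaf = "genome_id"))
  }
  if (!is.null(arrangements) && nrow(arrangements) > 0L) {
    wide <- arrangements |>
      select("genome_id", "system", "label") |>
      tidyr::pivot_wider(names_from = "system", values_from = "label",
                         names_prefix = "arrangement_")
    out <- left_join(out, wide, by = c(leaf = "genome_id"))
  }
  out
}
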