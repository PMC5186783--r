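# File-based orchestration: validated run configuration, the four
# pipeline commands (scan, classify, summarize, simulate) and their TSV
# outputs plus a YAML run manifest. All outputs are plain text; the
# manifest is the only place a timestamp appears, so reruns with the
# same config and inputs are byte-identical everywhere else.

#' Build and validate a run configuration
#'
#' @param genomes_dir Directory of `<genome_id>.faa` + `.gff3` (or
#'   `.features.tsv`) files.
#' @param out_dir Output directory (created on demand).
#' @param metadata Optional metadata TSV path.
#' @param panel_dir Optional query panel directory
#'   ([read_query_panel()] layout); `NULL` uses the built-in panel.
#' @param motif_config Optional motif panel YAML; `NULL` uses the
#'   built-in panel.
#' @param pattern_lookup Optional pattern lookup YAML.
#' @param tree Optional newick species tree path.
#' @param max_intervening Co-localization threshold (0-50).
#' @param thresholds Named numeric vector of per-family e-value
#'   threshold overrides.
#' @param seed Integer seed for stochastic steps (simulation).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(genomes_dir, out_dir, metadata = NULL,
                       panel_dir = NULL, motif_config = NULL,
                       pattern_lookup = NULL, tree = NULL,
                       max_intervening = 3L, thresholds = NULL, seed = 1L) {
  for (p in purrr::compact(list(genomes_dir, metadata, panel_dir,
                                motif_config, pattern_lookup, tree))) {
    if (!file.exists(p)) abort(paste0("path does not exist: ", p))
  }
  max_intervening <- as.integer(max_intervening)
  if (is.na(max_intervening) || max_intervening < 0L ||
      max_intervening > 50L) {
    abort("max_intervening must be between 0 and 50")
  }
  if (!is.null(thresholds) &&
      (is.null(names(thresholds)) || any(thresholds <= 0))) {
    abort("thresholds must be a named vector of positive values")
  }
  structure(list(genomes_dir = genomes_dir, out_dir = out_dir,
                 metadata = metadata, panel_dir = panel_dir,
                 motif_config = motif_config,
                 pattern_lookup = pattern_lookup, tree = tree,
                 max_intervening = max_intervening,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "run_config")
}

config_panel <- function(config) {
  panel <- if (is.null(config$panel_dir)) default_query_panel()
  else read_query_panel(config$panel_dir)
  if (!is.null(config$thresholds)) {
    for (fam in names(config$thresholds)) {
      panel$threshold[panel$family == fam] <- config$thresholds[[fam]]
    }
  }
  panel
}

config_motifs <- function(config, panel) {
  if (is.null(config$motif_config)) default_motif_panel(panel)
  else load_motif_panel(config$motif_config)
}

config_lookup <- function(config) {
  default_pattern_lookup(config$pattern_lookup)
}

config_genome_ids <- function(config) {
  sort(sub("\\.faa$", "", basename(
    list.files(config$genomes_dir, pattern = "\\.faa$"))))
}

config_metadata <- function(config) {
  if (is.null(config$metadata)) NULL else read_metadata(config$metadata)
}

write_manifest <- function(config, command, outputs) {
  cfg <- unclass(config)
  cfg$thresholds <- as.list(cfg$thresholds)
  manifest <- list(
    command = command,
    config = purrr::compact(cfg),
    config_hash = rlang::hash(purrr::compact(cfg)),
    package_version = as.character(utils::packageVersion("hydroscan")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = outputs)
  yaml::write_yaml(manifest,
                   file.path(config$out_dir,
                             paste0("manifest_", command, ".yaml")))
}

read_cohort <- function(config) {
  meta <- config_metadata(config)
  ids <- config_genome_ids(config)
  if (length(ids) == 0L) abort("no .faa files found in genomes_dir")
  genomes <- list()
  failed <- character()
  for (id in ids) {
    g <- tryCatch(read_genome(config$genomes_dir, id, meta),
                  error = function(e) {
                    inform(paste0("skipping unreadable genome ", id, ": ",
                                  conditionMessage(e)))
                    NULL
                  })
    if (is.null(g)) failed <- c(failed, id) else {
      genomes[[length(genomes) + 1L]] <- g
    }
  }
  list(genomes = genomes, failed = failed)
}

#' Scan a genome directory: hits, presence matrix, motif reports
#'
#' @param config A [run_config()].
#' @return Invisibly, the `h2ase_survey` object (also serialised as TSV
#'   under the output directory). Unreadable genomes are skipped with a
#'   logged error and reported in the manifest.
#' @export
cmd_scan <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- config_panel(config)
  motifs <- config_motifs(config, panel)
  cohort <- read_cohort(config)
  survey <- run_survey(cohort$genomes, panel, motifs,
                       max_intervening = config$max_intervening,
                       lookup = config_lookup(config))
  readr::write_tsv(survey$hits, file.path(config$out_dir, "hits.tsv"))
  readr::write_tsv(presence_matrix(survey),
                   file.path(config$out_dir, "presence_matrix.tsv"))
  long <- survey$presence |>
    mutate(member_protein_ids = purrr::map_chr(
      .data$member_protein_ids, paste, collapse = ";"))
  readr::write_tsv(long, file.path(config$out_dir, "presence_long.tsv"))
  if (nrow(survey$motif_reports)) {
    readr::write_tsv(survey$motif_reports,
                     file.path(config$out_dir, "motif_reports.tsv"))
  }
  write_manifest(config, "scan",
                 list(failed_genomes = as.list(cohort$failed)))
  if (length(cohort$failed)) {
    warn(paste0(length(cohort$failed), " genome(s) skipped: ",
                paste(cohort$failed, collapse = ", ")))
  }
  invisible(survey)
}

require_scan_outputs <- function(config) {
  f <- file.path(config$out_dir, "presence_long.tsv")
  if (!file.exists(f)) {
    abort("scan outputs not found in out_dir; run cmd_scan first")
  }
}

read_presence_long <- function(config) {
  readr::read_tsv(file.path(config$out_dir, "presence_long.tsv"),
                  show_col_types = FALSE,
                  col_types = readr::cols(copy_number = "i",
                                          .default = "c")) |>
    mutate(member_protein_ids = purrr::map(
      .data$member_protein_ids,
      ~if (is.na(.x) || !nzchar(.x)) character() else
        strsplit(.x, ";", fixed = TRUE)[[1]]))
}

#' Classify arrangements and capabilities from scan outputs
#'
#' @param config A [run_config()] whose `out_dir` holds [cmd_scan()]
#'   outputs.
#' @return Invisibly, a list with `arrangements` and `capability`.
#' @export
cmd_classify <- function(config) {
  require_scan_outputs(config)
  presence <- read_presence_long(config)
  reports_path <- file.path(config$out_dir, "motif_reports.tsv")
  reports <- if (file.exists(reports_path)) {
    readr::read_tsv(reports_path, show_col_types = FALSE,
                    col_types = readr::cols(reference_position = "i",
                                            target_position = "i",
                                            conserved = "l",
                                            .default = "c"))
  } else {
    mutate(empty_motif_report(), genome_id = character())
  }
  cohort <- read_cohort(config)
  lookup <- config_lookup(config)
  arr <- list(); capab <- list()
  for (g in cohort$genomes) {
    pres_g <- presence[presence$genome_id == g$genome_id, , drop = FALSE]
    rep_g <- reports[reports$genome_id == g$genome_id, , drop = FALSE]
    arr[[length(arr) + 1L]] <-
      classify_arrangements(g, pres_g, config$max_intervening, lookup)
    capab[[length(capab) + 1L]] <- call_capability(pres_g, rep_g)
  }
  arrangements <- list_rbind(arr)
  capability <- list_rbind(capab)
  readr::write_tsv(arrangements,
                   file.path(config$out_dir, "arrangements.tsv"))
  cap_out <- capability |>
    mutate(o2_tolerant = purrr::map_chr(
      .data$o2_tolerant,
      ~paste(paste0(.x$group, ":", .x$verdict), collapse = ";")))
  readr::write_tsv(cap_out, file.path(config$out_dir, "capability.tsv"))
  write_manifest(config, "classify", list())
  invisible(list(arrangements = arrangements, capability = capability))
}

#' Co-occurrence summary tables and optional tree annotation
#'
#' @param config A [run_config()] whose `out_dir` holds scan (and
#'   classify, for arrangement columns) outputs.
#' @return Invisibly, a named list of the written tables.
#' @export
cmd_summarize <- function(config) {
  require_scan_outputs(config)
  presence <- read_presence_long(config)
  categories <- categorize_genomes(presence)
  meta <- config_metadata(config)
  out <- list(overall = summarize_cooccurrence(categories, axis = "overall"))
  if (!is.null(meta)) {
    out$habitat <- summarize_cooccurrence(categories, meta, "habitat")
    out$subsection <- summarize_cooccurrence(categories, meta, "subsection")
  }
  for (nm in names(out)) {
    readr::write_tsv(out[[nm]],
                     file.path(config$out_dir,
                               paste0("summary_", nm, ".tsv")))
  }
  if (!is.null(config$tree)) {
    tree <- read_newick(config$tree)
    cap_path <- file.path(config$out_dir, "capability.tsv")
    capability <- if (file.exists(cap_path)) {
      readr::read_tsv(cap_path, show_col_types = FALSE,
                      col_types = readr::cols(hox_functional = "l",
                                              hup_functional = "l",
                                              nitrogen_fixing = "l",
                                              .default = "c"))
    } else NULL
    arr_path <- file.path(config$out_dir, "arrangements.tsv")
    arrangements <- if (file.exists(arr_path)) {
      readr::read_tsv(arr_path, show_col_types = FALSE,
                      col_types = readr::cols(.default = "c"))
    } else NULL
    out$tree <- annotate_tree(tree, categories, presence, capability,
                              arrangements)
    readr::write_tsv(out$tree,
                     file.path(config$out_dir, "tree_annotation.tsv"))
  }
  write_manifest(config, "summarize", list(tables = names(out)))
  invisible(out)
}

#' Simulate a cohort to disk
#'
#' @param out_dir Output directory for genome files + truth table.
#' @param n Number of genomes.
#' @param mix Category mix (see [generate_cohort()]); the string
#'   `"survey"` selects the curated 30-genome design (ignoring `n` and
#'   `mix`).
#' @param seed Master seed.
#' @return Invisibly, the cohort list.
#' @export
cmd_simulate <- function(out_dir, n = 30L, mix = NULL, seed = 1L) {
  cohort <- if (identical(mix, "survey")) {
    generate_survey_cohort(seed, dir = out_dir)
  } else if (is.null(mix)) {
    generate_cohort(n, seed = seed, dir = out_dir)
  } else {
    generate_cohort(n, mix = mix, seed = seed, dir = out_dir)
  }
  invisible(cohort)
}
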