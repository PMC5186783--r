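# End-to-end in-memory pipeline over a list of genomes, and the survey
# result object with broom-style accessors.

#' Run the full hydrogenase survey over genomes in memory
#'
#' For each genome: panel search with RBH confirmation, presence
#' calling, motif verification (with degenerate downgrades), capability
#' calling, arrangement classification; then cohort-level category
#' assignment.
#'
#' @param genomes List of `genome` objects.
#' @param panel Query panel tibble.
#' @param motifs Motif panel (list of [motif_definition()]).
#' @param reference_proteome RBH back-search proteome.
#' @param params [alignment_params()].
#' @param max_intervening Cluster co-localization threshold.
#' @param lookup Arrangement pattern lookup.
#' @param quiet Suppress per-genome progress messages.
#' @return An object of class `h2ase_survey`: a list of tibbles `hits`,
#'   `presence`, `motif_reports`, `arrangements`, `capability`,
#'   `categories`, `metadata`.
#' @export
run_survey <- function(genomes, panel = default_query_panel(),
                       motifs = default_motif_panel(panel),
                       reference_proteome = default_reference_proteome(panel),
                       params = alignment_params(), max_intervening = 3L,
                       lookup = default_pattern_lookup(), quiet = TRUE) {
  res <- purrr::map(genomes, function(g) {
    if (!quiet) inform(paste0("scanning ", g$genome_id))
    hits <- scan_genome(g, panel, reference_proteome, params)
    pres <- suppressMessages(call_presence(hits, g, panel))
    reports <- check_motif_panel(pres, g, motifs, params)
    pres <- apply_motif_downgrade(pres, reports)
    capab <- call_capability(pres, reports)
    arr <- classify_arrangements(g, pres, max_intervening, lookup)
    rep_out <- if (nrow(reports)) {
      mutate(reports, genome_id = g$genome_id, .before = 1L)
    } else NULL
    list(hits = hits, presence = pres, reports = rep_out,
         capability = capab, arrangements = arr)
  })
  presence <- purrr::map(res, "presence") |> list_rbind()
  out <- list(
    hits = purrr::map(res, "hits") |> list_rbind(),
    presence = presence,
    motif_reports = purrr::map(res, "reports") |> purrr::compact() |>
      list_rbind(),
    arrangements = purrr::map(res, "arrangements") |> list_rbind(),
    capability = purrr::map(res, "capability") |> list_rbind(),
    categories = categorize_genomes(presence),
    metadata = purrr::map(genomes, "metadata") |> list_rbind()
  )
  structure(out, class = "h2ase_survey")
}

#' @export
print.h2ase_survey <- function(x, ...) {
  n <- nrow(x$metadata)
  cat("<h2ase_survey> ", n, " genome(s)\n", sep = "")
  cat("  hox functional: ", sum(x$capability$hox_functional),
      " | hup functional: ", sum(x$capability$hup_functional),
      " | nitrogen fixing: ", sum(x$capability$nitrogen_fixing), "\n",
      sep = "")
  cat("  hydrogenase-free: ",
      sum(x$categories$hox_state == "absent" &
            x$categories$hup_state == "absent"), "\n", sep = "")
  invisible(x)
}

#' Tidy a survey into one row per genome and system state
#'
#' @param x An `h2ase_survey`.
#' @param ... Unused.
#' @return Long tibble: `genome_id`, `system`, `state`, plus capability
#'   columns joined per genome.
#' @export
tidy.h2ase_survey <- function(x, ...) {
  x$categories |>
    tidyr::pivot_longer(cols = c("hox_state", "hup_state", "nif_state"),
                        names_to = "system", values_to = "state") |>
    mutate(system = sub("_state$", "", .data$system)) |>
    left_join(select(x$capability, "genome_id", "hox_functional",
                     "hup_functional", "nitrogen_fixing"),
              by = "genome_id")
}

#' One-row summary of a survey
#'
#' @inheritParams tidy.h2ase_survey
#' @return One-row tibble with cohort-level counts.
#' @export
glance.h2ase_survey <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$metadata),
    n_hox_functional = sum(x$capability$hox_functional),
    n_hup_functional = sum(x$capability$hup_functional),
    n_nitrogen_fixing = sum(x$capability$nitrogen_fixing),
    n_h2ase_free = sum(x$categories$hox_state == "absent" &
                         x$categories$hup_state == "absent"),
    n_incomplete = sum((x$categories$hox_state == "incomplete" |
                          x$categories$hup_state == "incomplete") &
                         !(x$categories$hox_state == "complete" |
                             x$categories$hup_state == "complete")),
    n_complete_both = sum(x$categories$hox_state == "complete" &
                            x$categories$hup_state == "complete")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Wide presence/absence matrix
#'
#' @param survey An `h2ase_survey`.
#' @return Tibble: `genome_id` plus one column per family with codes
#'   `P` (present), `D` (present with degenerate residues), `A`
#'   (absent).
#' @export
presence_matrix <- function(survey) {
  survey$presence |>
    mutate(code = dplyr::case_match(.data$status, "present" ~ "P",
                                    "present_degenerate" ~ "D",
                                    "absent" ~ "A")) |>
    select("genome_id", "family", "code") |>
    tidyr::pivot_wider(names_from = "family", values_from = "code")
}

#' Score a survey against a synthetic cohort's truth table
#'
#' Compares presence states (with copy numbers), per-family motif
#' verdicts, arrangement labels, co-occurrence states, capability calls
#' and oxygen-tolerance verdicts, and reports per-component agreement
#' plus precision/recall of the three functional calls.
#'
#' @param survey `h2ase_survey` over the generated genomes.
#' @param truth Truth tibble from the generator.
#' @return List of tibbles: `presence`, `motifs`, `arrangements`,
#'   `capability`, `o2`, plus `summary` (one row of agreement metrics).
#' @export
score_against_truth <- function(survey, truth) {
  truth_pres <- truth$presence |> list_rbind()
  pres <- survey$presence |>
    select("genome_id", "family", "status", "copy_number") |>
    left_join(truth_pres, by = c("genome_id", "family"),
              suffix = c("", "_expected")) |>
    mutate(match = .data$status == .data$status_expected &
             .data$copy_number == .data$copy_number_expected)

  truth_mot <- truth$motifs |> list_rbind()
  obs_verdicts <- if (nrow(survey$motif_reports)) {
    survey$motif_reports |>
      group_by(.data$genome_id, .data$family) |>
      summarise(verdict = if (any(.data$verdict == "degenerate")) {
        "degenerate"
      } else "conserved", .groups = "drop")
  } else {
    tibble(genome_id = character(), family = character(),
           verdict = character())
  }
  mot <- truth_mot |>
    left_join(obs_verdicts, by = c("genome_id", "family"),
              suffix = c("_expected", "")) |>
    mutate(match = !is.na(.data$verdict) &
             .data$verdict == .data$verdict_expected)

  truth_arr <- truth$arrangements |> list_rbind()
  arr <- truth_arr |>
    left_join(select(survey$arrangements, "genome_id", "system", "label"),
              by = c("genome_id", "system"), suffix = c("_expected", "")) |>
    mutate(match = !is.na(.data$label) &
             .data$label == .data$label_expected)

  capab <- truth |>
    select("genome_id", "hox_functional", "hup_functional",
           "nitrogen_fixing", "hox_state", "hup_state", "nif_state") |>
    left_join(survey$capability |>
                select("genome_id", "hox_functional", "hup_functional",
                       "nitrogen_fixing"),
              by = "genome_id", suffix = c("_expected", "")) |>
    left_join(survey$categories, by = "genome_id",
              suffix = c("_expected", "")) |>
    mutate(match = .data$hox_functional == .data$hox_functional_expected &
             .data$hup_functional == .data$hup_functional_expected &
             .data$nitrogen_fixing == .data$nitrogen_fixing_expected &
             .data$hox_state == .data$hox_state_expected &
             .data$hup_state == .data$hup_state_expected &
             .data$nif_state == .data$nif_state_expected)

  truth_o2 <- purrr::map2(truth$genome_id, truth$o2_tolerant, function(g, t) {
    if (nrow(t)) mutate(t, genome_id = g, .before = 1L)
  }) |> purrr::compact() |> list_rbind()
  obs_o2 <- purrr::map2(survey$capability$genome_id,
                        survey$capability$o2_tolerant, function(g, t) {
    if (nrow(t)) mutate(select(t, "group", "verdict"), genome_id = g,
                        .before = 1L)
  }) |> purrr::compact() |> list_rbind()
  o2 <- if (!is.null(truth_o2) && nrow(truth_o2)) {
    truth_o2 |>
      left_join(obs_o2, by = c("genome_id", "group"),
                suffix = c("_expected", "")) |>
      mutate(match = !is.na(.data$verdict) &
               .data$verdict == .data$verdict_expected)
  } else {
    tibble(genome_id = character(), group = character(), match = logical())
  }
  spurious_o2 <- if (!is.null(obs_o2) && nrow(obs_o2)) {
    nrow(anti_join(obs_o2, truth_o2 %||%
                     tibble(genome_id = character(), group = character()),
                   by = c("genome_id", "group")))
  } else 0L

  pr <- function(flag) {
    obs <- setNames(survey$capability[[flag]], survey$capability$genome_id)
    exp <- setNames(truth[[flag]], truth$genome_id)[names(obs)]
    tp <- sum(obs & exp); fp <- sum(obs & !exp); fn <- sum(!obs & exp)
    c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
      recall = if (tp + fn == 0) 1 else tp / (tp + fn))
  }
  hoxpr <- pr("hox_functional"); huppr <- pr("hup_functional")
  nifpr <- pr("nitrogen_fixing")

  list(
    presence = pres, motifs = mot, arrangements = arr, capability = capab,
    o2 = o2,
    summary = tibble(
      presence_agreement = mean(pres$match),
      motif_agreement = if (nrow(mot)) mean(mot$match) else 1,
      arrangement_agreement = if (nrow(arr)) mean(arr$match) else 1,
      capability_agreement = mean(capab$match),
      o2_agreement = if (nrow(o2)) mean(o2$match) else 1,
      spurious_o2_calls = spurious_o2,
      hox_precision = hoxpr[["precision"]], hox_recall = hoxpr[["recall"]],
      hup_precision = huppr[["precision"]], hup_recall = huppr[["recall"]],
      nif_precision = nifpr[["precision"]], nif_recall = nifpr[["recall"]]
    )
  )
}
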