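# ggplot2 displays for the survey's result tables.

#' Presence/absence heatmap of a survey
#'
#' Tile map of genomes by families with the three display states:
#' present, present with degenerate catalytic residues, absent.
#'
#' @param object An `h2ase_survey`.
#' @param families Optional family subset (default: hox, hup, hyp, nif).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.h2ase_survey <- function(object,
                                  families = c(HOX_SYSTEM, HUP_SYSTEM,
                                               HYP_SYSTEM, NIF_ESSENTIAL),
                                  ...) {
  d <- object$presence |>
    filter(.data$family %in% families) |>
    mutate(family = factor(.data$family, levels = families),
           status = factor(.data$status,
                           levels = c("present", "present_degenerate",
                                      "absent")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$genome_id,
                                  fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = c(present = "#1b7837", present_degenerate = "#a6dba0",
                 absent = "#c2373b"),
      drop = FALSE, name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked co-occurrence bars per stratum
#'
#' One bar per stratum, stacked by the (hox, hup, nif) category
#' combination, labelled with display percentages.
#'
#' @param summary_table Output of [summarize_cooccurrence()].
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(summary_table) {
  d <- summary_table |>
    mutate(combo = paste0("hox", ifelse(.data$hox_state == "complete", "+",
                                        ifelse(.data$hox_state == "absent",
                                               "-", "~")),
                          " hup", ifelse(.data$hup_state == "complete", "+",
                                         ifelse(.data$hup_state == "absent",
                                                "-", "~")),
                          " nif", ifelse(.data$nif_state == "complete", "+",
                                         ifelse(.data$nif_state == "absent",
                                                "-", "~"))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = .data$percentage,
                                  fill = .data$combo)) +
    ggplot2::geom_col(position = "stack", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::scale_fill_brewer(palette = "Set3", name = "gene sets") +
    ggplot2::labs(x = NULL, y = "% of stratum") +
    ggplot2::theme_minimal()
}
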