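# Central vocabularies of the survey: gene families, habitats, subsections.

#' @noRd
HOX_STRUCTURAL <- c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH")
#' @noRd
HOX_SYSTEM <- c(HOX_STRUCTURAL, "hoxW")
#' @noRd
HUP_SYSTEM <- c("hupS", "hupL", "hupW")
#' @noRd
HYP_SYSTEM <- paste0("hyp", LETTERS[1:6])
#' @noRd
NIF_ESSENTIAL <- c("nifH", "nifD", "nifK", "nifB", "nifE", "nifN")
#' @noRd
NIF_DISPENSABLE <- c("nifU", "nifS", "nifV")
#' @noRd
MBH_ACCESSORY_CORE <- c("hoxZ", "hoxM")
#' @noRd
MBH_ACCESSORY_FULL <- c("hoxZ", "hoxM", "hoxL", "hoxO", "hoxQ",
                        "hoxR", "hoxT", "hoxV")
#' @noRd
SH3B_SUBUNITS <- paste0("sh3b_", c("alpha", "beta", "gamma", "delta"))
#' @noRd
O2_PROBES <- c("mbh1_large", "mbh1_small", SH3B_SUBUNITS)

#' @noRd
ALL_FAMILIES <- c(HOX_SYSTEM, HUP_SYSTEM, HYP_SYSTEM, NIF_ESSENTIAL,
                  NIF_DISPENSABLE, "xisC", MBH_ACCESSORY_FULL, O2_PROBES)

#' @noRd
HABITATS <- c("freshwater", "open_ocean", "coastal", "terrestrial",
              "hot_spring", "salt_lake", "other")
#' @noRd
SUBSECTIONS <- c("I", "II", "III", "IV", "V", "unknown")

#' Gene families recognised by the default survey panel
#'
#' Returns the closed vocabulary of family names used throughout the
#' pipeline: hox structural genes and their endopeptidase, hup structural
#' genes and peptidase, the six hyp maturation factors, nitrogenase
#' structural and cofactor genes, the xisC recombinase, the membrane-bound
#' hydrogenase (MBH) accessory genes, and the oxygen-tolerant hydrogenase
#' probe families (group 1 MBH large/small subunits and the four group 3b
#' subunits).
#'
#' @param system Optional system filter: one of `"hox"`, `"hup"`, `"hyp"`,
#'   `"nif"`, `"o2"`, `"accessory"`; `NULL` returns every family.
#' @return Character vector of family names.
#' @export
#' @examples
#' survey_families("hyp")
survey_families <- function(system = NULL) {
  if (is.null(system)) return(ALL_FAMILIES)
  switch(match.arg(system, c("hox", "hup", "hyp", "nif", "o2", "accessory")),
    hox = HOX_SYSTEM,
    hup = HUP_SYSTEM,
    hyp = HYP_SYSTEM,
    nif = c(NIF_ESSENTIAL, NIF_DISPENSABLE),
    o2 = O2_PROBES,
    accessory = MBH_ACCESSORY_FULL
  )
}
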