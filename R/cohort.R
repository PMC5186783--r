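# Cohort-level generation: mixes of planted genome categories with
# deterministic apportionment, and the curated 30-genome survey design
# that spans every supported arrangement label, planted degenerate
# motifs, incomplete sets and hydrogenase-free genomes.

# largest-remainder apportionment of n among named proportions
apportion <- function(n, props) {
  if (abs(sum(props) - 1) > 1e-8) abort("mix proportions must sum to 1")
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base) |> setNames(names(props))
}

derive_seed <- function(master, i) {
  (abs(as.integer(master)) %% 2000000L) * 1000L + as.integer(i)
}

ARCHETYPES <- list(
  hox_only = function(i) list(
    hox = list(arrangement = c("G1", "G2", "G7")[(i %% 3L) + 1L]),
    hyp = list(arrangement = c("1", "2")[(i %% 2L) + 1L])),
  hup_only = function(i) list(
    hup = list(arrangement = c("G1", "G2")[(i %% 2L) + 1L]),
    hyp = list(arrangement = "1"),
    nif = list()),
  both = function(i) list(
    hox = list(arrangement = "G1"), hup = list(arrangement = "G1"),
    hyp = list(arrangement = "1"), nif = list()),
  none = function(i) if (i %% 2L == 0L) list(nif = list()) else list()
)

#' Generate a synthetic cohort with a requested category mix
#'
#' Category counts follow the mix proportions under largest-remainder
#' rounding; per-genome seeds derive from the master seed, so the same
#' seed reproduces the cohort byte for byte.
#'
#' @param n Number of genomes (positive).
#' @param mix Named proportions over `hox_only`, `hup_only`, `both`,
#'   `none`; must sum to 1.
#' @param habitat_mix Named proportions over habitat labels.
#' @param seed Master integer seed.
#' @param dir Optional output directory for the genome files plus
#'   `truth.tsv` and `metadata.tsv`.
#' @return List with `genomes` (list of `genome` objects), `truth`
#'   (truth tibble, one row per genome) and `specs`.
#' @export
generate_cohort <- function(n,
                            mix = c(hox_only = 0.3, hup_only = 0.2,
                                    both = 0.2, none = 0.3),
                            habitat_mix = c(freshwater = 0.4, coastal = 0.15,
                                            open_ocean = 0.15,
                                            terrestrial = 0.15,
                                            hot_spring = 0.1,
                                            salt_lake = 0.05),
                            seed = 1L, dir = NULL) {
  if (n <= 0) abort("n must be positive")
  if (!all(names(mix) %in% names(ARCHETYPES))) {
    abort(paste0("unknown mix categories: ",
                 paste(setdiff(names(mix), names(ARCHETYPES)), collapse = ", ")))
  }
  counts <- apportion(n, mix)
  habitats <- rep(names(apportion(n, habitat_mix)), apportion(n, habitat_mix))
  specs <- list()
  i <- 0L
  for (cat in names(counts)) {
    for (k in seq_len(counts[[cat]])) {
      i <- i + 1L
      specs[[i]] <- plant_spec(
        genome_id = sprintf("sim%03d", i),
        habitat = habitats[i],
        subsection = SUBSECTIONS[(i %% 5L) + 1L],
        systems = ARCHETYPES[[cat]](i),
        decoys = 10L,
        seed = derive_seed(seed, i))
    }
  }
  build_cohort(specs, dir)
}

build_cohort <- function(specs, dir = NULL) {
  panel <- default_query_panel()
  out <- purrr::map(specs, generate_genome, panel = panel)
  genomes <- purrr::map(out, "genome")
  truth <- purrr::map(out, "truth") |> list_rbind()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    purrr::walk(genomes, write_genome, dir = dir)
    readr::write_tsv(
      select(truth, "genome_id", "habitat", "subsection", "hox_state",
             "hup_state", "nif_state", "hox_functional", "hup_functional",
             "nitrogen_fixing"),
      file.path(dir, "truth.tsv"))
    readr::write_tsv(select(truth, "genome_id", "habitat", "subsection"),
                     file.path(dir, "metadata.tsv"))
    yaml::write_yaml(list(genomes = purrr::map_chr(genomes, "genome_id")),
                     file.path(dir, "cohort.yaml"))
  }
  list(genomes = genomes, truth = truth, specs = specs)
}

#' The curated 30-genome survey design
#'
#' A fixed cohort design covering all seven hox arrangement groups, all
#' five hup groups, six hyp partition classes, planted degenerate motifs
#' (substitution and truncation), incomplete gene sets, multicopy hoxW,
#' the three oxygen-tolerant candidate groups with their graded verdicts,
#' and a nine-genome open-ocean stratum of eight hydrogenase-free
#' genomes plus one uptake-only genome. Only gene content is designed;
#' sequences, decoys and layout remain seed-driven.
#'
#' @param seed Master integer seed.
#' @return List of [plant_spec()] objects (length 30).
#' @export
survey_cohort_specs <- function(seed = 1L) {
  hyp1 <- list(arrangement = "1")
  rows <- list(
    list(sys = list(hox = list(arrangement = "G1"),
                    hup = list(arrangement = "G1"), hyp = hyp1,
                    nif = list()), hab = "freshwater", sub = "IV"),
    list(sys = list(hox = list(arrangement = "G2"),
                    hup = list(arrangement = "G2"),
                    hyp = list(arrangement = "2"), nif = list()),
         hab = "freshwater", sub = "I"),
    list(sys = list(hox = list(arrangement = "G3"),
                    hup = list(arrangement = "G3"),
                    hyp = list(arrangement = "4+2"), nif = list()),
         hab = "terrestrial", sub = "IV"),
    list(sys = list(hox = list(arrangement = "G4"),
                    hup = list(arrangement = "G4"),
                    hyp = list(arrangement = "3+3"), nif = list()),
         hab = "coastal", sub = "V"),
    list(sys = list(hox = list(arrangement = "G5"),
                    hup = list(arrangement = "G5"),
                    hyp = list(arrangement = "2+2+2"), nif = list()),
         hab = "hot_spring", sub = "IV"),
    list(sys = list(hox = list(arrangement = "G6"),
                    hyp = list(arrangement = "1+1+1+1+1+1"),
                    nif = list(families = NIF_ESSENTIAL)),
         hab = "salt_lake", sub = "I"),
    list(sys = list(hox = list(arrangement = "G7"), hyp = hyp1,
                    nif = list()), hab = "freshwater", sub = "V"),
    list(sys = list(hup = list(arrangement = "G1"), hyp = hyp1,
                    nif = list()), hab = "terrestrial", sub = "IV"),
    list(sys = list(hox = list(arrangement = "G1"),
                    hyp = list(arrangement = "2")),
         hab = "freshwater", sub = "III"),
    list(sys = list(hox = list(arrangement = "G1"), hyp = hyp1),
         mut = list(list(family = "hoxH", site = 62L, to = "A")),
         hab = "freshwater", sub = "III"),
    list(sys = list(hup = list(arrangement = "G1"), hyp = hyp1,
                    nif = list()),
         mut = list(list(family = "hupS", truncate_fraction = 0.7)),
         hab = "coastal", sub = "IV"),
    list(sys = list(hox = list(families = c("hoxE", "hoxF", "hoxU")),
                    hyp = hyp1, nif = list(families = NIF_ESSENTIAL)),
         hab = "freshwater", sub = "II"),
    list(sys = list(hup = list(families = c("hupS", "hupL")),
                    hyp = list(arrangement = "2"), nif = list()),
         hab = "terrestrial", sub = "IV"),
    list(sys = list(hox = list(arrangement = "G2"),
                    hyp = list(families = c("hypA", "hypB")),
                    nif = list(families = NIF_ESSENTIAL)),
         hab = "freshwater", sub = "I"),
    list(sys = list(hox = list(families = "hoxW"),
                    nif = list(families = NIF_ESSENTIAL)),
         extra = c(hoxW = 2L), hab = "coastal", sub = "I"),
    list(sys = list(mbh1 = list(), accessory = list(), hyp = hyp1),
         hab = "coastal", sub = "III"),
    list(sys = list(mbh1 = list(),
                    accessory = list(families = MBH_ACCESSORY_FULL),
                    hyp = hyp1),
         hab = "terrestrial", sub = "II"),
    list(sys = list(mbh1 = list(), accessory = list(), hyp = hyp1),
         mut = list(list(family = "mbh1_small", site = 115L, to = "S")),
         hab = "terrestrial", sub = "I"),
    list(sys = list(sh3b = list(), hyp = hyp1, nif = list()),
         hab = "freshwater", sub = "I"),
    list(sys = list(sh3b = list(),
                    hyp = list(families = c("hypA", "hypB"))),
         hab = "freshwater", sub = "III"),
    list(sys = list(nif = list()), hab = "freshwater", sub = "IV",
         dec = 12L,
         par = list(list(family = "hoxH", identity = 0.7))),
    list(sys = list(hup = list(arrangement = "G2"), hyp = hyp1,
                    nif = list()), hab = "open_ocean", sub = "I"),
    list(sys = list(nif = list(families = NIF_ESSENTIAL)),
         hab = "open_ocean", sub = "I", dec = 12L),
    list(sys = list(nif = list()), hab = "open_ocean", sub = "I",
         dec = 10L, par = list(list(family = "hoxY", identity = 0.65))),
    list(sys = list(nif = list(families = c("nifH", "nifD", "nifK"))),
         hab = "open_ocean", sub = "I", dec = 10L),
    list(sys = list(), hab = "open_ocean", sub = "I", dec = 12L),
    list(sys = list(), hab = "open_ocean", sub = "I", dec = 10L,
         par = list(list(family = "nifH", identity = 0.7))),
    list(sys = list(nif = list()), hab = "open_ocean", sub = "I",
         dec = 11L),
    list(sys = list(), hab = "open_ocean", sub = "II", dec = 10L),
    list(sys = list(nif = list(families = NIF_ESSENTIAL)),
         hab = "open_ocean", sub = "II", dec = 12L)
  )
  purrr::imap(rows, function(r, i) {
    plant_spec(genome_id = sprintf("syn%02d", i),
               habitat = r$hab, subsection = r$sub, systems = r$sys,
               mutations = r$mut %||% list(),
               decoys = r$dec %||% 8L,
               paralog_decoys = r$par %||% list(),
               extra_copies = r$extra %||% integer(),
               seed = derive_seed(seed, i))
  })
}

#' Generate the curated 30-genome survey cohort
#'
#' @inheritParams survey_cohort_specs
#' @param dir Optional output directory (see [generate_cohort()]).
#' @return As [generate_cohort()].
#' @export
generate_survey_cohort <- function(seed = 1L, dir = NULL) {
  build_cohort(survey_cohort_specs(seed), dir)
}
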