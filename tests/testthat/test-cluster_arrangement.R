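# Co-localization detection and canonical arrangement labels.

# genome whose genes are the named families, in order; "bg" entries are
# background genes
family_genome <- function(fams, strand = NULL, genome_id = "cg") {
  seqs <- setNames(as.list(strrep("A", 120 + seq_along(fams))),
                   paste0(genome_id, "_", make.unique(fams)))
  toy_genome(seqs, genome_id = genome_id, strand = strand)
}

presence_for <- function(fams, genome_id = "cg") {
  fams <- fams[fams != "bg"]
  toy_presence(setNames(rep("present", length(fams)), fams),
               genome_id = genome_id)
}

test_that("adjacent same-strand members form one cluster", {
  fams <- c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH")
  g <- family_genome(fams)
  cl <- find_clusters(g, presence_for(fams), "hox")
  expect_identical(nrow(cl), 5L)
  expect_identical(length(unique(cl$cluster_id)), 1L)
})

test_that("the co-localization boundary is exactly max_intervening", {
  base <- c("hoxE", rep("bg", 3), "hoxF")
  g3 <- family_genome(base)
  pres <- presence_for(base)
  cl3 <- find_clusters(g3, pres, "hox", max_intervening = 3L)
  expect_identical(length(unique(cl3$cluster_id)), 1L)

  base4 <- c("hoxE", rep("bg", 4), "hoxF")
  cl4 <- find_clusters(family_genome(base4), presence_for(base4), "hox",
                       max_intervening = 3L)
  expect_identical(length(unique(cl4$cluster_id)), 2L)
})

mirror_genome <- function(g) {
  L <- max(g$features$end) + 500L
  f <- g$features
  new_start <- L - f$end
  f$end <- L - f$start
  f$start <- new_start
  f$strand <- ifelse(f$strand == "+", "-", "+")
  genome(g$genome_id, g$proteins, f,
         habitat = g$metadata$habitat, subsection = g$metadata$subsection)
}

test_that("clustering and labels are invariant under coordinate mirroring", {
  spec <- plant_spec("mir", systems = list(
    hox = list(arrangement = "G1"), hup = list(arrangement = "G2"),
    hyp = list(arrangement = "2")), decoys = 6L, seed = 33L)
  g <- generate_genome(spec)$genome
  pres <- toy_presence(setNames(
    rep("present", 15),
    c(survey_families("hox"), survey_families("hup"),
      survey_families("hyp"))), genome_id = "mir")
  pres$member_protein_ids <- purrr::map(pres$family, function(f) {
    if (pres$status[pres$family == f] == "present") paste0("mir_", f)
    else character()
  })
  arr1 <- classify_arrangements(g, pres)
  arr2 <- classify_arrangements(mirror_genome(g), pres)
  expect_identical(arr1$label, arr2$label)
  expect_identical(arr1$partition_signature, arr2$partition_signature)
})

test_that("hox groups 1-3 follow the canonical definitions", {
  # G1: EFUYH cluster + distal W
  f1 <- c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH", rep("bg", 5), "hoxW")
  g1 <- family_genome(f1)
  cl1 <- find_clusters(g1, presence_for(f1), "hox")
  expect_identical(classify_hox(cl1)$label, "G1")

  # G2: all six together
  f2 <- c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH", "hoxW")
  cl2 <- find_clusters(family_genome(f2), presence_for(f2), "hox")
  expect_identical(classify_hox(cl2)$label, "G2")

  # G3: EFUY + distal H + distal W
  f3 <- c("hoxE", "hoxF", "hoxU", "hoxY", rep("bg", 5), "hoxH",
          rep("bg", 5), "hoxW")
  cl3 <- find_clusters(family_genome(f3), presence_for(f3), "hox")
  expect_identical(classify_hox(cl3)$label, "G3")

  # mixed orientation in the main cluster drops out of G1
  g1m <- family_genome(f1, strand = c("+", "-", "+", "+", "+",
                                      rep("+", 5), "+"))
  cl1m <- find_clusters(g1m, presence_for(f1), "hox")
  expect_identical(classify_hox(cl1m)$label, "unclassified")

  # incomplete set is a contract violation
  expect_error(classify_hox(cl1[cl1$family != "hoxW", ]), "complete")
})

test_that("hup labels differ across the two axes and degenerate layouts", {
  f <- c("hupS", "hupL", "hupW")
  cl <- find_clusters(family_genome(f), presence_for(f), "hup")
  lab_clustered_none <- classify_hup(cl, "none")
  expect_identical(lab_clustered_none$label, "G1")

  fd <- c("hupS", "hupL", rep("bg", 5), "hupW")
  cld <- find_clusters(family_genome(fd), presence_for(fd), "hup")
  lab_distal_xisL <- classify_hup(cld, "hupL")
  expect_identical(lab_distal_xisL$label, "G4")
  expect_false(identical(lab_clustered_none$label, lab_distal_xisL$label))
  expect_identical(lab_distal_xisL$interrupted_by, "xisC")

  # hupS and hupL far apart: outside the taxonomy
  fu <- c("hupS", rep("bg", 6), "hupL", "hupW")
  clu <- find_clusters(family_genome(fu), presence_for(fu), "hup")
  expect_identical(classify_hup(clu, "none")$label, "unclassified")
})

test_that("hyp classes follow the partition signatures", {
  f1 <- survey_families("hyp")
  cl1 <- find_clusters(family_genome(f1), presence_for(f1), "hyp")
  expect_identical(classify_hyp(cl1)$label, "1")

  f2 <- c(f1[1:5], rep("bg", 5), f1[6])
  cl2 <- find_clusters(family_genome(f2), presence_for(f2), "hyp")
  expect_identical(classify_hyp(cl2)$label, "2")

  f6 <- c(rbind(f1, matrix(rep("bg", 30), nrow = 5)))
  cl6 <- find_clusters(family_genome(f6), presence_for(f6), "hyp")
  r6 <- classify_hyp(cl6)
  expect_identical(r6$label, "1+1+1+1+1+1")
  # partition property: each member in exactly one block
  expect_identical(sort(cl6$family), sort(f1))
})

test_that("xisC interruption is detected in nested and split forms", {
  # nested: xisC inside the hupL span
  seqs <- list(cg_hupS = strrep("A", 100), cg_hupL = strrep("A", 400),
               cg_xisC = strrep("A", 80), cg_hupW = strrep("A", 90))
  g <- toy_genome(seqs, genome_id = "cg")
  f <- g$features
  f$start[f$gene_id == "cg_xisC"] <- f$start[f$gene_id == "cg_hupL"] + 90L
  f$end[f$gene_id == "cg_xisC"] <- f$start[f$gene_id == "cg_xisC"] + 243L
  g <- genome("cg", g$proteins, f)
  pres <- toy_presence(c(hupS = "present", hupL = "present",
                         hupW = "present", xisC = "present"),
                       genome_id = "cg")
  expect_identical(detect_xisc_interruption(g, pres), "hupL")

  # split: two hupS fragments flanking xisC
  seqs2 <- list(cg_hupS = strrep("A", 60), cg_xisC = strrep("A", 80),
                cg_hupS2 = strrep("A", 60), cg_hupL = strrep("A", 400))
  g2 <- toy_genome(seqs2, genome_id = "cg")
  pres2 <- pres
  pres2$member_protein_ids[pres2$family == "hupS"] <-
    list(c("cg_hupS", "cg_hupS2"))
  expect_identical(detect_xisc_interruption(g2, pres2), "hupS")

  # no xisC present at all
  pres3 <- toy_presence(c(hupS = "present", hupL = "present",
                          hupW = "present"), genome_id = "cg")
  expect_identical(detect_xisc_interruption(g, pres3), "none")
})

test_that("a member without coordinates is an error", {
  fams <- c("hoxE", "hoxF")
  g <- family_genome(fams)
  pres <- presence_for(c(fams, "hoxU"))
  pres$member_protein_ids[pres$family == "hoxU"] <- list("cg_hoxU")
  expect_error(find_clusters(g, pres, "hox"), "without coordinates")
})

test_that("generated arrangements round-trip for every supported label", {
  cases <- list(
    list(system = "hox", labels = paste0("G", 1:7)),
    list(system = "hup", labels = paste0("G", 1:5)),
    list(system = "hyp", labels = c("1", "2", "4+2", "3+3", "2+2+2",
                                    "1+1+1+1+1+1"))
  )
  seed <- 100L
  for (case in cases) {
    for (lab in case$labels) {
      seed <- seed + 1L
      systems <- setNames(list(list(arrangement = lab)), case$system)
      spec <- plant_spec(paste0("rt_", case$system, "_", lab),
                         systems = systems, decoys = 4L, seed = seed)
      gg <- generate_genome(spec)
      sv <- suppressMessages(run_survey(list(gg$genome)))
      got <- sv$arrangements$label[sv$arrangements$system == case$system]
      expect_identical(got, lab,
                       label = paste(case$system, lab, "->", got))
    }
  }
})
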