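# Thresholded family search and reciprocal-best-hit confirmation.

make_target_proteome <- function(n, seed, lengths = 150:400) {
  hydroscan:::with_seed(seed, {
    tibble::tibble(
      protein_id = sprintf("t%02d", seq_len(n)),
      genome_id = "tg",
      sequence = vapply(seq_len(n), function(i) {
        hydroscan:::random_protein(sample(lengths, 1))
      }, character(1)))
  })
}

test_that("a planted homolog is recovered exactly from a decoy proteome", {
  panel <- default_query_panel()
  prot <- make_target_proteome(50, seed = 11)
  planted <- hydroscan:::with_seed(12, mutate_protein(
    panel$sequence[panel$family == "hoxH"], identity = 0.95))
  prot$sequence[25] <- planted
  g <- genome("tg", prot,
              tibble::tibble(gene_id = character(), genome_id = character(),
                             replicon_id = character(), start = integer(),
                             end = integer(), strand = character(),
                             protein_id = character()))
  hits <- search_family("hoxH", g, panel)
  expect_identical(hits$protein_id, "t25")
  expect_true(all(hits$evalue <= panel$threshold[panel$family == "hoxH"]))
})

test_that("random proteomes yield no hits at the structural threshold", {
  panel <- default_query_panel()
  prot <- make_target_proteome(20, seed = 21)
  g <- genome("tg", prot, tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character()))
  hits <- search_family("hoxH", g, panel)
  expect_identical(nrow(hits), 0L)
})

test_that("an infinite threshold returns every protein", {
  panel <- default_query_panel()
  panel$threshold[panel$family == "hoxH"] <- Inf
  prot <- make_target_proteome(8, seed = 22)
  g <- genome("tg", prot, tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character()))
  hits <- search_family("hoxH", g, panel)
  expect_identical(nrow(hits), 8L)
  expect_true(all(diff(hits$evalue) >= 0))  # sorted ascending
})

test_that("search output is invariant under proteome permutation", {
  panel <- default_query_panel()
  prot <- make_target_proteome(12, seed = 23)
  prot$sequence[4] <- hydroscan:::with_seed(24, mutate_protein(
    panel$sequence[panel$family == "hypB"], identity = 0.9))
  empty_feats <- tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character())
  g1 <- genome("tg", prot, empty_feats)
  g2 <- genome("tg", prot[rev(seq_len(nrow(prot))), ], empty_feats)
  h1 <- search_family("hypB", g1, panel)
  h2 <- search_family("hypB", g2, panel)
  expect_identical(h1, h2)
})

test_that("RBH confirms the only candidate and rejects weaker pairings", {
  panel <- default_query_panel()
  ref <- default_reference_proteome(panel)
  # single true homolog: reciprocal in both directions
  planted <- hydroscan:::with_seed(31, mutate_protein(
    panel$sequence[panel$family == "hypD"], identity = 0.95))
  prot <- make_target_proteome(10, seed = 32)
  prot$sequence[3] <- planted
  g <- genome("tg", prot, tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character()))
  hit <- list(protein_id = "t03", best_query_id = "hypD_ref")
  expect_true(confirm_rbh(hit, g, ref))

  # a closer paralog of a different reference member: the weaker pairing
  # (decoy vs searched family) must fail
  decoy <- hydroscan:::with_seed(33, mutate_protein(
    ref$sequence[ref$protein_id == "shadow_maturase"], identity = 0.8))
  prot$sequence[7] <- decoy
  g2 <- genome("tg", prot, tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character()))
  expect_false(confirm_rbh(list(protein_id = "t07",
                                best_query_id = "hypD_ref"), g2, ref))
  expect_error(confirm_rbh(list(protein_id = "nope",
                                best_query_id = "hypD_ref"), g2, ref),
               "not in genome")
})

test_that("the RBH relation is symmetric across the two proteomes", {
  # two small proteomes; check confirm_rbh(q -> t) == confirm_rbh(t -> q)
  # by swapping the roles of genome and reference
  hydroscan:::with_seed(41, {
    base <- replicate(4, hydroscan:::random_protein(120))
    pa <- tibble::tibble(
      protein_id = paste0("a", 1:4), genome_id = "A",
      sequence = vapply(base, mutate_protein, character(1),
                        identity = 0.9))
    pb <- tibble::tibble(
      protein_id = paste0("b", 1:4), genome_id = "B",
      sequence = vapply(base, mutate_protein, character(1),
                        identity = 0.85))
  })
  empty_feats <- tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character())
  ga <- genome("A", pa, empty_feats)
  gb <- genome("B", pb, empty_feats)
  ref_a <- dplyr::mutate(pa, family = NA_character_)
  ref_b <- dplyr::mutate(pb, family = NA_character_)
  for (i in 1:4) for (j in 1:4) {
    fwd <- confirm_rbh(list(protein_id = paste0("b", j),
                            best_query_id = paste0("a", i)), gb, ref_a)
    rev <- confirm_rbh(list(protein_id = paste0("a", i),
                            best_query_id = paste0("b", j)), ga, ref_b)
    expect_identical(fwd, rev)
  }
})

test_that("scores climb monotonically along an identity ladder", {
  panel <- default_query_panel()
  q <- panel$sequence[panel$family == "hoxY"]
  p <- alignment_params()
  scores <- hydroscan:::with_seed(51, vapply(
    c(0.5, 0.65, 0.8, 0.9, 0.98, 1.0), function(id) {
      local_align_score(q, mutate_protein(q, id), p)
    }, integer(1)))
  expect_true(all(diff(scores) >= 0))
})

test_that("scan_genome separates paralogous families by back-search", {
  # a genome with a true hupL: searching hoxH finds it (paralogy) but
  # must not RBH-confirm it, and its back-family must be hupL
  panel <- default_query_panel()
  spec <- plant_spec("px", systems = list(
    hup = list(families = c("hupS", "hupL", "hupW"))), decoys = 4L,
    seed = 61L)
  g <- generate_genome(spec)$genome
  hits <- scan_genome(g, panel)
  hoxh_hits <- hits[hits$family == "hoxH", ]
  expect_true(nrow(hoxh_hits) >= 1L)
  expect_false(any(hoxh_hits$rbh))
  expect_true(all(hoxh_hits$back_family == "hupL"))
  hupl_hits <- hits[hits$family == "hupL", ]
  expect_true(any(hupl_hits$rbh))
})
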