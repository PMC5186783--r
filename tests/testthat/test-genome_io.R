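# Format readers/writers and the internal coordinate convention.

test_that("FASTA reading normalises case and stop codons", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "mkval", "RNDc*",
               ">p2", "ARNDX"), f)
  recs <- read_fasta(f, genome_id = "g")
  expect_identical(recs$protein_id, c("p1", "p2"))
  expect_identical(recs$sequence, c("MKVALRNDC", "ARNDX"))
  expect_identical(recs$genome_id, c("g", "g"))
})

test_that("FASTA reading rejects malformed or invalid input", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c("p1", "ARND"), f)
  expect_error(read_fasta(f), "lacks '>'")

  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")

  writeLines(c(">p1", "ARND", ">p1", "RNDA"), f)
  expect_error(read_fasta(f), "duplicate protein id.*p1")

  writeLines(c(">p1", "ARBD"), f)  # B is not in the 20+X alphabet
  expect_error(read_fasta(f), "non-standard")
})

test_that("FASTA round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".faa")
  prot <- tibble::tibble(protein_id = c("a", "b"),
                         sequence = c("MKV", "ARNDX"))
  write_fasta(prot, f)
  back <- read_fasta(f, genome_id = "g")
  expect_identical(back$protein_id, prot$protein_id)
  expect_identical(back$sequence, prot$sequence)
})

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t11\t40\t.\t+\t0\tID=g1;protein_id=p1",
               "chr\tsrc\tCDS\t61\t90\t.\t-\t0\tID=g2;protein_id=p2",
               "chr\tsrc\tgene\t5\t95\t.\t+\t.\tID=skipme"), f)
  feats <- read_features(f, "gff3", genome_id = "g")
  expect_identical(nrow(feats), 2L)                 # only CDS rows
  expect_identical(feats$start, c(10L, 60L))
  expect_identical(feats$end, c(40L, 90L))
  expect_identical(feats$strand, c("+", "-"))
  # feature length: end - start internally, end - start + 1 in GFF3
  expect_identical(feats$end - feats$start, c(30L, 30L))

  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, out, source = "src")
  reread <- read_features(out, "gff3", genome_id = "g")
  expect_identical(reread$start, feats$start)
  expect_identical(reread$end, feats$end)
  # printed 1-based coordinates preserved exactly
  printed <- read.delim(out, header = FALSE, skip = 1)
  expect_identical(as.integer(printed$V4), c(11L, 61L))
  expect_identical(as.integer(printed$V5), c(40L, 90L))
})

test_that("undefined strand on a CDS is an error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t11\t40\t.\t.\t0\tID=g1;protein_id=p1"), f)
  expect_error(read_features(f, "gff3"), "strand")
})

test_that("feature TSV dialect round-trips unchanged", {
  feats <- tibble::tibble(
    gene_id = c("g1", "g2"), genome_id = "g", replicon_id = "chr",
    start = c(10L, 400L), end = c(40L, 700L), strand = c("+", "-"),
    protein_id = c("p1", NA))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(feats, f)
  back <- read_features(f, "tsv", genome_id = "g")
  expect_identical(back$start, feats$start)
  expect_identical(back$end, feats$end)
  expect_identical(back$protein_id, feats$protein_id)
  expect_identical(back$strand, feats$strand)
})

test_that("feature order is stable and inverted intervals are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\treplicon_id\tstart\tend\tstrand\tprotein_id",
               "g2\tchr\t500\t700\t-\tp2",
               "g1\tchr\t11\t40\t+\tp1"), f)
  feats <- read_features(f, "tsv")
  expect_identical(feats$gene_id, c("g2", "g1"))  # input order kept

  writeLines(c("gene_id\treplicon_id\tstart\tend\tstrand\tprotein_id",
               "g1\tchr\t40\t11\t+\tp1"), f)
  expect_error(read_features(f, "tsv"), "end <= start")
})

test_that("metadata applies the fallback vocabulary rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\thabitat\tsubsection",
               "g1\tfreshwater\tIV",
               "g2\tswamp\tII",
               "g3\topen_ocean\t"), f)
  expect_warning(meta <- read_metadata(f), "swamp")
  expect_identical(meta$habitat, c("freshwater", "other", "open_ocean"))
  expect_identical(meta$subsection, c("IV", "II", "unknown"))

  writeLines(c("genome_id\thabitat\tsubsection",
               "g1\tfreshwater\tI",
               "g1\tcoastal\tII"), f)
  expect_error(read_metadata(f), "duplicate genome_id")
})

test_that("newick trees parse and expose leaves", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a,(b,c));", f)
  expect_setequal(read_newick(f)$tip.label, c("a", "b", "c"))

  writeLines("(a,(b,c)", f)
  expect_error(read_newick(f), "parse")
})

test_that("genome objects enforce protein linkage", {
  prot <- tibble::tibble(protein_id = "p1", genome_id = "g",
                         sequence = "MKV")
  feats <- tibble::tibble(gene_id = "g1", genome_id = "g",
                          replicon_id = "chr", start = 0L, end = 12L,
                          strand = "+", protein_id = "p2")
  expect_error(genome("g", prot, feats), "does not resolve")
})

test_that("a genome survives a write/read round trip", {
  spec <- plant_spec("rt1", habitat = "freshwater", subsection = "I",
                     systems = list(hyp = list(arrangement = "1")),
                     decoys = 3L, seed = 9L)
  g <- generate_genome(spec)$genome
  dir <- withr::local_tempdir()
  write_genome(g, dir)
  meta <- tibble::tibble(genome_id = "rt1", habitat = "freshwater",
                         subsection = "I")
  back <- read_genome(dir, "rt1", meta)
  expect_identical(back$proteins$sequence, g$proteins$sequence)
  expect_identical(back$features$start, g$features$start)
  expect_identical(back$features$end, g$features$end)
  expect_identical(back$metadata$habitat, "freshwater")
})
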