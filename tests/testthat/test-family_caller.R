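# Presence calling, completeness rules and the three-criteria
# capability verdicts.

toy_hit <- function(family, protein_id, rbh, back_family = family,
                    genome_id = "toy") {
  tibble::tibble(family = family, genome_id = genome_id,
                 protein_id = protein_id, best_query_id = paste0(family, "_ref"),
                 score = 500L, evalue = 1e-50, rbh = rbh,
                 back_family = back_family)
}

toy_scan_genome <- function(protein_ids, genome_id = "toy") {
  prot <- tibble::tibble(protein_id = protein_ids, genome_id = genome_id,
                         sequence = strrep("A", 50))
  genome(genome_id, prot, tibble::tibble(
    gene_id = character(), genome_id = character(),
    replicon_id = character(), start = integer(), end = integer(),
    strand = character(), protein_id = character()))
}

test_that("presence counts multicopy and rejects non-RBH-only families", {
  g <- toy_scan_genome(c("w1", "w2", "a1", "a2", "x1"))
  hits <- dplyr::bind_rows(
    toy_hit("hoxW", "w1", rbh = TRUE),
    toy_hit("hoxW", "w2", rbh = FALSE),          # second copy, same family
    toy_hit("hypA", "a1", rbh = TRUE),
    toy_hit("hypA", "a2", rbh = FALSE, back_family = "hypB"),
    toy_hit("hupL", "x1", rbh = FALSE, back_family = NA_character_))
  pres <- suppressMessages(call_presence(hits, g))
  row <- function(f) pres[pres$family == f, ]
  expect_identical(row("hoxW")$status, "present")
  expect_identical(row("hoxW")$copy_number, 2L)
  expect_identical(row("hypA")$status, "present")
  expect_identical(row("hypA")$copy_number, 1L)
  expect_identical(row("hupL")$status, "absent")
  expect_identical(row("hupL")$copy_number, 0L)
  expect_message(call_presence(hits, g), "none RBH-confirmed")
})

test_that("no hits at all means every family absent", {
  g <- toy_scan_genome("p1")
  pres <- call_presence(toy_hit("hoxH", "p1", TRUE)[0, ], g)
  expect_true(all(pres$status == "absent"))
  expect_true(all(pres$copy_number == 0L))
})

test_that("hits from another genome are rejected", {
  g <- toy_scan_genome("p1")
  expect_error(call_presence(toy_hit("hoxH", "p1", TRUE,
                                     genome_id = "other"), g),
               "different genome")
})

test_that("completeness rules follow the gene-set definitions", {
  all_hox <- setNames(rep("present", 6), survey_families("hox"))
  expect_true(complete_hox(toy_presence(all_hox)))
  # hoxW alone is a real observed state but not a complete set
  expect_false(complete_hox(toy_presence(c(hoxW = "present"))))
  deg <- all_hox; deg["hoxU"] <- "present_degenerate"
  expect_false(complete_hox(toy_presence(deg)))

  expect_true(complete_hup(toy_presence(
    c(hupS = "present", hupL = "present", hupW = "present"))))
  expect_false(complete_hup(toy_presence(
    c(hupS = "present", hupL = "present"))))

  expect_true(complete_hyp(toy_presence(
    setNames(rep("present", 6), survey_families("hyp")))))
  expect_false(complete_hyp(toy_presence(
    c(hypA = "present", hypB = "present"))))
})

test_that("nitrogen fixing ignores the dispensable nifUSV genes", {
  ess <- setNames(rep("present", 6),
                  c("nifH", "nifD", "nifK", "nifB", "nifE", "nifN"))
  expect_true(call_nitrogen_fixing(toy_presence(ess)))
  expect_true(call_nitrogen_fixing(toy_presence(
    c(ess, nifU = "absent", nifS = "absent", nifV = "absent"))))
  expect_false(call_nitrogen_fixing(toy_presence(ess[-1])))
  expect_true(call_nitrogen_fixing(toy_presence(
    c(ess, nifU = "present", nifS = "present", nifV = "present"))))
})

functional_fixture <- function() {
  status <- setNames(rep("present", 15),
                     c(survey_families("hox"), survey_families("hyp"),
                       "hupS", "hupL", "hupW"))
  pres <- toy_presence(status)
  reports <- dplyr::bind_rows(lapply(
    c("hoxE", "hoxF", "hoxU", "hoxY", "hoxH", "hupS", "hupL"),
    toy_motif_report))
  list(presence = pres, reports = reports)
}

test_that("all three criteria met gives functional calls with no reasons", {
  fx <- functional_fixture()
  cap <- call_capability(fx$presence, fx$reports)
  expect_true(cap$hox_functional)
  expect_true(cap$hup_functional)
  expect_identical(cap$reasons, "nif: essential gene set incomplete")
})

test_that("incomplete hyp blocks capability and is named as the reason", {
  fx <- functional_fixture()
  pres <- fx$presence
  pres$status[pres$family %in% c("hypC", "hypD")] <- "absent"
  cap <- call_capability(pres, fx$reports)
  expect_false(cap$hox_functional)
  expect_false(cap$hup_functional)
  expect_match(cap$reasons, "hox: hyp maturation set incomplete")
  expect_match(cap$reasons, "hup: hyp maturation set incomplete")
})

test_that("degenerate motifs block capability even with complete sets", {
  fx <- functional_fixture()
  reports <- fx$reports
  reports$verdict[reports$family == "hoxH"] <- "degenerate"
  reports$conserved[reports$family == "hoxH"] <- FALSE
  cap <- call_capability(fx$presence, reports)
  expect_false(cap$hox_functional)
  expect_true(cap$hup_functional)
  expect_match(cap$reasons, "hox: degenerate catalytic residues")
})

test_that("a missing motif report for a present subunit is an error", {
  fx <- functional_fixture()
  reports <- fx$reports[fx$reports$family != "hoxY", ]
  expect_error(call_capability(fx$presence, reports),
               "missing motif report.*hoxY")
})

test_that("capability calls are monotone under family removal", {
  fx <- functional_fixture()
  cap_full <- call_capability(fx$presence, fx$reports)
  present_fams <- fx$presence$family[fx$presence$status == "present"]
  for (f in present_fams) {
    pres <- fx$presence
    pres$status[pres$family == f] <- "absent"
    pres$copy_number[pres$family == f] <- 0L
    pres$member_protein_ids[pres$family == f] <- list(character())
    reports <- fx$reports[fx$reports$family != f, ]
    cap <- call_capability(pres, reports)
    expect_true(cap_full$hox_functional >= cap$hox_functional)
    expect_true(cap_full$hup_functional >= cap$hup_functional)
    expect_true(cap_full$nitrogen_fixing >= cap$nitrogen_fixing)
    # every false verdict carries at least one reason
    if (!cap$hox_functional || !cap$hup_functional ||
        !cap$nitrogen_fixing) {
      expect_gt(nchar(cap$reasons), 0L)
    }
  }
})

test_that("capability calling is a pure function of its inputs", {
  fx <- functional_fixture()
  expect_identical(call_capability(fx$presence, fx$reports),
                   call_capability(fx$presence, fx$reports))
})

test_that("MBH oxygen-tolerance verdicts grade on the accessory set", {
  base_status <- c(mbh1_large = "present", mbh1_small = "present",
                   setNames(rep("present", 6), survey_families("hyp")))
  sig_ok <- toy_motif_report("mbh1_small")

  # hoxZ + hoxM only: questionable, reasons list the missing accessories
  pres <- toy_presence(c(base_status, hoxZ = "present", hoxM = "present"))
  cap <- call_capability(pres, sig_ok)
  o2 <- cap$o2_tolerant[[1]]
  expect_identical(o2$verdict[o2$group == "1"], "questionable")
  expect_match(o2$reasons[o2$group == "1"], "hoxL")

  # full accessory set: candidate
  pres2 <- toy_presence(c(base_status,
                          setNames(rep("present", 8),
                                   survey_families("accessory"))))
  cap2 <- call_capability(pres2, sig_ok)
  o22 <- cap2$o2_tolerant[[1]]
  expect_identical(o22$verdict[o22$group == "1"], "candidate")

  # no hoxZ/hoxM at all: rejected
  pres3 <- toy_presence(base_status)
  cap3 <- call_capability(pres3, sig_ok)
  o23 <- cap3$o2_tolerant[[1]]
  expect_identical(o23$verdict[o23$group == "1"], "rejected")

  # degenerate signature: rejected even with accessories
  sig_bad <- toy_motif_report("mbh1_small", "degenerate")
  cap4 <- call_capability(pres, sig_bad)
  o24 <- cap4$o2_tolerant[[1]]
  expect_identical(o24$verdict[o24$group == "1"], "rejected")
})

test_that("group 3b candidacy needs all subunits plus complete hyp", {
  subs <- setNames(rep("present", 4), survey_families("o2")[3:6])
  hyp <- setNames(rep("present", 6), survey_families("hyp"))
  sig <- toy_motif_report("sh3b_delta")
  cap <- call_capability(toy_presence(c(subs, hyp)), sig)
  o2 <- cap$o2_tolerant[[1]]
  expect_identical(o2$verdict[o2$group == "3b"], "candidate")

  # hypAB only (the maturation-deficient state): rejected
  cap2 <- call_capability(
    toy_presence(c(subs, hypA = "present", hypB = "present")), sig)
  o22 <- cap2$o2_tolerant[[1]]
  expect_identical(o22$verdict[o22$group == "3b"], "rejected")
  expect_match(o22$reasons[o22$group == "3b"], "hyp")
})

test_that("motif downgrades flip presence to the degenerate state", {
  pres <- toy_presence(c(hoxH = "present", hoxY = "present"))
  reports <- dplyr::bind_rows(toy_motif_report("hoxH", "degenerate"),
                              toy_motif_report("hoxY"))
  down <- apply_motif_downgrade(pres, reports)
  expect_identical(down$status[down$family == "hoxH"],
                   "present_degenerate")
  expect_identical(down$status[down$family == "hoxY"], "present")
})
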