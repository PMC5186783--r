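---
title: "Surveying [NiFe] hydrogenase gene systems with hydroscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying [NiFe] hydrogenase gene systems with hydroscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroscan)
```

## The problem

Cyanobacteria metabolise molecular hydrogen through two [NiFe]
hydrogenases — the bidirectional Hox enzyme (group 3d, encoded by
*hoxEFUYH* plus the endopeptidase *hoxW*) and the uptake Hup enzyme
(group 2a, *hupSL* plus the peptidase *hupW*) — whose active site is
assembled by the six maturation factors HypABCDEF. Whether a sequenced
strain can plausibly make a *functional* enzyme is not decided by a
single BLAST hit: the gene set must be complete, the maturation
machinery must be there, and the catalytic residues must be intact.
`hydroscan` packages that three-criteria logic, together with
gene-neighbourhood (synteny) classification and habitat/morphology
co-occurrence accounting, as a reusable pipeline that runs on any set
of annotated genomes — and, crucially, on synthetic genomes with
planted truth, so every stage is testable without downloading
anything.

A genome is called **hox-functional** when

1. the structural set *hoxE, hoxF, hoxU, hoxY, hoxH* and the
   endopeptidase *hoxW* are all present,
2. the full *hypABCDEF* maturation set is present, and
3. every checked catalytic motif in the present structural subunits is
   conserved.

The hup call is analogous (*hupS*, *hupL*, *hupW*). A strain is called
potentially nitrogen-fixing when *nifH*, *nifDK* and *nifBEN* are
present; *nifUSV* are treated as dispensable. Oxygen-tolerant
candidates are screened separately for groups 1 (membrane-bound, MBH),
3b (tetrameric bifunctional) and 3d, with graded verdicts
(`candidate` / `questionable` / `rejected`) described below.

## Homology detection

### Exact alignment instead of heuristic search

Family detection uses optimal Smith–Waterman local alignment with
affine gaps (BLOSUM62, gap existence 11, extension 1 — a gap of length
$L$ costs $11 + L$). An exact aligner makes every score deterministic
and lets us verify the engine against brute-force enumeration of all
alignments, which the test suite does exhaustively for short peptides
and by seeded sampling up to length 6, and cross-checks against an
independent alignment library on longer random sequences. The
ambiguity residue X scores 0 against everything, so it can neither
create nor rescue a hit. Ties are broken deterministically everywhere:
higher score, then lower e-value, then lexicographically smallest
protein id; in tracebacks, diagonal over gap, then gap-in-target over
gap-in-reference.

Scores are converted to e-values with the Karlin–Altschul form
$E = K m n e^{-\lambda S}$, with $m$ the query length and $n$ the
searched proteome size in residues, using the published ungapped
BLOSUM62 constants ($K = 0.041$, $\lambda = 0.267$). These e-values
are comparable within a run, which is all the thresholding requires.
Per-family thresholds default to `1e-10` for structural subunits and
`1e-6` for accessory and maturation proteins, and every threshold is
overridable per family in the run configuration — the appropriate
values depend on the query panel in use, so they are data, not code.

### Reciprocal-best-hit confirmation

A hit only establishes presence after reciprocal-best-hit (RBH)
confirmation, interpreted strictly: the hit protein's best-scoring
partner in the reference proteome must be the query, *and* the query's
best-scoring partner in the genome must be the hit protein. The
reference proteome deliberately contains more than the search panel:
it also carries *shadow relatives* — paralogous sequences that are not
themselves searched. A paralog in the target genome then maps back to
its true relative rather than to the query family and is rejected,
which is exactly how back-searching against a query's full source
proteome discriminates paralogs in practice.

Copy number is counted at the family level: a protein counts as a copy
of family *F* when its best reference partner belongs to *F*. With a
single query per family, strict reciprocity can confirm only one copy,
so presence requires one strict RBH while copy number counts all
family-mapped hits — a genome with two *hoxW* genes is `present` with
copy number 2, while a family whose only hits map back elsewhere is
`absent` with a logged note.

## Motif verification

Catalytic and oxygen-tolerance residues are checked by anchoring each
motif to a reference protein and transferring the anchor positions
onto the target through a global (Needleman–Wunsch, end-gap-penalised)
alignment. A site is conserved when the mapped residue is in the
allowed set; a site mapped to a gap, or to an X, is never conserved. A
protein's verdict is `conserved` only if every site is. A degenerate
verdict downgrades the family's presence to `present_degenerate` — a
distinct display state that still counts as "present" for the
incomplete/absent distinction but never towards a complete set.

The shipped panel covers the HoxH L1/L2 motifs with their Ni-ligand
cysteines, the HoxY and HoxE/F/U FeS-cluster cysteines, HupL L1/L2,
the HupS FeS cysteines, the group 3b small-subunit 4-cysteine set, and
the MBH proximal-cluster signature of oxygen-tolerant group 1 enzymes:
six cysteines at anchor positions 17, 19, 20, 115, 120 and 149 plus
the proline at 242 (Hyd-1 numbering). The exact residue sets of the
L1/L2 consensus motifs are not canonical published literals, so they
ship as an editable YAML config
(`write_motif_panel()` / `load_motif_panel()`); the defaults accept
exactly the anchor residue at each site. The anchors themselves are
synthetic sequences (see below) — for production use on real genomes,
replace them with the real reference proteins in the same config
layout. The group 3b 4-cysteine set is anchored on the delta subunit;
the source description names only "the small subunit", and delta is
the package's documented choice.

## Cluster arrangements

Two members of a gene system co-cluster when they lie on the same
replicon with at most `max_intervening` (default 3) non-member genes
strictly between them, closed transitively. A gene-count rule was
chosen over a base-pair distance because it is independent of
annotation density; the threshold is exposed as a parameter. Labels
are invariant under coordinate mirroring and input order, which the
suite checks.

* **hox**: G1 (*EFUYH* one same-orientation cluster, *W* elsewhere),
  G2 (all six clustered, same orientation), G3 (*EFUY* clustered, *H*
  and *W* elsewhere), G7 (*FUYHW* clustered, *E* elsewhere). Groups
  4–6 share only the trait that *hoxE*/*hoxF* are co-clustered; their
  exact membership is shipped as a partition-signature lookup
  (`inst/extdata/pattern_lookup.yaml`) with placeholder assignments
  (G4 = `EF+UY+H+W`, G5 = `UYH+EF+W`, G6 = `EF+H+U+W+Y`), explicitly
  flagged as replaceable data.
* **hup**: *hupS*–*hupL* must be co-clustered (otherwise
  `unclassified`); the group label is read from a lookup over two
  axes — *hupW* clustered with *hupSL* vs distal, and interruption of
  *hupS* or *hupL* by the *xisC* recombinase. The default mapping is
  G1 = clustered/none, G2 = distal/none, G3 = clustered/*hupL*,
  G4 = distal/*hupL*, G5 = */hupS*; only the axes are canonical, the
  numbers are config. An interruption is detected when an xisC gene
  lies strictly inside a subunit's span or between two fragments of a
  split subunit.
* **hyp**: class 1 is a single six-gene cluster and class 2 a
  five-plus-one partition; every other layout is labelled by its
  canonical cluster-size signature (`4+2`, `2+2+2`, `1+1+1+1+1+1`,
  ...), which enumerates the remaining classes deterministically.

Partition signatures are canonicalised by sorting blocks by size
(largest first), then alphabetically; members within a block follow
the system's gene order. Signatures not present in a lookup yield
`unclassified` rather than a guess.

## Oxygen-tolerance screening

Group 1 (MBH) candidacy requires the large+small subunit pair, a fully
conserved proximal signature, and at minimum the *hoxZ* and *hoxM*
accessory genes; only a complete accessory set
(*hoxZMLOQ* + *hoxRTV*) elevates the verdict from `questionable` to
`candidate`, encoding the graded conclusion appropriate when a genome
carries the enzyme but lacks most of its dedicated maturation
machinery. Group 3b requires all four subunits plus the complete hyp
set; group 3d follows the hox three-criteria call. Every non-candidate
verdict carries reasons naming the failed requirement.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates
the statistical structure the analysis assumes:

* **True homologs** are copies of the panel queries with at most 2%
  random substitutions. Substitutions avoid motif sites unless a
  mutation is explicitly requested, so the presence and motif axes of
  a test are independent.
* **Paralog decoys** are derived from the shadow relatives of the
  reference proteome at a requested intermediate identity. They
  typically pass the forward e-value threshold — the realistic failure
  mode — and are rejected by the RBH back-search.
* **Background genes** are drawn from a seeded uniform residue model
  at 150–600 aa. Under the default thresholds they never produce a
  confirmed hit; the suite verifies zero RBH-confirmed background
  hits across 100 seeded genomes.
* **Layout** realises a requested arrangement exactly: cluster members
  are adjacent, and separate clusters are divided by five background
  genes — beyond any co-localization threshold up to 4 — so a
  requested label round-trips through the classifier. xisC
  interruptions are planted as a recombinase gene nested inside the
  subunit's span.

Every genome derives from a `plant_spec()` and a per-genome seed, and
its expected presence table, motif verdicts, arrangement labels and
capability calls are computed from the spec alone (`truth_row()`),
never by running the pipeline — the round-trip comparison is therefore
a real test, not a tautology.

What the generator does *not* emulate: real sequence evolution
(indels, domain shuffling, compositional bias), fragmented assemblies,
annotation errors, or genuinely ambiguous paralogy at equal identity.
A perfect score on synthetic cohorts therefore demonstrates the
pipeline's logic is correct under its stated assumptions, not that the
default thresholds are optimal for any particular real dataset —
threshold calibration against curated genomes remains the user's
task, and the config surface exists for exactly that reason.

## Study conditions and problem sizes

The cohort used by the acceptance analysis is a curated 30-genome
design (`survey_cohort_specs()`): all seven hox arrangement groups,
all five hup groups, six hyp partition classes, planted degenerate
motifs by substitution (HoxH Ni-ligand Cys→Ala) and truncation (a
HupS fragment losing a distal FeS cysteine), incomplete hox/hup/hyp
sets, a hoxW-only genome with two copies, the three oxygen-tolerant
groups in candidate / questionable / rejected configurations, and a
nine-genome open-ocean stratum with eight hydrogenase-free genomes
and one uptake-only genome — whose accounting reproduces an 89% / 11%
display split under half-up integer rounding. Percentages are
rounded half-up for display only; exact values are retained in every
table.

The alignment-oracle comparison enumerates all alignments by brute
force. The number of peptide pairs of length ≤ 6 over a four-letter
alphabet is ~30 million, so the suite checks every pair of lengths
≤ 2 exhaustively and stratified seeded samples across all length
combinations up to 6×6 — the enumeration oracle, not the sample size,
is the point of the check. Cohort analyses complete in about a minute
on one CPU; the full test suite in a few minutes.

## Numerical and design choices

* Internal coordinates are 0-based half-open; GFF3 and the TSV dialect
  convert at the boundary (1-based inclusive) and round-trip exactly.
* Amino-acid sequences admit the 20 canonical residues plus X; other
  ambiguity codes are rejected at parse time because the scoring
  matrix is defined over 20+X.
* "Incomplete" means at least one but not all members of a system
  present; a genome with zero members is "absent". The two states are
  kept distinct in every summary (the survey's gene-free vs
  incomplete classes). Whether a published "incomplete" count tallies
  missing maturation genes as well as structural ones is ambiguous;
  this package counts each system separately and surfaces the states
  per system, so either reading can be recovered from the output.
* Unrecognised habitat labels map to `other` with a warning rather
  than erroring: metadata vocabularies drift, and a survey should not
  fall over on a new label. Subsections outside I–V become `unknown`.
* The synthetic query panel is a fixed constant (internal seed), so
  the default pipeline is fully deterministic; user-supplied panels
  replace it wholesale via `read_query_panel()`.

## Known limitations

* With a single query per family, strict RBH plus family-level copy
  counting is a compromise; families with many true in-paralogs would
  need multi-query panels for faithful copy numbers.
* E-values use ungapped Karlin–Altschul constants with gapped
  alignment scores; they are ranking devices within a run, not
  calibrated significance estimates.
* The hox G4–G6 and hup G1–G5 lookups are placeholders pending a
  curated mapping; `unclassified` is the honest default for unknown
  signatures.
* Group 2b and group 5 oxygen-tolerant enzymes are not screened (no
  cyanobacterial homologs are expected); adding probes is a config
  change, not a code change.
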