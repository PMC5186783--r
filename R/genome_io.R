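# Readers and writers for the external formats the survey consumes:
# protein FASTA, gene features (GFF3 or a documented TSV dialect),
# strain metadata TSV and newick species trees. All coordinates are
# normalised at this boundary to 0-based half-open intervals; every
# writer converts back, so printed GFF3 coordinates round-trip exactly.

#' Read a protein FASTA file
#'
#' The first whitespace-delimited token of each header is the protein id.
#' Sequences are uppercased and trailing `*` stop codons stripped; residues
#' must then fall in the 20-letter amino-acid alphabet plus `X`.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome identifier stamped on every record.
#' @return A tibble with columns `protein_id`, `genome_id`, `sequence`.
#' @export
read_fasta <- function(path, genome_id = fs_stem(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("empty FASTA file: ", path))
  if (!startsWith(lines[[1]], ">")) {
    abort(paste0("malformed FASTA (first line lacks '>'): ", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate protein id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for protein: ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad)) {
    abort(paste0("non-standard residues (only 20 canonical + X accepted) in: ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(protein_id = unname(ids), genome_id = genome_id,
         sequence = unname(seqs))
}

fs_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Write protein records as FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", proteins$protein_id, "\n", proteins$sequence), con,
             sep = "\n")
  invisible(path)
}

FEATURE_COLS <- c("gene_id", "genome_id", "replicon_id", "start", "end",
                  "strand", "protein_id")

#' Read gene features from GFF3 or tabular annotation
#'
#' GFF3 input is 1-based inclusive and only CDS rows are consumed; the TSV
#' dialect has header columns `gene_id`, `replicon_id`, `start`, `end`,
#' `strand`, `protein_id` (also 1-based inclusive). Internally all
#' coordinates become 0-based half-open, so a GFF3 row `start=11, end=40`
#' is stored as `(10, 40)`.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param genome_id Genome identifier stamped on every feature.
#' @param link_attribute GFF3 attribute key carrying the protein link
#'   (falls back to `ID` when the key is absent).
#' @return Tibble with columns `gene_id`, `genome_id`, `replicon_id`,
#'   `start`, `end` (0-based half-open), `strand`, `protein_id`
#'   (`NA` for non-coding features in the TSV dialect).
#' @export
read_features <- function(path, dialect = c("gff3", "tsv"),
                          genome_id = fs_stem(path),
                          link_attribute = "protein_id") {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    g <- as.data.frame(rtracklayer::readGFF(path))
    g <- g[g$type == "CDS", , drop = FALSE]
    strand <- as.character(g$strand)
    if (any(!strand %in% c("+", "-"))) {
      abort("GFF3 CDS rows must have strand '+' or '-'")
    }
    link <- if (link_attribute %in% names(g)) {
      as.character(g[[link_attribute]])
    } else {
      rep(NA_character_, nrow(g))
    }
    id <- if ("ID" %in% names(g)) as.character(g$ID) else link
    link <- ifelse(is.na(link), id, link)
    out <- tibble(
      gene_id = ifelse(is.na(id), link, id),
      genome_id = genome_id,
      replicon_id = as.character(g$seqid),
      start = as.integer(g$start) - 1L,
      end = as.integer(g$end),
      strand = strand,
      protein_id = link
    )
  } else {
    d <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    need <- setdiff(setdiff(FEATURE_COLS, "genome_id"), names(d))
    if (length(need)) {
      abort(paste0("feature TSV missing columns: ", paste(need, collapse = ", ")))
    }
    if (any(!d$strand %in% c("+", "-"))) abort("unknown strand symbol in feature TSV")
    out <- tibble(
      gene_id = d$gene_id,
      genome_id = genome_id,
      replicon_id = d$replicon_id,
      start = as.integer(d$start) - 1L,
      end = as.integer(d$end),
      strand = d$strand,
      protein_id = dplyr::na_if(d$protein_id, "")
    )
  }
  if (any(out$end <= out$start)) {
    abort("feature with end <= start after coordinate conversion")
  }
  out
}

#' Write features in the package's TSV dialect (1-based inclusive)
#'
#' @param features Internal feature tibble (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  out <- features |>
    mutate(start = .data$start + 1L,
           protein_id = dplyr::coalesce(.data$protein_id, "")) |>
    select(all_of(setdiff(FEATURE_COLS, "genome_id")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write features as GFF3 (CDS rows, 1-based inclusive)
#'
#' @inheritParams write_features_tsv
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "hydroscan") {
  attrs <- ifelse(
    is.na(features$protein_id),
    paste0("ID=", features$gene_id),
    paste0("ID=", features$gene_id, ";protein_id=", features$protein_id)
  )
  lines <- paste(features$replicon_id, source, "CDS",
                 features$start + 1L, features$end, ".",
                 features$strand, "0", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read strain metadata
#'
#' TSV with header `genome_id`, `habitat`, `subsection`. Habitat strings
#' outside the survey vocabulary (freshwater, open_ocean, coastal,
#' terrestrial, hot_spring, salt_lake, other) are mapped to `other` with a
#' warning; a missing subsection becomes `unknown`.
#'
#' @param path Metadata TSV path.
#' @return Tibble with `genome_id`, `habitat`, `subsection`.
#' @export
read_metadata <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  need <- setdiff(c("genome_id", "habitat"), names(d))
  if (length(need)) {
    abort(paste0("metadata TSV missing columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(d$genome_id)) {
    abort(paste0("duplicate genome_id in metadata: ",
                 paste(unique(d$genome_id[duplicated(d$genome_id)]),
                       collapse = ", ")))
  }
  habitat <- d$habitat
  unknown_hab <- !is.na(habitat) & !habitat %in% HABITATS
  if (any(unknown_hab)) {
    warn(paste0("unrecognised habitat label(s) mapped to 'other': ",
                paste(unique(habitat[unknown_hab]), collapse = ", ")))
    habitat[unknown_hab] <- "other"
  }
  habitat[is.na(habitat)] <- "other"
  subsection <- if ("subsection" %in% names(d)) d$subsection else NA_character_
  subsection[is.na(subsection) | !subsection %in% SUBSECTIONS] <- "unknown"
  tibble(genome_id = d$genome_id, habitat = habitat, subsection = subsection)
}

#' Read a newick species tree
#'
#' Leaf labels are genome ids; internal node labels are ignored.
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) abort(paste0("newick parse error: ",
                                                  conditionMessage(e))))
  if (is.null(tr)) abort(paste0("newick parse error in ", path))
  tr
}

#' Assemble a genome object
#'
#' A genome bundles the proteome, gene features and strain metadata of one
#' analysed strain. Every feature `protein_id` must resolve to a protein
#' record (features without a protein link are allowed).
#'
#' @param genome_id Identifier.
#' @param proteins Tibble from [read_fasta()].
#' @param features Tibble from [read_features()].
#' @param habitat,subsection Strain metadata labels.
#' @return An object of class `genome`.
#' @export
genome <- function(genome_id, proteins, features,
                   habitat = "other", subsection = "unknown") {
  if (!habitat %in% HABITATS) habitat <- "other"
  if (!subsection %in% SUBSECTIONS) subsection <- "unknown"
  if (anyDuplicated(proteins$protein_id)) {
    abort("duplicate protein ids within genome")
  }
  linked <- features$protein_id[!is.na(features$protein_id)]
  missing <- setdiff(linked, proteins$protein_id)
  if (length(missing)) {
    abort(paste0("feature protein link does not resolve: ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(genome_id = genome_id,
         proteins = mutate(proteins, genome_id = genome_id),
         features = mutate(features, genome_id = genome_id),
         metadata = tibble(genome_id = genome_id, habitat = habitat,
                           subsection = subsection)),
    class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$genome_id, ": ", nrow(x$proteins), " proteins, ",
      nrow(x$features), " features, habitat=", x$metadata$habitat,
      ", subsection=", x$metadata$subsection, "\n", sep = "")
  invisible(x)
}

#' Read one genome from a directory
#'
#' Expects `<genome_id>.faa` and `<genome_id>.gff3` (or `.features.tsv`)
#' in `dir`; metadata is looked up in the supplied table.
#'
#' @param dir Directory holding the genome files.
#' @param genome_id Genome identifier / file stem.
#' @param metadata Optional metadata tibble from [read_metadata()].
#' @return A `genome` object.
#' @export
read_genome <- function(dir, genome_id, metadata = NULL) {
  faa <- file.path(dir, paste0(genome_id, ".faa"))
  gff <- file.path(dir, paste0(genome_id, ".gff3"))
  tsv <- file.path(dir, paste0(genome_id, ".features.tsv"))
  proteins <- read_fasta(faa, genome_id = genome_id)
  features <- if (file.exists(gff)) {
    read_features(gff, "gff3", genome_id = genome_id)
  } else {
    read_features(tsv, "tsv", genome_id = genome_id)
  }
  hab <- "other"; sub <- "unknown"
  if (!is.null(metadata)) {
    row <- metadata[metadata$genome_id == genome_id, ]
    if (nrow(row) == 1L) { hab <- row$habitat; sub <- row$subsection }
  }
  genome(genome_id, proteins, features, habitat = hab, subsection = sub)
}

#' Write a genome's files to a directory
#'
#' Emits `<id>.faa` and `<id>.gff3` in the dialects [read_genome()] expects.
#'
#' @param g A `genome` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(g$proteins, file.path(dir, paste0(g$genome_id, ".faa")))
  write_gff3(g$features, file.path(dir, paste0(g$genome_id, ".gff3")))
  invisible(dir)
}
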