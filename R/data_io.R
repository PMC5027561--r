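# Reading, validating and writing barcode data sets.

.META_COLS <- c("specimen_id", "species", "genus", "family", "order",
                "class", "country_or_site")

#' Construct a validated barcode data set
#'
#' Bundles an aligned sequence matrix with its specimen metadata after
#' checking the invariants every downstream analysis relies on: unique
#' specimen ids, one alignment length, non-empty taxonomy from species up to
#' class, a functional taxonomy (each taxon name has exactly one parent), and
#' a legal alphabet (`ACGT`, IUPAC ambiguity codes, `N`, `-`).
#'
#' @param metadata data frame with columns `specimen_id`, `species`, `genus`,
#'   `family`, `order`, `class`, `country_or_site` (in that order).
#' @param sequences character vector of aligned sequences named by
#'   `specimen_id`, or unnamed and in metadata row order.
#' @return An object of class `barcode_dataset`: a list with elements
#'   `metadata`, `sequences` (upper-case, named) and `alignment_length`.
#' @export
barcode_dataset <- function(metadata, sequences) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!identical(names(metadata), .META_COLS))
    .stopf("metadata columns must be exactly: %s",
           paste(.META_COLS, collapse = ", "))
  for (col in .META_COLS)
    metadata[[col]] <- trimws(as.character(metadata[[col]]))
  if (anyDuplicated(metadata$specimen_id))
    .stopf("duplicate specimen_id: %s",
           metadata$specimen_id[duplicated(metadata$specimen_id)][1L])
  for (col in .RANKS) {
    bad <- metadata$specimen_id[!nzchar(metadata[[col]])]
    if (length(bad))
      .stopf("empty '%s' for specimen '%s'", col, bad[1L])
  }
  # functional taxonomy: one parent per taxon name
  for (i in seq_len(length(.RANKS) - 1L)) {
    child <- metadata[[.RANKS[i]]]
    parent <- metadata[[.RANKS[i + 1L]]]
    n_par <- tapply(parent, child, function(p) length(unique(p)))
    if (any(n_par > 1L))
      .stopf("taxon '%s' at rank %s has multiple parents at rank %s",
             names(n_par)[n_par > 1L][1L], .RANKS[i], .RANKS[i + 1L])
  }
  sequences <- toupper(as.character(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- metadata$specimen_id
  } else if (!setequal(names(sequences), metadata$specimen_id)) {
    .stopf("sequence names do not match metadata specimen_id")
  } else {
    sequences <- sequences[metadata$specimen_id]
  }
  if (length(sequences) == 0L) .stopf("empty data set")
  len <- nchar(sequences)
  if (length(unique(len)) != 1L)
    .stopf("unequal sequence lengths: specimen '%s' has %d sites, '%s' has %d",
           names(sequences)[1L], len[1L],
           names(sequences)[len != len[1L]][1L], len[len != len[1L]][1L])
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1L]])
  bad <- setdiff(chars, .IUPAC)
  if (length(bad)) {
    offender <- names(sequences)[grepl(bad[1L], sequences, fixed = TRUE)][1L]
    .stopf("illegal character '%s' in sequence of specimen '%s'",
           bad[1L], offender)
  }
  structure(list(metadata = metadata,
                 sequences = sequences,
                 alignment_length = unname(len[1L])),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("barcode_dataset: %d specimens, %d species, %d sites\n",
              nrow(x$metadata), length(unique(x$metadata$species)),
              x$alignment_length))
  invisible(x)
}

#' Number of specimens per species
#'
#' @param dataset a `barcode_dataset`.
#' @return Named integer vector of specimen counts, one entry per species.
#' @export
species_sizes <- function(dataset) {
  tab <- table(dataset$metadata$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Species label of each specimen
#'
#' @param dataset a `barcode_dataset`.
#' @return Character vector of species names, named by specimen id.
#' @export
species_labels <- function(dataset) {
  stats::setNames(dataset$metadata$species, dataset$metadata$specimen_id)
}

#' Read an aligned FASTA plus a specimen-metadata table
#'
#' The FASTA ids and the metadata `specimen_id` column must be set-equal; the
#' returned data set preserves FASTA order.  The metadata is a UTF-8 TSV with
#' a header row and the fixed column order `specimen_id, species, genus,
#' family, order, class, country_or_site`.
#'
#' @param fasta_path path to the aligned FASTA file ('-' is the only gap
#'   character accepted; '.' is rejected).
#' @param metadata_path path to the metadata TSV.
#' @return A [barcode_dataset()].
#' @export
read_dataset <- function(fasta_path, metadata_path) {
  seqs_bin <- ape::read.FASTA(fasta_path)
  if (anyDuplicated(names(seqs_bin)))
    .stopf("duplicate FASTA id: %s",
           names(seqs_bin)[duplicated(names(seqs_bin))][1L])
  seqs <- vapply(as.character(seqs_bin),
                 function(s) paste(s, collapse = ""), character(1))
  md <- utils::read.delim(metadata_path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(md), .META_COLS))
    .stopf("metadata header must be: %s", paste(.META_COLS, collapse = "\t"))
  missing_md <- setdiff(names(seqs), md$specimen_id)
  if (length(missing_md))
    .stopf("FASTA id '%s' has no metadata row", missing_md[1L])
  missing_fa <- setdiff(md$specimen_id, names(seqs))
  if (length(missing_fa))
    .stopf("metadata specimen '%s' has no sequence", missing_fa[1L])
  md <- md[match(names(seqs), md$specimen_id), , drop = FALSE]
  rownames(md) <- NULL
  barcode_dataset(md, seqs)
}

#' Write a barcode data set back to FASTA + metadata TSV
#'
#' Inverse of [read_dataset()]: sequences and metadata round-trip exactly
#' (modulo FASTA line wrapping and letter case).
#'
#' @param dataset a `barcode_dataset`.
#' @param fasta_path,metadata_path output paths.
#' @return Invisibly, `dataset`.
#' @export
write_dataset <- function(dataset, fasta_path, metadata_path) {
  lines <- character(2L * length(dataset$sequences))
  lines[c(TRUE, FALSE)] <- paste0(">", names(dataset$sequences))
  lines[c(FALSE, TRUE)] <- dataset$sequences
  writeLines(lines, fasta_path)
  utils::write.table(dataset$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dataset)
}

#' GC content of a sequence over unambiguous, ungapped sites
#'
#' @param sequence character vector of DNA strings.
#' @return Numeric vector: (G+C)/(A+C+G+T) per sequence; `NA` when a
#'   sequence has no countable base (all gaps / ambiguities).
#' @examples
#' gc_content(c("GCGC", "ATAT", "ATGC", "AT-GC-N"))
#' @export
gc_content <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    den <- sum(ch %in% c("A", "C", "G", "T"))
    if (den == 0L) return(NA_real_)
    sum(ch %in% c("G", "C")) / den
  }, numeric(1), USE.NAMES = FALSE)
}

#' Chi-square test of homogeneity on a count table
#'
#' Pearson chi-square without continuity correction, expected counts from
#' row/column margins.  Zero-margin rows and columns are dropped first.
#'
#' @param counts numeric matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    return(list(statistic = 0, df = 0L, p_value = 1))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Sequence-composition summary by species
#'
#' Per-species GC content and base counts over unambiguous sites, plus a
#' chi-square test of homogeneity of nucleotide frequencies among species
#' (species x \{A,C,G,T\} table, df = (n_species - 1) x 3).  Species with no
#' countable base are excluded with a warning.
#'
#' @param dataset a `barcode_dataset` with at least two species.
#' @return Object of class `composition_summary`: list with `per_species`
#'   (data frame: species, n_specimens, gc, A, C, G, T), `mean_gc`,
#'   `chi2_statistic`, `chi2_df`, `chi2_p`.
#' @export
composition_summary <- function(dataset) {
  sp <- dataset$metadata$species
  if (length(unique(sp)) < 2L) .stopf("need at least 2 species")
  code <- .encode_sequences(dataset$sequences)
  counts <- t(vapply(split(seq_along(sp), sp), function(rows) {
    sub <- code[rows, , drop = FALSE]
    c(A = sum(sub == 1L), C = sum(sub == 2L),
      G = sum(sub == 3L), T = sum(sub == 4L))
  }, numeric(4)))
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    .warnf("excluding %d species with no countable bases: %s",
           sum(zero), paste(rownames(counts)[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  gc <- (counts[, "G"] + counts[, "C"]) / rowSums(counts)
  chi <- chi2_homogeneity(counts)
  per_species <- data.frame(
    species = rownames(counts),
    n_specimens = as.integer(table(sp)[rownames(counts)]),
    gc = unname(gc),
    counts,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_species = per_species,
                 mean_gc = mean(gc),
                 chi2_statistic = chi$statistic,
                 chi2_df = chi$df,
                 chi2_p = chi$p_value),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf(
    "composition_summary: %d species, mean GC %.2f%%, chi2 = %.2f (df %d, p %.3g)\n",
    nrow(x$per_species), 100 * x$mean_gc,
    x$chi2_statistic, x$chi2_df, x$chi2_p))
  invisible(x)
}

#' Read a specimen-to-BIN assignment table
#'
#' Barcode Index Numbers (BINs) are consumed as opaque external labels; this
#' reads a two-column TSV (`specimen_id`, `bin`).  Rows whose specimen is not
#' in the data set are excluded with a warning (their count is kept in the
#' `n_excluded` attribute); a specimen mapped to two different BINs is an
#' error.  Specimens without any BIN row are allowed: the mapping is partial.
#'
#' @param path path to the TSV.
#' @param dataset a `barcode_dataset` the ids are checked against.
#' @return Data frame with columns `specimen_id`, `bin` and attribute
#'   `n_excluded`.
#' @export
read_bin_assignments <- function(path, dataset) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) != 2L) .stopf("BIN table must have exactly 2 columns")
  names(tab) <- c("specimen_id", "bin")
  tab <- unique(tab)
  dup <- tab$specimen_id[duplicated(tab$specimen_id)]
  if (length(dup))
    .stopf("specimen '%s' is assigned to more than one BIN", dup[1L])
  known <- tab$specimen_id %in% dataset$metadata$specimen_id
  if (any(!known))
    .warnf("excluding %d BIN rows with unknown specimen ids (e.g. '%s')",
           sum(!known), tab$specimen_id[!known][1L])
  out <- tab[known, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!known)
  out
}
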