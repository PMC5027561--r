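# Concordance of externally supplied BIN labels with species labels.

# Lowest-rank conflict label for a set of species drawn together in one
# BIN, computed from the data set's own taxonomy table.  Congeneric species
# conflict at the "species" level; different genera of one family at
# "genus"; and so on.  Classes are the top of the stored taxonomy, so BINs
# mixing classes are ranked "class".
.conflict_rank <- function(md, species_set) {
  if (length(species_set) < 2L) return("none")
  rows <- md[match(species_set, md$species), , drop = FALSE]
  if (length(unique(rows$genus)) == 1L) return("species")
  if (length(unique(rows$family)) == 1L) return("genus")
  if (length(unique(rows$order)) == 1L) return("family")
  if (length(unique(rows$class)) == 1L) return("order")
  "class"
}

#' Classify BIN assignments against species labels
#'
#' Barcode Index Numbers (BINs) are consumed as opaque external cluster
#' labels.  Each BIN is classified as `singleton` (one specimen),
#' `discordant_merged` (two or more species names) or `concordant`; merged
#' BINs carry the lowest taxonomic rank at which their member species
#' conflict.  Each species is flagged as split when it is distributed over
#' two or more BINs.  Specimens without a BIN are excluded with a count.
#'
#' @param dataset a `barcode_dataset`.
#' @param assignments data frame with columns `specimen_id`, `bin` (see
#'   [read_bin_assignments()]); every assigned specimen must exist in the
#'   data set, and no specimen may carry two BINs.
#' @return Object of class `bin_report`: list with
#'   `bin_table` (bin, n_specimens, n_species, species, status,
#'   conflict_rank), `species_table` (species, n_bins, bins, split),
#'   `sharing_table` (the merged-BIN view: one row per discordant BIN with
#'   its species set), `split_table` (one row per BIN of each split
#'   species), `counts` (`n_bins`, `n_concordant`, `n_discordant_merged`,
#'   `n_singleton`, `n_species_split`, `pct_concordant` with denominator =
#'   all BINs, `n_specimens_assigned`, `n_specimens_unassigned`).
#' @export
classify_bins <- function(dataset, assignments) {
  md <- dataset$metadata
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "bin") %in% names(assignments)))
    .stopf("assignments need columns specimen_id, bin")
  unknown <- setdiff(assignments$specimen_id, md$specimen_id)
  if (length(unknown))
    .stopf("assigned specimen '%s' is not in the data set", unknown[1L])
  assignments <- unique(assignments[, c("specimen_id", "bin")])
  dup <- assignments$specimen_id[duplicated(assignments$specimen_id)]
  if (length(dup))
    .stopf("specimen '%s' carries conflicting BIN assignments", dup[1L])
  sp <- stats::setNames(md$species, md$specimen_id)
  fam <- stats::setNames(md$family, md$specimen_id)
  by_bin <- split(assignments$specimen_id, assignments$bin)
  bin_rows <- lapply(names(by_bin), function(b) {
    ids <- by_bin[[b]]
    spp <- sort(unique(sp[ids]))
    status <- if (length(ids) == 1L) "singleton"
              else if (length(spp) >= 2L) "discordant_merged"
              else "concordant"
    data.frame(bin = b, n_specimens = length(ids), n_species = length(spp),
               species = paste(spp, collapse = ","),
               family = paste(sort(unique(fam[ids])), collapse = ","),
               status = status,
               conflict_rank = if (status == "discordant_merged")
                 .conflict_rank(md, spp) else "none",
               stringsAsFactors = FALSE)
  })
  bin_table <- do.call(rbind, bin_rows)
  assigned_sp <- sort(unique(sp[assignments$specimen_id]))
  sp_rows <- lapply(assigned_sp, function(s) {
    bins <- sort(unique(assignments$bin[sp[assignments$specimen_id] == s]))
    data.frame(species = s, n_bins = length(bins),
               bins = paste(bins, collapse = ","),
               split = length(bins) >= 2L, stringsAsFactors = FALSE)
  })
  species_table <- do.call(rbind, sp_rows)
  sharing_table <- bin_table[bin_table$status == "discordant_merged",
                             c("family", "species", "bin", "conflict_rank"),
                             drop = FALSE]
  rownames(sharing_table) <- NULL
  split_sp <- species_table$species[species_table$split]
  split_table <- do.call(rbind, lapply(split_sp, function(s) {
    bins <- strsplit(species_table$bins[species_table$species == s],
                     ",", fixed = TRUE)[[1L]]
    data.frame(family = fam[md$specimen_id[match(s, md$species)]],
               species = s, bin = bins, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  if (is.null(split_table))
    split_table <- data.frame(family = character(), species = character(),
                              bin = character())
  counts <- list(
    n_bins = nrow(bin_table),
    n_concordant = sum(bin_table$status == "concordant"),
    n_discordant_merged = sum(bin_table$status == "discordant_merged"),
    n_singleton = sum(bin_table$status == "singleton"),
    n_species_split = length(split_sp),
    pct_concordant = .pct(sum(bin_table$status == "concordant") /
                            nrow(bin_table), 1),
    n_specimens_assigned = nrow(assignments),
    n_specimens_unassigned = nrow(md) - nrow(assignments))
  structure(list(bin_table = bin_table, species_table = species_table,
                 sharing_table = sharing_table, split_table = split_table,
                 counts = counts),
            class = "bin_report")
}

#' @export
print.bin_report <- function(x, ...) {
  cat(sprintf(
    "bin_report: %d BINs -- %d concordant (%.1f%%), %d merged, %d singleton; %d species split; %d specimens unassigned\n",
    x$counts$n_bins, x$counts$n_concordant, x$counts$pct_concordant,
    x$counts$n_discordant_merged, x$counts$n_singleton,
    x$counts$n_species_split, x$counts$n_specimens_unassigned))
  invisible(x)
}
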