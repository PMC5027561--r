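# Barcode-gap analysis: maximum intraspecific divergence vs the
# nearest-neighbour (NN) distance, per species.

.check_species <- function(dataset, species) {
  if (!species %in% dataset$metadata$species)
    .stopf("unknown species '%s'", species)
}

#' Maximum intraspecific K2P divergence of a species
#'
#' Maximum over the defined conspecific pair distances; `NA` for singletons
#' (no conspecific pair exists) or when every conspecific pair is undefined.
#'
#' @param matrix a `k2p_matrix`.
#' @param dataset the matching `barcode_dataset`.
#' @param species species name.
#' @return A distance (proportion) or `NA`.
#' @export
max_intraspecific <- function(matrix, dataset, species) {
  .check_species(dataset, species)
  rows <- which(dataset$metadata$species == species)
  if (length(rows) < 2L) return(NA_real_)
  d <- matrix$distance[rows, rows]
  d <- d[upper.tri(d)]
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  max(d)
}

#' Nearest-neighbour species and distance
#'
#' The minimum defined distance from any specimen of `species` to any
#' heterospecific specimen.  Exact distance ties between candidate
#' neighbour species are broken by lexicographically smaller species name;
#' all tied species are reported in the `ties` element.
#'
#' @inheritParams max_intraspecific
#' @return List with `nn_species`, `nn_distance`, `ties` (character vector
#'   of all species attaining the minimum).
#' @export
nearest_neighbor <- function(matrix, dataset, species) {
  .check_species(dataset, species)
  sp <- dataset$metadata$species
  rows <- which(sp == species)
  others <- which(sp != species)
  if (!length(others)) .stopf("data set has a single species")
  d <- matrix$distance[rows, others, drop = FALSE]
  per_spec <- tapply(as.vector(t(d)), rep(sp[others], length(rows)),
                     function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  per_spec <- per_spec[!is.na(per_spec)]
  if (!length(per_spec))
    .stopf("all heterospecific distances from '%s' are undefined", species)
  m <- min(per_spec)
  ties <- sort(names(per_spec)[per_spec == m])
  list(nn_species = ties[1L], nn_distance = unname(m), ties = ties)
}

#' Barcode-gap report over all species
#'
#' One record per multi-specimen species comparing its maximum intraspecific
#' divergence with the distance to its nearest neighbour.  A species has a
#' barcode gap when `nn_distance > max_intra`; ties count as overlap (a tied
#' distance defeats identification).  Singleton species are listed
#' separately and excluded from overlap counting, but their sequences remain
#' available as potential neighbours.
#'
#' @inheritParams max_intraspecific
#' @param low_nn_threshold the "low NN" cutoff as a proportion (default 0.02).
#' @return Object of class `gap_report`: list with `species_table` (species,
#'   n_specimens, max_intra, nn_species, nn_distance, has_gap, low_nn_flag),
#'   `singletons` (species, nn_species, nn_distance) and `counts`
#'   (`n_assessed`, `n_overlap`, `n_zero_nn` = overlapping species whose NN
#'   distance is zero, `n_low_nn` = species with NN distance <= the cutoff
#'   that still show a gap).
#' @export
gap_report <- function(matrix, dataset, low_nn_threshold = 0.02) {
  sizes <- species_sizes(dataset)
  all_sp <- sort(names(sizes))
  multi <- all_sp[sizes[all_sp] >= 2L]
  singles <- setdiff(all_sp, multi)
  rec <- lapply(multi, function(s) {
    mi <- max_intraspecific(matrix, dataset, s)
    nn <- nearest_neighbor(matrix, dataset, s)
    data.frame(species = s,
               n_specimens = unname(sizes[s]),
               max_intra = mi,
               nn_species = nn$nn_species,
               nn_distance = nn$nn_distance,
               has_gap = if (is.na(mi)) NA else nn$nn_distance > mi,
               low_nn_flag = nn$nn_distance <= low_nn_threshold,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rec)
  if (is.null(tab))
    tab <- data.frame(species = character(), n_specimens = integer(),
                      max_intra = numeric(), nn_species = character(),
                      nn_distance = numeric(), has_gap = logical(),
                      low_nn_flag = logical())
  singleton_tab <- do.call(rbind, lapply(singles, function(s) {
    nn <- nearest_neighbor(matrix, dataset, s)
    data.frame(species = s, nn_species = nn$nn_species,
               nn_distance = nn$nn_distance, stringsAsFactors = FALSE)
  }))
  assessed <- tab[!is.na(tab$has_gap), , drop = FALSE]
  counts <- list(
    n_assessed = nrow(assessed),
    n_overlap = sum(!assessed$has_gap),
    n_zero_nn = sum(!assessed$has_gap & assessed$nn_distance == 0),
    n_low_nn = sum(assessed$has_gap & assessed$low_nn_flag))
  structure(list(species_table = tab, singletons = singleton_tab,
                 counts = counts),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf(
    "gap_report: %d species assessed, %d overlap (%d with zero NN), %d low-NN with gap\n",
    x$counts$n_assessed, x$counts$n_overlap, x$counts$n_zero_nn,
    x$counts$n_low_nn))
  invisible(x)
}

#' Write the barcode-gap report as TSV
#'
#' Distances are rendered in percent with 2 decimals.
#'
#' @param report a `gap_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gap_report <- function(report, path) {
  tab <- report$species_table
  tab$max_intra <- .pct(tab$max_intra)
  tab$nn_distance <- .pct(tab$nn_distance)
  names(tab)[names(tab) == "max_intra"] <- "max_intra_pct"
  names(tab)[names(tab) == "nn_distance"] <- "nn_distance_pct"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
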