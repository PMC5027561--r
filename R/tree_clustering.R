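# Neighbour-joining trees, species-cluster assessment, haplotype collapsing
# and deep-lineage (cryptic diversity) detection.

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]).  Undefined distance
#' entries are not allowed by the algorithm: by default specimens are
#' iteratively dropped (greatest number of undefined entries first) until
#' the matrix is complete, and the dropped ids are reported in a message
#' and in the `"dropped"` attribute.  Negative branch-length estimates are
#' clamped to zero; the number clamped is kept in the `"n_clamped"`
#' attribute.
#'
#' @param matrix a `k2p_matrix` or a symmetric numeric matrix with
#'   dimnames.
#' @param drop_undefined drop specimens involved in undefined entries
#'   (default); when `FALSE`, undefined entries raise an error naming the
#'   offending pairs.
#' @return An unrooted `phylo` tree whose tips are the (remaining)
#'   specimen ids.
#' @export
neighbor_joining <- function(matrix, drop_undefined = TRUE) {
  d <- if (inherits(matrix, "k2p_matrix")) matrix$distance else as.matrix(matrix)
  dropped <- character()
  if (anyNA(d)) {
    if (!drop_undefined) {
      idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
      pairs <- paste(rownames(d)[idx[, 1L]], colnames(d)[idx[, 2L]],
                     sep = "--")
      .stopf("undefined distance entries: %s",
             paste(utils::head(pairs, 5L), collapse = ", "))
    }
    while (anyNA(d)) {
      worst <- which.max(rowSums(is.na(d)))
      dropped <- c(dropped, rownames(d)[worst])
      d <- d[-worst, -worst, drop = FALSE]
    }
    message(sprintf("neighbor_joining: dropped %d specimens with undefined distances: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (nrow(d) < 3L) .stopf("need at least 3 leaves after dropping")
  tree <- ape::nj(d)
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "dropped") <- dropped
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and scores each internal edge of the original tree by the
#' percentage of replicates containing the same bipartition.  Replicates
#' whose resampled matrix contains undefined entries are skipped (their
#' count is reported in the `"n_skipped"` attribute, and the support
#' denominator is the number of usable replicates).  Deterministic for a
#' fixed seed.
#'
#' @param dataset a `barcode_dataset` (alignment length >= 10).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the column resampler.
#' @return The NJ tree of the full data with `node.label` set to percent
#'   support (`NA` at the root).
#' @export
bootstrap_support <- function(dataset, n_reps = 100, seed = 1) {
  if (n_reps < 1L) .stopf("n_reps must be >= 1")
  if (dataset$alignment_length < 10L) .stopf("alignment too short")
  code <- .encode_sequences(dataset$sequences)
  base <- .k2p_core(code)$d
  if (anyNA(base)) .stopf("undefined distances in the full matrix; drop first")
  tree <- ape::nj(base)
  tree$edge.length[tree$edge.length < 0] <- 0
  L <- ncol(code)
  set.seed(seed)
  rep_trees <- list()
  n_skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    db <- .k2p_core(code[, cols, drop = FALSE])$d
    if (anyNA(db)) {
      n_skipped <- n_skipped + 1L
      next
    }
    tb <- ape::nj(db)
    tb$edge.length[tb$edge.length < 0] <- 0
    rep_trees[[length(rep_trees) + 1L]] <- tb
  }
  if (!length(rep_trees)) .stopf("no usable bootstrap replicate")
  class(rep_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- round(100 * counts / length(rep_trees), 1)
  attr(tree, "n_skipped") <- n_skipped
  attr(tree, "n_replicates_used") <- length(rep_trees)
  tree
}

#' Species-cluster assessment on a labelled tree
#'
#' Roots the tree at its midpoint (for clade enumeration only) and, for
#' each multi-specimen species, inspects the minimal clade containing all
#' its tips:
#' * only conspecific tips -- `distinct_cluster`;
#' * extra tips, but every foreign species in the clade mutually contains
#'   this species in its own minimal clade (one mixed clade of mutually
#'   overlapping species) -- `shared_cluster`;
#' * extra tips otherwise (the species' own tips form two or more separate
#'   blocks around other species) -- `paraphyletic`.
#'
#' Singletons are reported separately (`singleton_unassessable`).  Species
#' pairs known to share identical haplotypes can be supplied to force the
#' `shared_cluster` status (sharing takes precedence over paraphyly even
#' when the species are additionally interleaved).
#'
#' @param tree a `phylo` whose tips are specimen ids.
#' @param species named species labels covering every tip.
#' @param shared_haplotype_pairs optional 2-column character matrix of
#'   species pairs that share a haplotype.
#' @return Object of class `cluster_assessment`: list with `status` (named
#'   character vector over species), `counts` (named integer vector over
#'   the four statuses), `shared_groups` (list of species sets forming
#'   mixed clusters), `n_species`.
#' @export
assess_species_clusters <- function(tree, species,
                                    shared_haplotype_pairs = NULL) {
  if (!all(tree$tip.label %in% names(species)))
    .stopf("unlabelled leaf: %s",
           setdiff(tree$tip.label, names(species))[1L])
  rooted <- phangorn::midpoint(tree)
  tip_sp <- species[rooted$tip.label]
  all_sp <- sort(unique(tip_sp))
  sizes <- table(tip_sp)
  multi <- all_sp[sizes[all_sp] >= 2L]
  # minimal-clade species content per multi-specimen species
  clade_sp <- list()
  for (s in multi) {
    tips <- which(tip_sp == s)
    node <- ape::getMRCA(rooted, tips)
    in_clade <- phangorn::Descendants(rooted, node, type = "tips")[[1L]]
    clade_sp[[s]] <- unique(tip_sp[in_clade])
  }
  forced <- matrix(character(), ncol = 2L)
  if (!is.null(shared_haplotype_pairs) && length(shared_haplotype_pairs))
    forced <- matrix(as.character(shared_haplotype_pairs), ncol = 2L)
  is_forced <- function(s) any(forced[, 1L] == s | forced[, 2L] == s)
  status <- stats::setNames(rep("singleton_unassessable", length(all_sp)),
                            all_sp)
  for (s in multi) {
    extras <- setdiff(clade_sp[[s]], s)
    if (!length(extras)) {
      status[[s]] <- if (is_forced(s)) "shared_cluster" else "distinct_cluster"
      next
    }
    mutual <- vapply(extras, function(b)
      b %in% multi && s %in% clade_sp[[b]], logical(1))
    status[[s]] <- if (all(mutual) || is_forced(s)) "shared_cluster"
                   else "paraphyletic"
  }
  # group species of shared clusters into mixed-cluster components
  shared <- names(status)[status == "shared_cluster"]
  edges <- matrix(character(), ncol = 2L)
  for (s in intersect(shared, multi))
    for (b in intersect(setdiff(clade_sp[[s]], s), shared))
      edges <- rbind(edges, c(s, b))
  if (nrow(forced)) edges <- rbind(edges, forced)
  edges <- edges[edges[, 1L] %in% shared & edges[, 2L] %in% shared, ,
                 drop = FALSE]
  groups <- if (length(shared)) .components(shared, edges) else list()
  groups <- unname(groups[order(vapply(groups, min, character(1)))])
  counts <- vapply(c("distinct_cluster", "paraphyletic", "shared_cluster",
                     "singleton_unassessable"),
                   function(k) sum(status == k), integer(1))
  structure(list(status = status, counts = counts,
                 shared_groups = groups, n_species = length(all_sp)),
            class = "cluster_assessment")
}

#' @export
print.cluster_assessment <- function(x, ...) {
  cat(sprintf(
    "cluster_assessment: %d species -- %d distinct, %d paraphyletic, %d shared, %d singletons\n",
    x$n_species, x$counts[["distinct_cluster"]], x$counts[["paraphyletic"]],
    x$counts[["shared_cluster"]], x$counts[["singleton_unassessable"]]))
  invisible(x)
}

#' Collapse identical sequences into haplotypes
#'
#' Exact-identity collapsing after removing columns that are gaps in every
#' specimen.  Ambiguity codes must match exactly (a sequence differing only
#' at an `N` site is a distinct haplotype).  A haplotype carried by two or
#' more species is flagged as shared.
#'
#' @param dataset a `barcode_dataset`.
#' @return Object of class `haplotype_table`: data frame with columns
#'   `haplotype`, `n_specimens`, `specimen_ids` (comma-joined), `species`
#'   (comma-joined set), `n_species`, `shared`; the representative
#'   sequences are kept in the `"representatives"` attribute.
#' @export
collapse_haplotypes <- function(dataset) {
  seqs <- dataset$sequences
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- colSums(chars != "-") > 0
  stripped <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(stripped) <- names(seqs)
  sp <- species_labels(dataset)
  groups <- split(names(stripped), factor(stripped, levels = unique(stripped)))
  tab <- do.call(rbind, lapply(seq_along(groups), function(k) {
    ids <- groups[[k]]
    spp <- sort(unique(sp[ids]))
    data.frame(haplotype = sprintf("H%04d", k),
               n_specimens = length(ids),
               specimen_ids = paste(ids, collapse = ","),
               species = paste(spp, collapse = ","),
               n_species = length(spp),
               shared = length(spp) >= 2L,
               stringsAsFactors = FALSE)
  }))
  attr(tab, "representatives") <- stats::setNames(names(groups), tab$haplotype)
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

#' Species pairs sharing a haplotype
#'
#' @param haplotypes a `haplotype_table`.
#' @return Two-column character matrix of species pairs (possibly 0 rows).
#' @export
shared_haplotype_pairs <- function(haplotypes) {
  out <- matrix(character(), ncol = 2L,
                dimnames = list(NULL, c("species_a", "species_b")))
  for (k in which(haplotypes$shared)) {
    spp <- strsplit(haplotypes$species[k], ",", fixed = TRUE)[[1L]]
    cmb <- utils::combn(sort(spp), 2L)
    out <- rbind(out, t(cmb))
  }
  unique(out)
}

#' Deeply divergent intraspecific lineages
#'
#' Average-linkage agglomerative clustering of one species' specimens on
#' K2P distances: clusters are merged while the smallest between-cluster
#' mean divergence is `<= cutoff`, so that in the final partition every
#' between-cluster mean divergence exceeds the cutoff and no further merge
#' is possible without violating it.  With the default 2% cutoff, a species
#' with two or more lineages is a candidate cryptic complex.
#'
#' @param matrix a `k2p_matrix`.
#' @param dataset the matching `barcode_dataset`.
#' @param species species name with >= 2 specimens.
#' @param cutoff mean-divergence cutoff as a proportion (default 0.02,
#'   strict: a between-cluster mean of exactly the cutoff is still merged).
#' @return Object of class `lineage_partition`: list with `species`,
#'   `clusters` (list of specimen-id vectors), `n_lineages`,
#'   `between_means` (matrix of pairwise mean divergences between final
#'   clusters), `cutoff`.
#' @export
deep_lineages <- function(matrix, dataset, species, cutoff = 0.02) {
  .check_species(dataset, species)
  ids <- dataset$metadata$specimen_id[dataset$metadata$species == species]
  if (length(ids) < 2L) .stopf("species '%s' is a singleton", species)
  d <- matrix$distance[ids, ids, drop = FALSE]
  clusters <- as.list(ids)
  mean_between <- function(a, b) {
    v <- d[a, b]
    v <- v[!is.na(v)]
    if (!length(v)) Inf else mean(v)
  }
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA_integer_, NA_integer_)
    best_m <- Inf
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      m <- mean_between(clusters[[i]], clusters[[j]])
      if (m < best_m) {
        best_m <- m
        best <- c(i, j)
      }
    }
    if (best_m > cutoff) break
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  k <- length(clusters)
  bm <- matrix(NA_real_, k, k)
  if (k > 1L)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
      bm[i, j] <- bm[j, i] <- mean_between(clusters[[i]], clusters[[j]])
  structure(list(species = species, clusters = clusters, n_lineages = k,
                 between_means = bm, cutoff = cutoff),
            class = "lineage_partition")
}

#' @export
print.lineage_partition <- function(x, ...) {
  cat(sprintf("lineage_partition: '%s', %d lineage(s) at cutoff %g\n",
              x$species, x$n_lineages, x$cutoff))
  invisible(x)
}

#' Family-level candidate-species summary
#'
#' Aggregates lineage partitions over families: species barcoded, species
#' indistinguishable by barcodes (shared clusters), species with two or
#' more deep lineages, and the total candidate lineages those deep species
#' represent.
#'
#' @param partitions list of `lineage_partition` objects (one per
#'   multi-specimen species).
#' @param dataset the `barcode_dataset`.
#' @param indistinguishable character vector of species classified as
#'   shared clusters (see [assess_species_clusters()]).
#' @return Object of class `family_summary`: data frame with columns
#'   `family`, `species_barcoded`, `species_indistinguishable`,
#'   `deep_species`, `candidate_lineages`, ordered by decreasing
#'   `species_barcoded`; totals and the percent increase in species
#'   diversity are attached via [family_summary_totals()] as attribute
#'   `"totals"`.
#' @export
candidate_species_summary <- function(partitions, dataset,
                                      indistinguishable = character()) {
  md <- dataset$metadata
  sp_fam <- tapply(md$family, md$species, function(f) f[1L])
  n_lin <- vapply(partitions, function(p) p$n_lineages, integer(1))
  names(n_lin) <- vapply(partitions, function(p) p$species, character(1))
  fams <- sort(unique(md$family))
  rows <- lapply(fams, function(f) {
    spp <- names(sp_fam)[sp_fam == f]
    deep <- names(n_lin)[names(n_lin) %in% spp & n_lin >= 2L]
    data.frame(family = f,
               species_barcoded = length(spp),
               species_indistinguishable = sum(indistinguishable %in% spp),
               deep_species = length(deep),
               candidate_lineages = sum(n_lin[deep]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$species_barcoded, tab$family), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "totals") <- family_summary_totals(tab)
  class(tab) <- c("family_summary", "data.frame")
  tab
}

#' Totals and diversity increase of a family summary table
#'
#' Column sums plus the percent increase in species diversity implied by
#' the candidate lineages: `100 * (total lineages - deep species) / total
#' species`, rounded to an integer.
#'
#' @param tab data frame with columns `species_barcoded`,
#'   `species_indistinguishable`, `deep_species`, `candidate_lineages`.
#' @return List with `species_total`, `indistinguishable_total`,
#'   `deep_species_total`, `candidate_lineages_total`, `percent_increase`.
#' @export
family_summary_totals <- function(tab) {
  st <- sum(tab$species_barcoded)
  dt <- sum(tab$deep_species)
  lt <- sum(tab$candidate_lineages)
  list(species_total = st,
       indistinguishable_total = sum(tab$species_indistinguishable),
       deep_species_total = dt,
       candidate_lineages_total = lt,
       percent_increase = round(100 * (lt - dt) / st))
}
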