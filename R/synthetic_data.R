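# Seeded simulator of aligned COI-like data sets with controlled distance
# structure and planted features (singletons, shared haplotypes, deep
# lineages, geography), plus a machine-readable truth table.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the distance structure of a large coastal mollusc COI
#' library at desk scale: conspecific divergence around 1%, congeneric
#' around 19%, confamilial around 22%, ordinal around 25%, class-level
#' around 31%; about a third of species as singletons with a mean of 4.9
#' specimens per species; and AT-rich base composition.  Sequences evolve
#' under the two-parameter (Kimura) substitution process with
#' transition:transversion rate ratio `kappa`, the same model the distance
#' estimator assumes.
#'
#' @param seed integer seed; all randomness in [generate_dataset()] flows
#'   from it.
#' @param alignment_length number of sites (default 600).
#' @param n_classes,n_orders,n_families taxonomy breadth; families are
#'   assigned round-robin to orders, orders to classes.
#' @param genera_per_family,species_per_genus taxonomy shape.
#' @param specimens_per_species optional integer vector (recycled across
#'   species) overriding the sample-size distribution.
#' @param singleton_fraction probability a species is a singleton (default
#'   0.32).
#' @param mean_specimens target mean specimens per species (default 4.9);
#'   non-singleton sizes are `2 + Poisson` with the matching rate.
#' @param kappa transition:transversion rate ratio (> 0, default 3).
#' @param target_intra expected conspecific K2P distance (default 0.01).
#' @param target_congeneric expected congeneric distance (default 0.1867).
#' @param target_confamilial,target_ordinal,target_class,target_between_class
#'   expected distances at the higher levels.
#' @param base_freqs root base frequencies (A, C, G, T).
#' @param planted_shared_pairs number of congeneric species pairs given one
#'   literally copied haplotype.
#' @param planted_deep_species list of `c(n_lineages, divergence)` pairs;
#'   each plants one species whose specimens split into `n_lineages`
#'   lineages separated by about `divergence` (> 0.02), each lineage in a
#'   different geographic location.
#' @param geography_labels locality labels.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         alignment_length = 600,
                         n_classes = 2,
                         n_orders = 3,
                         n_families = 6,
                         genera_per_family = 5,
                         species_per_genus = 4,
                         specimens_per_species = NULL,
                         singleton_fraction = 0.32,
                         mean_specimens = 4.9,
                         kappa = 3,
                         target_intra = 0.01,
                         target_congeneric = 0.1867,
                         target_confamilial = 0.2247,
                         target_ordinal = 0.253,
                         target_class = 0.306,
                         target_between_class = 0.35,
                         base_freqs = c(A = 0.2297, C = 0.1666,
                                        G = 0.2096, T = 0.3941),
                         planted_shared_pairs = 2,
                         planted_deep_species = list(c(2, 0.08), c(3, 0.05)),
                         geography_labels = c("China", "Japan", "Korea",
                                              "Russia")) {
  stopifnot(kappa > 0, alignment_length >= 1,
            target_intra < target_congeneric,
            target_congeneric < target_confamilial,
            target_confamilial < target_ordinal,
            target_ordinal < target_class,
            target_class < target_between_class,
            singleton_fraction >= 0, singleton_fraction < 1)
  for (dl in planted_deep_species)
    if (length(dl) != 2L || dl[1L] < 2L || dl[2L] <= 0.02)
      .stopf("planted deep species need n_lineages >= 2 and divergence > 0.02")
  structure(as.list(environment()), class = "synth_config")
}

# K80 transition-probability draw: mutate a coded base vector along a
# branch of `t` expected substitutions per site.
.evolve_code <- function(code, t, kappa) {
  if (t == 0) return(code)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e4 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  probs <- c(0.25 + 0.25 * e4 + 0.5 * e2,   # identical
             0.25 + 0.25 * e4 - 0.5 * e2,   # transition
             0.25 - 0.25 * e4,              # first transversion target
             0.25 - 0.25 * e4)              # second transversion target
  event <- sample.int(4L, length(code), replace = TRUE, prob = probs)
  # codes: A=1, C=2, G=3, T=4; transition partner and the two transversion
  # targets per base:
  ts_map <- c(3L, 4L, 1L, 2L)
  tv1_map <- c(2L, 1L, 2L, 1L)
  tv2_map <- c(4L, 3L, 4L, 3L)
  out <- code
  out[event == 2L] <- ts_map[code[event == 2L]]
  out[event == 3L] <- tv1_map[code[event == 3L]]
  out[event == 4L] <- tv2_map[code[event == 4L]]
  out
}

.code_to_string <- function(code) paste(c("A", "C", "G", "T")[code],
                                        collapse = "")

#' Evolve a sequence under the two-parameter substitution process
#'
#' Per-site substitution with transition:transversion rate ratio `kappa`
#' along a branch of `branch_length` expected substitutions per site; the
#' expected K2P distance to the ancestor equals the branch length.  Uses
#' the current RNG state: call `set.seed()` first for determinism.
#'
#' @param ancestor DNA string over `ACGT`.
#' @param branch_length expected substitutions per site (>= 0).
#' @param kappa transition:transversion rate ratio (> 0).
#' @return The evolved DNA string.
#' @export
evolve_sequence <- function(ancestor, branch_length, kappa = 3) {
  stopifnot(branch_length >= 0, kappa > 0)
  code <- .encode_sequences(c(x = ancestor))[1L, ]
  if (any(code == 0L)) .stopf("ancestor must contain only A, C, G, T")
  .code_to_string(.evolve_code(code, branch_length, kappa))
}

#' Generate a synthetic barcode data set with planted features
#'
#' Simulates sequences down a star taxonomy: class, order, family, genus
#' and species ancestors at depths set by the target divergences, then
#' specimens coalescing within species at depth `target_intra / 2`.
#' Planted deep species get lineage ancestors at half the requested
#' divergence, one geographic label per lineage; planted shared pairs copy
#' one haplotype verbatim between two congeneric species (both forced
#' non-singleton).  Everything is driven by `config$seed`.
#'
#' @param config a [synth_config()].
#' @return List with `dataset` (a `barcode_dataset`), `truth` (list with
#'   per-`specimens` and per-`species` data frames) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  n_genera <- cf$n_families * cf$genera_per_family
  n_species <- n_genera * cf$species_per_genus
  n_deep <- length(cf$planted_deep_species)
  if (cf$planted_shared_pairs > 0 && cf$species_per_genus < 2L)
    .stopf("shared pairs need genera with at least 2 species")
  if (n_deep + cf$planted_shared_pairs > n_genera)
    .stopf("not enough genera for the requested planted features")
  # branch lengths from the nested target divergences
  bi <- cf$target_intra / 2
  bs <- cf$target_congeneric / 2 - bi
  bg <- cf$target_confamilial / 2 - bs - bi
  bf <- cf$target_ordinal / 2 - bg - bs - bi
  bo <- cf$target_class / 2 - bf - bg - bs - bi
  bc <- cf$target_between_class / 2 - bo - bf - bg - bs - bi
  if (any(c(bi, bs, bg, bf, bo, bc) < 0))
    .stopf("target divergences are not nested increasing")
  L <- cf$alignment_length
  root <- sample.int(4L, L, replace = TRUE, prob = cf$base_freqs)
  class_names <- sprintf("Classis%02d", seq_len(cf$n_classes))
  order_names <- sprintf("Ordo%02d", seq_len(cf$n_orders))
  family_names <- sprintf("Familia%02d", seq_len(cf$n_families))
  order_of_family <- rep_len(seq_len(cf$n_orders), cf$n_families)
  class_of_order <- rep_len(seq_len(cf$n_classes), cf$n_orders)
  class_anc <- lapply(seq_len(cf$n_classes),
                      function(i) .evolve_code(root, bc, cf$kappa))
  order_anc <- lapply(seq_len(cf$n_orders), function(i)
    .evolve_code(class_anc[[class_of_order[i]]], bo, cf$kappa))
  family_anc <- lapply(seq_len(cf$n_families), function(i)
    .evolve_code(order_anc[[order_of_family[i]]], bf, cf$kappa))
  # species bookkeeping: genus g holds species (g-1)*S+1 .. g*S
  deep_species_idx <- if (n_deep)
    (seq_len(n_deep) - 1L) * cf$species_per_genus + 1L else integer()
  shared_genera <- if (cf$planted_shared_pairs > 0)
    seq(n_genera, by = -1L, length.out = cf$planted_shared_pairs)
  else integer()
  # sample sizes
  if (!is.null(cf$specimens_per_species)) {
    n_i <- rep_len(as.integer(cf$specimens_per_species), n_species)
  } else {
    lambda <- max(0, (cf$mean_specimens - cf$singleton_fraction) /
                       (1 - cf$singleton_fraction) - 2)
    n_i <- ifelse(stats::runif(n_species) < cf$singleton_fraction, 1L,
                  2L + stats::rpois(n_species, lambda))
  }
  meta <- list()
  seqs <- list()
  truth_rows <- list()
  sp_rows <- list()
  spec_counter <- 0L
  sp_idx <- 0L
  for (g in seq_len(n_genera)) {
    fam_i <- (g - 1L) %/% cf$genera_per_family + 1L
    genus_name <- sprintf("Genus%03d", g)
    genus_code <- .evolve_code(family_anc[[fam_i]], bg, cf$kappa)
    for (s in seq_len(cf$species_per_genus)) {
      sp_idx <- sp_idx + 1L
      sp_name <- sprintf("%s sp%02d", genus_name, s)
      deep_k <- match(sp_idx, deep_species_idx)
      n_lineages <- 1L
      divergence <- NA_real_
      n_here <- n_i[sp_idx]
      if (!is.na(deep_k)) {
        n_lineages <- as.integer(cf$planted_deep_species[[deep_k]][1L])
        divergence <- cf$planted_deep_species[[deep_k]][2L]
        n_here <- max(n_here, 2L * n_lineages)
      }
      if (g %in% shared_genera && s <= 2L) n_here <- max(n_here, 2L)
      sp_code <- .evolve_code(genus_code, bs, cf$kappa)
      lin_anc <- if (n_lineages > 1L)
        lapply(seq_len(n_lineages),
               function(i) .evolve_code(sp_code, divergence / 2, cf$kappa))
      else list(sp_code)
      lineage_of <- rep_len(seq_len(n_lineages), n_here)
      geo_of <- if (n_lineages > 1L)
        rep_len(cf$geography_labels, n_lineages)[lineage_of]
      else sample(cf$geography_labels, n_here, replace = TRUE)
      for (k in seq_len(n_here)) {
        spec_counter <- spec_counter + 1L
        id <- sprintf("S%04d", spec_counter)
        seqs[[id]] <- .evolve_code(lin_anc[[lineage_of[k]]], bi, cf$kappa)
        meta[[id]] <- data.frame(
          specimen_id = id, species = sp_name, genus = genus_name,
          family = family_names[fam_i],
          order = order_names[order_of_family[fam_i]],
          class = class_names[class_of_order[order_of_family[fam_i]]],
          country_or_site = geo_of[k], stringsAsFactors = FALSE)
        truth_rows[[id]] <- data.frame(
          specimen_id = id, species = sp_name,
          lineage = lineage_of[k], geography = geo_of[k],
          stringsAsFactors = FALSE)
      }
      sp_rows[[sp_name]] <- data.frame(
        species = sp_name, n_specimens = n_here, n_lineages = n_lineages,
        lineage_divergence = divergence, singleton = n_here == 1L,
        shared_partner = NA_character_, stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, meta)
  rownames(md) <- NULL
  species_tr <- do.call(rbind, sp_rows)
  rownames(species_tr) <- NULL
  # plant shared haplotypes by literal copying between the first two
  # species of each designated genus
  for (g in shared_genera) {
    sp_a <- sprintf("Genus%03d sp01", g)
    sp_b <- sprintf("Genus%03d sp02", g)
    id_a <- md$specimen_id[md$species == sp_a][1L]
    id_b <- md$specimen_id[md$species == sp_b][1L]
    seqs[[id_b]] <- seqs[[id_a]]
    species_tr$shared_partner[species_tr$species == sp_a] <- sp_b
    species_tr$shared_partner[species_tr$species == sp_b] <- sp_a
  }
  sequences <- vapply(seqs, .code_to_string, character(1))[md$specimen_id]
  dataset <- barcode_dataset(md, sequences)
  specimens_tr <- do.call(rbind, truth_rows)[md$specimen_id, ]
  rownames(specimens_tr) <- NULL
  specimens_tr$singleton <-
    species_tr$singleton[match(specimens_tr$species, species_tr$species)]
  list(dataset = dataset,
       truth = list(specimens = specimens_tr, species = species_tr),
       config = cf)
}
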