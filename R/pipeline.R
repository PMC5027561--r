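# End-to-end pipeline chaining all stages, with a flat key=value config
# reader and report rendering in the standard table shapes.

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Recognised keys:
#' `fasta`, `metadata`, `bins`, `out_dir`, `seed`, `synthetic`
#' (true/false), `lineage_cutoff`, `bootstrap_reps`, `thresholds`
#' (comma-separated subset of `standard,optimized,local_minima` or numbers).
#'
#' @param path path to the config file.
#' @return Named list of character values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) .stopf("malformed config line: '%s'", bad[1L])
  stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                  vapply(kv, function(m) trimws(m[2L]), character(1)))
}

.log_stage <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full barcode-audit pipeline
#'
#' Chains every stage on a data set read from disk or generated by the
#' simulator: pairwise K2P matrix, distance summary by taxonomic level,
#' barcode-gap report, threshold selection (cumulative-error scan and
#' density local minima), leave-one-out BM/BCM/ASB identification at the
#' three canonical thresholds (0.01 / optimised / first local minimum), NJ
#' tree, species-cluster assessment, deep-lineage detection at the 2%
#' cutoff with a family-level candidate-species summary, and (when BIN
#' assignments are supplied) the BIN concordance report.  All tables are
#' written as TSV, the tree as Newick, and a JSON manifest collects every
#' count.  Percentages in TSVs use 2 decimals.
#'
#' @param out_dir output directory (created if missing).
#' @param fasta,metadata input paths (ignored when `synth` is given).
#' @param bins optional specimen-to-BIN TSV path.
#' @param synth optional [synth_config()]; when supplied the data set is
#'   generated and also written to `out_dir`.
#' @param thresholds character subset of
#'   `c("standard", "optimized", "local_minima")` and/or numeric values.
#' @param lineage_cutoff deep-lineage mean-divergence cutoff (proportion in
#'   (0, 0.5); default 0.02).
#' @param bootstrap_reps NJ bootstrap replicates (0 = skip bootstrap).
#' @param seed seed for the bootstrap resampler (the simulator uses
#'   `synth$seed`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir,
                         fasta = NULL, metadata = NULL, bins = NULL,
                         synth = NULL,
                         thresholds = c("standard", "optimized",
                                        "local_minima"),
                         lineage_cutoff = 0.02,
                         bootstrap_reps = 0,
                         seed = 1) {
  stopifnot(lineage_cutoff > 0, lineage_cutoff < 0.5)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, lineage_cutoff = lineage_cutoff)
  if (!is.null(synth)) {
    .log_stage("generating synthetic data set (seed %d)", synth$seed)
    gen <- generate_dataset(synth)
    dataset <- gen$dataset
    write_dataset(dataset, file.path(out_dir, "dataset.fasta"),
                  file.path(out_dir, "dataset.tsv"))
    .write_tsv(gen$truth$specimens, file.path(out_dir, "truth_specimens.tsv"))
    .write_tsv(gen$truth$species, file.path(out_dir, "truth_species.tsv"))
    jsonlite::write_json(gen$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    if (is.null(fasta) || is.null(metadata))
      .stopf("either synth or fasta+metadata must be supplied")
    .log_stage("reading data set")
    dataset <- read_dataset(fasta, metadata)
  }
  manifest$n_specimens <- nrow(dataset$metadata)
  manifest$n_species <- length(unique(dataset$metadata$species))
  manifest$n_singleton_species <- sum(species_sizes(dataset) == 1L)
  manifest$mean_specimens_per_species <-
    round(manifest$n_specimens / manifest$n_species, 1)

  .log_stage("computing pairwise K2P matrix (%d specimens)",
             manifest$n_specimens)
  dm <- pairwise_matrix(dataset)
  manifest$n_undefined_pairs <- dm$n_undefined
  write_distance_matrix(dm, file.path(out_dir, "distances.tsv"))

  .log_stage("distance summary by taxonomic level")
  lev <- summarize_by_level(dm, dataset)
  .write_tsv(lev, file.path(out_dir, "distance_summary.tsv"))
  within_sp <- lev$mean_pct[lev$level == "within_species"]
  within_gen <- lev$mean_pct[lev$level == "within_genus_between_species"]
  manifest$mean_within_species_pct <- within_sp
  manifest$mean_congeneric_pct <- within_gen
  manifest$congeneric_conspecific_ratio <-
    if (is.finite(within_sp) && within_sp > 0)
      congeneric_conspecific_ratio(within_gen, within_sp) else NA

  .log_stage("barcode-gap analysis")
  gap <- gap_report(dm, dataset)
  write_gap_report(gap, file.path(out_dir, "gap_report.tsv"))
  manifest$gap <- gap$counts

  .log_stage("threshold selection")
  species <- species_labels(dataset)
  scan <- optimize_threshold_cumulative(dm, species)
  pair_d <- dm$distance[upper.tri(dm$distance)]
  minima <- tryCatch(density_local_minima(pair_d[!is.na(pair_d)]),
                     error = function(e) numeric())
  thr <- c()
  for (t in thresholds) {
    if (t == "standard") thr <- c(thr, standard = 0.01)
    else if (t == "optimized") thr <- c(thr, optimized = scan$selected)
    else if (t == "local_minima") {
      if (length(minima)) thr <- c(thr, local_minima = minima[1L])
      else .warnf("no density local minimum; skipping that threshold")
    } else thr <- c(thr, stats::setNames(as.numeric(t), t))
  }
  manifest$thresholds <- as.list(thr)
  manifest$threshold_scan <- list(
    optimal_interval = scan$optimal_interval, selected = scan$selected,
    min_cumulative_error = min(scan$cumulative))
  manifest$density_minima <- as.numeric(minima)

  .log_stage("leave-one-out identification (%d thresholds)", length(thr))
  idn <- simulate_identification(dataset, dm, thresholds = thr)
  .write_tsv(idn$summary, file.path(out_dir, "identification_summary.tsv"))
  .write_tsv(idn$per_query, file.path(out_dir, "identification_per_query.tsv"))
  manifest$identification <- idn$summary
  manifest$n_queries <- idn$n_queries
  manifest$n_skipped_queries <- idn$n_skipped

  .log_stage("neighbour joining and cluster assessment")
  tree <- neighbor_joining(dm)
  if (bootstrap_reps > 0) {
    .log_stage("bootstrap (%d replicates)", bootstrap_reps)
    tree <- bootstrap_support(dataset, n_reps = bootstrap_reps, seed = seed)
  }
  ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  haps <- collapse_haplotypes(dataset)
  .write_tsv(as.data.frame(haps), file.path(out_dir, "haplotypes.tsv"))
  shared_pairs <- shared_haplotype_pairs(haps)
  assess <- assess_species_clusters(tree, species, shared_pairs)
  .write_tsv(data.frame(species = names(assess$status),
                        status = unname(assess$status)),
             file.path(out_dir, "cluster_assessment.tsv"))
  manifest$clusters <- as.list(assess$counts)
  manifest$n_shared_haplotypes <- sum(haps$shared)

  .log_stage("deep-lineage detection (cutoff %.3f)", lineage_cutoff)
  sizes <- species_sizes(dataset)
  multi <- names(sizes)[sizes >= 2L]
  partitions <- lapply(multi, function(s)
    deep_lineages(dm, dataset, s, cutoff = lineage_cutoff))
  lin_tab <- do.call(rbind, lapply(partitions, function(p)
    data.frame(species = p$species, n_lineages = p$n_lineages,
               stringsAsFactors = FALSE)))
  .write_tsv(lin_tab, file.path(out_dir, "lineages.tsv"))
  indist <- names(assess$status)[assess$status == "shared_cluster"]
  fam <- candidate_species_summary(partitions, dataset,
                                   indistinguishable = indist)
  .write_tsv(as.data.frame(fam), file.path(out_dir, "family_summary.tsv"))
  manifest$family_summary <- attr(fam, "totals")

  if (!is.null(bins)) {
    .log_stage("BIN concordance")
    assignments <- read_bin_assignments(bins, dataset)
    rep <- classify_bins(dataset, assignments)
    .write_tsv(rep$bin_table, file.path(out_dir, "bin_table.tsv"))
    .write_tsv(rep$sharing_table, file.path(out_dir, "bin_sharing.tsv"))
    .write_tsv(rep$split_table, file.path(out_dir, "bin_splits.tsv"))
    manifest$bins <- rep$counts
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  .log_stage("done: %s", out_dir)
  invisible(manifest)
}
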