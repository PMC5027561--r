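# Leave-one-out specimen identification: Best Match (BM), Best Close Match
# (BCM) and All Species Barcodes (ASB), plus the two data-driven
# threshold-selection procedures.

# Outcome of one query given its distances to the references.
# criterion: "BM" (threshold ignored), "BCM", "ASB".
# "Below a defined threshold" is implemented as strict `<`; distance ties
# are detected by exact equality of stored values (no epsilon), so that
# planted exact ties behave deterministically.
.query_outcome <- function(d_ref, ref_species, query_species,
                           criterion, threshold = NULL) {
  defined <- !is.na(d_ref)
  if (!any(defined))
    .stopf("all distances from the query to references are undefined")
  d <- d_ref[defined]
  sp <- ref_species[defined]
  if (criterion != "BM") {
    within <- d < threshold
    if (!any(within))
      return(list(outcome = "no_id", best_match_species = NA_character_,
                  best_match_distance = NA_real_))
    d <- d[within]
    sp <- sp[within]
  }
  if (criterion == "ASB") {
    species_in <- unique(sp)
    outcome <- if (length(species_in) >= 2L) "ambiguous"
               else if (species_in == query_species) "true" else "false"
    best <- which.min(d)
    return(list(outcome = outcome, best_match_species = sp[best],
                best_match_distance = d[best]))
  }
  m <- min(d)
  best_sp <- unique(sp[d == m])
  outcome <- if (length(best_sp) >= 2L) "ambiguous"
             else if (best_sp == query_species) "true" else "false"
  list(outcome = outcome,
       best_match_species = if (length(best_sp) == 1L) best_sp else NA_character_,
       best_match_distance = m)
}

.one_query <- function(query_id, matrix, species, criterion, threshold) {
  i <- match(query_id, matrix$ids)
  if (is.na(i)) .stopf("unknown specimen '%s'", query_id)
  res <- .query_outcome(matrix$distance[i, -i], species[matrix$ids[-i]],
                        species[[query_id]], criterion, threshold)
  c(list(query_id = query_id, criterion = criterion,
         threshold = if (criterion == "BM") NA_real_ else threshold), res)
}

#' Best Match identification of one query
#'
#' Leave-one-out: the query is identified by its closest reference
#' regardless of distance.  `true` if the unique closest reference is
#' conspecific, `false` if heterospecific, `ambiguous` when the minimal
#' distance is attained by references of two or more species.  BM never
#' returns `no_id`.
#'
#' @param query_id specimen id of the query.
#' @param matrix a `k2p_matrix` over all records (query included).
#' @param species named character vector of species labels (see
#'   [species_labels()]).
#' @return List with `query_id`, `criterion`, `threshold`, `outcome`,
#'   `best_match_species`, `best_match_distance`.
#' @export
best_match <- function(query_id, matrix, species)
  .one_query(query_id, matrix, species, "BM", NULL)

#' Best Close Match identification of one query
#'
#' Like [best_match()], but references farther than the threshold (strict
#' `<`) are discarded first; an empty reference set yields `no_id`.
#'
#' @inheritParams best_match
#' @param threshold positive distance threshold.
#' @export
best_close_match <- function(query_id, matrix, species, threshold) {
  stopifnot(threshold > 0)
  .one_query(query_id, matrix, species, "BCM", threshold)
}

#' All Species Barcodes identification of one query
#'
#' Collects every reference closer than the threshold: none gives `no_id`;
#' references of two or more species give `ambiguous`; a single species
#' gives `true`/`false` by congruence with the query's label.
#'
#' @inheritParams best_close_match
#' @export
all_species_barcodes <- function(query_id, matrix, species, threshold) {
  stopifnot(threshold > 0)
  .one_query(query_id, matrix, species, "ASB", threshold)
}

.OUTCOMES <- c("true", "false", "ambiguous", "no_id")

#' Leave-one-out identification simulation
#'
#' Every record is used once as a query against all remaining records, for
#' each requested criterion and (for BCM/ASB) each threshold.  Percentages
#' are reported over all queries and, in the `*_excl` columns, after
#' excluding singleton queries (species with one specimen, which can never
#' be identified as `true`).  Queries whose distances to every reference
#' are undefined are skipped, with a count.
#'
#' @param dataset a `barcode_dataset`.
#' @param matrix the matching `k2p_matrix`.
#' @param criteria subset of `c("BM", "BCM", "ASB")`.
#' @param thresholds named numeric vector of thresholds applied to BCM and
#'   ASB (names label the rows, e.g. `c(standard = 0.01)`).
#' @return Object of class `identification_summary`: list with `summary`
#'   (one row per criterion x threshold: percentages of
#'   true/false/ambiguous/no_id, with and without singletons), `per_query`
#'   (long data frame of every outcome), `n_queries`, `n_singletons`,
#'   `n_skipped`.
#' @export
simulate_identification <- function(dataset, matrix,
                                    criteria = c("BM", "BCM", "ASB"),
                                    thresholds = c(standard = 0.01)) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  species <- species_labels(dataset)
  sizes <- species_sizes(dataset)
  singleton <- stats::setNames(unname(sizes[species]) == 1L, names(species))
  ids <- matrix$ids
  n <- length(ids)
  usable <- vapply(seq_len(n), function(i)
    any(!is.na(matrix$distance[i, -i])), logical(1))
  n_skipped <- sum(!usable)
  runs <- list()
  if ("BM" %in% criteria)
    runs[[length(runs) + 1L]] <- list(criterion = "BM",
                                      threshold = NA_real_,
                                      threshold_name = "")
  for (cr in intersect(c("BCM", "ASB"), criteria))
    for (k in seq_along(thresholds))
      runs[[length(runs) + 1L]] <- list(
        criterion = cr, threshold = unname(thresholds[k]),
        threshold_name = if (is.null(names(thresholds))) "" else names(thresholds)[k])
  per_query <- list()
  summary_rows <- list()
  for (run in runs) {
    out <- vapply(which(usable), function(i) {
      r <- .query_outcome(matrix$distance[i, -i], species[ids[-i]],
                          species[[ids[i]]], run$criterion, run$threshold)
      c(r$outcome, r$best_match_species, as.character(r$best_match_distance))
    }, character(3))
    outcome <- factor(out[1L, ], levels = .OUTCOMES)
    per_query[[length(per_query) + 1L]] <- data.frame(
      query_id = ids[usable], criterion = run$criterion,
      threshold = run$threshold, threshold_name = run$threshold_name,
      outcome = as.character(outcome),
      best_match_species = out[2L, ],
      best_match_distance = as.numeric(out[3L, ]),
      singleton = unname(singleton[ids[usable]]),
      stringsAsFactors = FALSE)
    pcts <- function(keep) {
      tb <- table(outcome[keep])
      as.numeric(.pct(tb / sum(tb), 2))
    }
    all_p <- pcts(rep(TRUE, sum(usable)))
    ns_p <- pcts(!singleton[ids[usable]])
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      criterion = run$criterion, threshold = run$threshold,
      threshold_name = run$threshold_name,
      n_queries = sum(usable),
      pct_true = all_p[1L], pct_false = all_p[2L],
      pct_ambiguous = all_p[3L], pct_no_id = all_p[4L],
      pct_true_excl = ns_p[1L], pct_false_excl = ns_p[2L],
      pct_ambiguous_excl = ns_p[3L], pct_no_id_excl = ns_p[4L],
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 per_query = do.call(rbind, per_query),
                 n_queries = sum(usable),
                 n_singletons = sum(singleton[ids[usable]]),
                 n_skipped = n_skipped),
            class = "identification_summary")
}

#' @export
print.identification_summary <- function(x, ...) {
  cat(sprintf("identification_summary: %d queries (%d singletons, %d skipped)\n",
              x$n_queries, x$n_singletons, x$n_skipped))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Threshold optimisation by cumulative identification error
#'
#' Scans a grid of candidate thresholds and, at each value `t`, counts the
#' false-positive error (queries with no conspecific match closer than `t`
#' although conspecific records exist in the data set) and the
#' false-negative error (queries with records of more than one species
#' closer than `t`).  The optimal interval is the grid region attaining the
#' minimum of their sum; the selected threshold is the mean of the interval
#' endpoints.  Queries of singleton species are excluded from the
#' false-positive count (no conspecific is available to them).
#'
#' @param matrix a `k2p_matrix`.
#' @param species named species labels (see [species_labels()]).
#' @param grid strictly increasing vector of candidate thresholds; the
#'   default, 0.001 to 0.20 by 0.001, covers the usual COI range.
#' @return Object of class `threshold_scan`: list with `grid`,
#'   `false_positive`, `false_negative`, `cumulative`, `optimal_interval`
#'   (`c(lo, hi)`), `selected`.
#' @export
optimize_threshold_cumulative <- function(matrix, species,
                                          grid = seq(0.001, 0.20, by = 0.001)) {
  if (!length(grid)) .stopf("empty threshold grid")
  if (any(diff(grid) <= 0)) .stopf("grid must be strictly increasing")
  ids <- matrix$ids
  n <- length(ids)
  sp <- species[ids]
  # per query: min conspecific distance (Inf when conspecifics exist but
  # are all undefined), and the distance at which a second species enters.
  min_consp <- rep(NA_real_, n)
  second_sp <- rep(Inf, n)
  has_consp <- logical(n)
  for (i in seq_len(n)) {
    d <- matrix$distance[i, -i]
    rsp <- sp[-i]
    has_consp[i] <- any(rsp == sp[i])
    if (has_consp[i]) {
      dc <- d[rsp == sp[i]]
      min_consp[i] <- if (all(is.na(dc))) Inf else min(dc, na.rm = TRUE)
    }
    per_sp <- tapply(d, rsp, function(v)
      if (all(is.na(v))) Inf else min(v, na.rm = TRUE))
    per_sp <- sort(per_sp)
    if (length(per_sp) >= 2L) second_sp[i] <- per_sp[2L]
  }
  fp <- vapply(grid, function(t) sum(has_consp & !(min_consp < t)), numeric(1))
  fn <- vapply(grid, function(t) sum(second_sp < t), numeric(1))
  cum <- fp + fn
  best <- which(cum == min(cum))
  interval <- c(grid[min(best)], grid[max(best)])
  structure(list(grid = grid, false_positive = fp, false_negative = fn,
                 cumulative = cum, optimal_interval = interval,
                 selected = mean(interval)),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "threshold_scan: minimum cumulative error %d in [%g, %g]; selected %g\n",
    min(x$cumulative), x$optimal_interval[1L], x$optimal_interval[2L],
    x$selected))
  invisible(x)
}

#' Local minima of the pairwise-distance density
#'
#' Gaussian kernel density estimate of all defined pairwise distances
#' (Silverman's rule-of-thumb bandwidth, 512-point grid over `[0, max]`);
#' returns every interior grid point whose density is strictly smaller than
#' both neighbours, in ascending order.  The first minimum is the
#' designated transition between intra- and interspecific distances.
#'
#' @param distances numeric vector of defined pairwise distances (>= 10
#'   values).
#' @param bw bandwidth rule passed to [stats::density()]; the default
#'   `"nrd0"` is Silverman's rule of thumb.
#' @param n_grid number of grid points.
#' @return Numeric vector of local-minimum locations (possibly empty, with
#'   a warning when the density is monotone); the estimated density is
#'   attached as attribute `"density"`.
#' @export
density_local_minima <- function(distances, bw = "nrd0", n_grid = 512) {
  distances <- distances[!is.na(distances)]
  if (length(distances) < 10L) .stopf("need at least 10 distance values")
  dens <- stats::density(distances, bw = bw, n = n_grid,
                         from = 0, to = max(distances))
  y <- dens$y
  # the FFT-based KDE leaves numerical ripple around zero in empty regions;
  # clamp it so noise is not mistaken for multimodality
  y[y < max(y) * 1e-10] <- 0
  n <- length(y)
  is_min <- logical(n)
  k <- seq(2L, n - 1L)
  is_min[k] <- y[k] < y[k - 1L] & y[k] < y[k + 1L]
  # an interior zero plateau flanked by positive density is one minimum,
  # placed at the plateau midpoint
  r <- rle(y == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values))
    if (starts[i] > 1L && ends[i] < n)
      is_min[(starts[i] + ends[i]) %/% 2L] <- TRUE
  minima <- dens$x[is_min]
  if (!length(minima))
    .warnf("density has no interior local minimum")
  structure(minima, density = dens)
}
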