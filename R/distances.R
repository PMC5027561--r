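# Kimura two-parameter distances and hierarchical distance summaries.

# K2P estimator from transition fraction P and transversion fraction Q:
#   d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))
# Undefined (saturated) when either log argument is non-positive.
.k2p_from_pq <- function(p, q) {
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d <- rep(NA_real_, length(w1))
  dim(d) <- dim(w1)
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  d
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap, `N` or an IUPAC ambiguity code
#' are excluded (pairwise deletion).  Over the remaining `n_sites`, `P` is
#' the transition fraction (A<->G, C<->T) and `Q` the transversion fraction;
#' the distance is `-1/2 ln((1-2P-Q) sqrt(1-2Q))`.  The distance is `NA`
#' (undefined: saturation, or zero site overlap) when a log argument is
#' non-positive or no site is comparable.
#'
#' @param seq_a,seq_b aligned DNA strings of equal length.
#' @return List with `distance` (or `NA`), `p_transitions`,
#'   `q_transversions`, `n_sites`.
#' @examples
#' k2p_distance("AAAA", "AAGA")  # P = 0.25: distance 0.34657
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    .stopf("sequence length mismatch: %d vs %d", nchar(seq_a), nchar(seq_b))
  code <- .encode_sequences(c(a = seq_a, b = seq_b))
  ok <- code[1L, ] > 0L & code[2L, ] > 0L
  n <- sum(ok)
  if (n == 0L)
    return(list(distance = NA_real_, p_transitions = NA_real_,
                q_transversions = NA_real_, n_sites = 0L))
  a <- code[1L, ok]
  b <- code[2L, ok]
  diff <- a != b
  # purines coded 1 (A) and 3 (G); transition iff both purine or both pyrimidine
  ts <- diff & ((a %% 2L) == (b %% 2L))
  p <- sum(ts) / n
  q <- sum(diff & !ts) / n
  list(distance = .k2p_from_pq(p, q), p_transitions = p,
       q_transversions = q, n_sites = n)
}

# Distance-matrix core on an encoded (n x L integer) alignment; returns the
# estimator pieces so callers can keep or drop the components.
.k2p_core <- function(code) {
  ia <- (code == 1L) * 1
  ic <- (code == 2L) * 1
  ig <- (code == 3L) * 1
  it <- (code == 4L) * 1
  v <- ia + ic + ig + it
  n_sites <- v %*% t(v)
  match_ <- ia %*% t(ia) + ic %*% t(ic) + ig %*% t(ig) + it %*% t(it)
  ts <- ia %*% t(ig) + ig %*% t(ia) + ic %*% t(it) + it %*% t(ic)
  tv <- n_sites - match_ - ts
  p <- ifelse(n_sites > 0, ts / n_sites, NA_real_)
  q <- ifelse(n_sites > 0, tv / n_sites, NA_real_)
  d <- .k2p_from_pq(p, q)
  diag(d) <- 0
  list(d = d, p = p, q = q, n_sites = n_sites)
}

#' Pairwise K2P distance matrix for a data set
#'
#' Computes every unordered pair under pairwise deletion.  Undefined entries
#' (saturation or zero overlap) are `NA`, symmetrically.  Implemented with
#' per-base indicator cross-products so the full matrix of a few hundred
#' specimens takes seconds.
#'
#' @param dataset a `barcode_dataset` with at least 2 records.
#' @return Object of class `k2p_matrix`: list with `ids`, `distance`
#'   (symmetric matrix, `NA` = undefined, zero diagonal), `p`, `q`,
#'   `n_sites` (matrices of the estimator components) and `n_undefined`
#'   (count of undefined unordered pairs).
#' @export
pairwise_matrix <- function(dataset) {
  if (length(dataset$sequences) < 2L) .stopf("need at least 2 records")
  code <- .encode_sequences(dataset$sequences)
  core <- .k2p_core(code)
  d <- core$d
  p <- core$p
  q <- core$q
  n_sites <- core$n_sites
  ids <- names(dataset$sequences)
  dimnames(d) <- dimnames(p) <- dimnames(q) <- dimnames(n_sites) <-
    list(ids, ids)
  structure(list(ids = ids, distance = d, p = p, q = q,
                 n_sites = n_sites,
                 n_undefined = sum(is.na(d[upper.tri(d)]))),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat(sprintf("k2p_matrix: %d specimens, %d undefined pairs\n",
              length(x$ids), x$n_undefined))
  invisible(x)
}

.LEVELS <- c("within_species",
             "within_genus_between_species",
             "within_family_between_genera",
             "within_order_between_families",
             "within_class_between_orders",
             "between_classes")

# Level code (1..6) of every unordered specimen pair: the lowest shared
# taxonomic rank determines the level.
.pair_levels <- function(dataset) {
  md <- dataset$metadata
  n <- nrow(md)
  lev <- matrix(6L, n, n)
  same <- function(col) outer(md[[col]], md[[col]], "==")
  lev[same("class")] <- 5L
  lev[same("order")] <- 4L
  lev[same("family")] <- 3L
  lev[same("genus")] <- 2L
  lev[same("species")] <- 1L
  lev
}

#' Distance summary by taxonomic level
#'
#' Assigns every specimen pair to exactly one level by the lowest shared
#' rank (conspecific, congeneric non-conspecific, confamilial different
#' genera, ...) and reports min / mean / max / SE of the K2P distances per
#' level, in percent.  SE is the standard error of the mean over pair
#' distances (pairs treated as independent).  Undefined distances are
#' excluded, with their count reported per level.  Pairs from different
#' classes fall in an extra `between_classes` row.
#'
#' @param matrix a `k2p_matrix` from [pairwise_matrix()].
#' @param dataset the `barcode_dataset` the matrix was computed from.
#' @return Data frame with columns `level`, `n_pairs`, `n_undefined`,
#'   `min_pct`, `mean_pct`, `max_pct`, `se_pct`.  Empty levels keep
#'   `n_pairs = 0` and `NA` statistics.
#' @export
summarize_by_level <- function(matrix, dataset) {
  stopifnot(inherits(matrix, "k2p_matrix"))
  if (!identical(matrix$ids, dataset$metadata$specimen_id))
    .stopf("matrix ids do not match dataset order")
  lev <- .pair_levels(dataset)
  ut <- upper.tri(lev)
  lev_v <- lev[ut]
  d_v <- matrix$distance[ut]
  out <- lapply(seq_along(.LEVELS), function(k) {
    d <- d_v[lev_v == k]
    nd <- sum(is.na(d))
    d <- d[!is.na(d)]
    data.frame(level = .LEVELS[k],
               n_pairs = length(d),
               n_undefined = nd,
               min_pct = if (length(d)) .pct(min(d)) else NA_real_,
               mean_pct = if (length(d)) .pct(mean(d)) else NA_real_,
               max_pct = if (length(d)) .pct(max(d)) else NA_real_,
               se_pct = if (length(d) > 1L)
                 .pct(stats::sd(d) / sqrt(length(d)), 3)
               else if (length(d) == 1L) 0 else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (res$n_pairs[res$level == "between_classes"] == 0L &&
      res$n_undefined[res$level == "between_classes"] == 0L)
    res <- res[res$level != "between_classes", , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ratio of congeneric to conspecific mean divergence
#'
#' @param mean_congeneric_pct mean congeneric (between-species) divergence,
#'   percent.
#' @param mean_conspecific_pct mean conspecific divergence, percent; must be
#'   positive.
#' @return The ratio rounded to 2 decimals, or `NA` with a warning when the
#'   denominator is zero.
#' @examples
#' congeneric_conspecific_ratio(18.67, 0.97)  # 19.25
#' @export
congeneric_conspecific_ratio <- function(mean_congeneric_pct,
                                         mean_conspecific_pct) {
  if (!is.finite(mean_conspecific_pct) || mean_conspecific_pct <= 0) {
    .warnf("conspecific mean is zero or undefined; ratio undefined")
    return(NA_real_)
  }
  round(mean_congeneric_pct / mean_conspecific_pct, 2)
}

#' Ordinary least-squares regression
#'
#' Thin wrapper around [stats::lm()] returning the quantities reported for
#' sample-size regressions: slope, intercept, R-squared, the two-sided
#' p-value for slope = 0, and n.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, `x` not constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) .stopf("need at least 3 complete observations")
  if (stats::var(x) == 0) .stopf("x is constant")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1L], r_squared = 0,
                p_value = NA_real_, n = length(x)))
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2L, 4L]),
       n = length(x))
}

#' Export a distance matrix as TSV / PHYLIP text
#'
#' Writes either a lower-triangular TSV (`specimen_a`, `specimen_b`,
#' `distance`) or a square PHYLIP-style matrix.  Undefined entries are the
#' literal `NA`.
#'
#' @param matrix a `k2p_matrix`.
#' @param path output path.
#' @param format `"tsv"` (long lower triangle) or `"phylip"` (square).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(matrix, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  d <- matrix$distance
  if (format == "tsv") {
    idx <- which(lower.tri(d), arr.ind = TRUE)
    tab <- data.frame(specimen_a = matrix$ids[idx[, 2L]],
                      specimen_b = matrix$ids[idx[, 1L]],
                      distance = d[idx])
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d", length(matrix$ids)), con)
    for (i in seq_along(matrix$ids))
      writeLines(paste(c(matrix$ids[i], formatC(d[i, ], format = "g")),
                       collapse = "\t"), con)
  }
  invisible(path)
}
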