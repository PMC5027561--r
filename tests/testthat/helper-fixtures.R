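# Fixture builders and independent brute-force oracles used across tests.

# Minimal dataset from sequences + species labels; higher ranks default to
# one genus per species-name prefix, one family/order/class overall.
make_dataset <- function(sequences, species,
                         genus = sub(" .*", "", species),
                         family = "FamA", order = "OrdA", class = "ClsA",
                         site = "") {
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("q%02d", seq_len(n))
  md <- data.frame(specimen_id = ids, species = species, genus = genus,
                   family = rep_len(family, n), order = rep_len(order, n),
                   class = rep_len(class, n),
                   country_or_site = rep_len(site, n),
                   stringsAsFactors = FALSE)
  barcode_dataset(md, stats::setNames(sequences, ids))
}

# Wrap a plain symmetric matrix as the distance object the analysis
# functions consume, so tests can force exact distances and ties.
fake_matrix <- function(d, ids = rownames(d)) {
  if (is.null(ids)) ids <- sprintf("q%02d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, distance = d, p = NULL, q = NULL,
                 n_sites = NULL, n_undefined = sum(is.na(d[upper.tri(d)]))),
            class = "k2p_matrix")
}

# Dataset with dummy one-base-per-site sequences for functions that need a
# dataset alongside a fake matrix (sequences unused there).
fake_dataset_for <- function(ids, species, genus = sub(" .*", "", species)) {
  make_dataset(stats::setNames(rep(strrep("A", 10), length(ids)), ids),
               species, genus = genus)
}

# --- independent oracles -------------------------------------------------

# Naive per-site K2P: direct transcription of the closed form.
oracle_k2p <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  if (n == 0) return(NA_real_)
  ts <- sum((av == "A" & bv == "G") | (av == "G" & bv == "A") |
            (av == "C" & bv == "T") | (av == "T" & bv == "C"))
  tv <- sum(av != bv) - ts
  P <- ts / n; Q <- tv / n
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

oracle_pairwise <- function(dataset) {
  seqs <- dataset$sequences
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    d[i, j] <- d[j, i] <- oracle_k2p(seqs[[i]], seqs[[j]])
  d
}

# Brute-force nearest neighbour of a species: minimum over every
# heterospecific specimen pair.
oracle_nn <- function(d, species_of, focal) {
  rows <- which(species_of == focal)
  best <- Inf; best_sp <- NA_character_
  for (i in rows) for (j in which(species_of != focal)) {
    if (!is.na(d[i, j])) {
      if (d[i, j] < best ||
          (d[i, j] == best && species_of[j] < best_sp)) {
        best <- d[i, j]; best_sp <- species_of[j]
      }
    }
  }
  list(nn_species = best_sp, nn_distance = best)
}

# Brute-force leave-one-out outcome for one query.
oracle_outcome <- function(d, species_of, i, criterion, threshold = NULL) {
  dd <- d[i, -i]; sp <- species_of[-i]
  ok <- !is.na(dd)
  dd <- dd[ok]; sp <- sp[ok]
  if (criterion %in% c("BCM", "ASB")) {
    keep <- dd < threshold
    if (!any(keep)) return("no_id")
    dd <- dd[keep]; sp <- sp[keep]
  }
  if (criterion == "ASB") {
    u <- unique(sp)
    if (length(u) > 1) return("ambiguous")
    return(if (u == species_of[i]) "true" else "false")
  }
  m <- min(dd)
  u <- unique(sp[dd == m])
  if (length(u) > 1) return("ambiguous")
  if (u == species_of[i]) "true" else "false"
}

# Brute-force cumulative-error scan.
oracle_scan <- function(d, species_of, grid) {
  n <- nrow(d)
  fp <- fn <- numeric(length(grid))
  singleton <- table(species_of)[species_of] == 1
  for (k in seq_along(grid)) {
    t <- grid[k]
    for (i in seq_len(n)) {
      dd <- d[i, -i]; sp <- species_of[-i]
      within <- !is.na(dd) & dd < t
      if (!singleton[i] && !any(within & sp == species_of[i]))
        fp[k] <- fp[k] + 1
      if (length(unique(sp[within])) > 1)
        fn[k] <- fn[k] + 1
    }
  }
  list(fp = fp, fn = fn, cum = fp + fn)
}

# Random additive distance matrix from a random tree.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  as.matrix(stats::cophenetic(tr))
}
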