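# Leave-one-out identification: outcome rules, simulation, and the two
# threshold-selection procedures.

.id_fixture <- function() {
  ids <- c("a1", "a2", "b1", "b2", "c1")
  sp <- stats::setNames(c("G spA", "G spA", "G spB", "G spB", "G spC"), ids)
  d <- matrix(0.10, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.005
  d["b1", "b2"] <- d["b2", "b1"] <- 0.008
  d["c1", "b1"] <- d["b1", "c1"] <- 0.09  # singleton's unique closest
  list(ids = ids, sp = sp, dm = fake_matrix(d, ids),
       ds = fake_dataset_for(ids, unname(sp)))
}

test_that("best match: conspecific, heterospecific and tied closest", {
  f <- .id_fixture()
  expect_equal(best_match("a1", f$dm, f$sp)$outcome, "true")
  # singleton query: closest is necessarily heterospecific
  expect_equal(best_match("c1", f$dm, f$sp)$outcome, "false")
  # exact-distance tie across two species is ambiguous
  d <- f$dm$distance
  d["a1", "b1"] <- d["b1", "a1"] <- 0.005  # ties with a2 at 0.005
  expect_equal(best_match("a1", fake_matrix(d), f$sp)$outcome, "ambiguous")
  # conspecific-only tie stays true
  d <- f$dm$distance
  d["a1", "a2"] <- d["a2", "a1"] <- 0.005
  ids6 <- c(f$ids, "a3")
  d6 <- rbind(cbind(d, a3 = 0.1), a3 = c(rep(0.1, 5), 0))
  d6["a1", "a3"] <- d6["a3", "a1"] <- 0.005
  sp6 <- c(f$sp, a3 = "G spA")
  expect_equal(best_match("a1", fake_matrix(d6, ids6), sp6)$outcome, "true")
})

test_that("best close match: threshold filter and no_id", {
  f <- .id_fixture()
  expect_equal(best_close_match("a1", f$dm, f$sp, 0.01)$outcome, "true")
  # nearest reference beyond the threshold
  expect_equal(best_close_match("c1", f$dm, f$sp, 0.01)$outcome, "no_id")
  # strict '<': a reference exactly at the threshold is outside it
  expect_equal(best_close_match("a1", f$dm, f$sp, 0.005)$outcome, "no_id")
  # tie below threshold between two species
  d <- f$dm$distance
  d["a1", "b1"] <- d["b1", "a1"] <- 0.005
  expect_equal(best_close_match("a1", fake_matrix(d), f$sp, 0.01)$outcome,
               "ambiguous")
})

test_that("all species barcodes: every in-threshold reference must agree", {
  f <- .id_fixture()
  # only conspecifics within threshold
  expect_equal(all_species_barcodes("a1", f$dm, f$sp, 0.01)$outcome, "true")
  # conspecific at 0.004 plus heterospecific at 0.009: ASB ambiguous, BCM true
  d <- f$dm$distance
  d["a1", "a2"] <- d["a2", "a1"] <- 0.004
  d["a1", "b1"] <- d["b1", "a1"] <- 0.009
  dm <- fake_matrix(d)
  expect_equal(all_species_barcodes("a1", dm, f$sp, 0.01)$outcome, "ambiguous")
  expect_equal(best_close_match("a1", dm, f$sp, 0.01)$outcome, "true")
  # heterospecific only
  d2 <- f$dm$distance
  d2["c1", "a1"] <- d2["a1", "c1"] <- 0.003
  expect_equal(all_species_barcodes("c1", fake_matrix(d2), f$sp, 0.01)$outcome,
               "false")
})

test_that("simulation matches hand-enumerated fixtures", {
  # 2 species x 2 records, intra 0.01 / inter 0.10: all four BM queries true
  ids <- c("a1", "a2", "b1", "b2")
  sp <- c("G spA", "G spA", "G spB", "G spB")
  d <- matrix(0.10, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.01
  d["b1", "b2"] <- d["b2", "b1"] <- 0.01
  ds <- fake_dataset_for(ids, sp)
  sim <- simulate_identification(ds, fake_matrix(d, ids), criteria = "BM")
  expect_equal(sim$summary$pct_true, 100)
  # adding a singleton: 5 queries, 4 true, 1 false (the singleton)
  ids5 <- c(ids, "c1")
  d5 <- matrix(0.10, 5, 5, dimnames = list(ids5, ids5))
  diag(d5) <- 0
  d5[ids, ids] <- d
  d5["c1", "b1"] <- d5["b1", "c1"] <- 0.09  # unique closest for the singleton
  ds5 <- fake_dataset_for(ids5, c(sp, "G spC"))
  sim5 <- simulate_identification(ds5, fake_matrix(d5, ids5),
                                  criteria = "BM")
  expect_equal(sim5$summary$pct_true, 80)
  expect_equal(sim5$summary$pct_false, 20)
  # singleton exclusion restores 100% true
  expect_equal(sim5$summary$pct_true_excl, 100)
  # BCM with a vacuous threshold reproduces BM outcomes exactly
  sim_both <- simulate_identification(ds5, fake_matrix(d5, ids5),
                                      criteria = c("BM", "BCM"),
                                      thresholds = c(high = 0.5))
  pq <- sim_both$per_query
  expect_identical(pq$outcome[pq$criterion == "BM"],
                   pq$outcome[pq$criterion == "BCM"])
})

test_that("simulation equals brute force on random 25-record fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 25
    sp <- paste("G", sample(sprintf("sp%02d", 1:8), n, TRUE))
    d <- matrix(0, n, n)
    vals <- sample(seq(0.001, 0.25, 0.001), n * (n - 1) / 2, TRUE)
    d[upper.tri(d)] <- vals
    d <- d + t(d)
    ids <- sprintf("s%02d", 1:n)
    dimnames(d) <- list(ids, ids)
    ds <- fake_dataset_for(ids, sp)
    sim <- simulate_identification(ds, fake_matrix(d, ids),
                                   thresholds = c(t1 = 0.02))
    pq <- sim$per_query
    for (cr in c("BM", "BCM", "ASB")) {
      got <- pq$outcome[pq$criterion == cr]
      want <- vapply(seq_len(n), function(i)
        oracle_outcome(d, sp, i, cr, 0.02), character(1))
      expect_identical(got, want)
    }
  }
})

test_that("outcome categories always partition the queries", {
  f <- .id_fixture()
  sim <- simulate_identification(f$ds, f$dm,
                                 thresholds = c(a = 0.005, b = 0.05))
  sums <- rowSums(sim$summary[, c("pct_true", "pct_false",
                                  "pct_ambiguous", "pct_no_id")])
  expect_true(all(abs(sums - 100) < 0.05))
})

test_that("ASB true implies BCM true at every threshold", {
  cf <- synth_config(seed = 9, n_families = 2, genera_per_family = 2,
                     species_per_genus = 3, mean_specimens = 3,
                     planted_shared_pairs = 1,
                     planted_deep_species = list(c(2, 0.06)))
  g <- generate_dataset(cf)
  dm <- pairwise_matrix(g$dataset)
  sim <- simulate_identification(g$dataset, dm,
                                 thresholds = c(t1 = 0.01, t2 = 0.053))
  pq <- sim$per_query
  for (t in c(0.01, 0.053)) {
    asb <- pq$outcome[pq$criterion == "ASB" & pq$threshold == t]
    bcm <- pq$outcome[pq$criterion == "BCM" & pq$threshold == t]
    expect_true(all(bcm[asb == "true"] == "true"))
    s <- sim$summary
    expect_gte(s$pct_true[s$criterion == "BCM" & s$threshold == t],
               s$pct_true[s$criterion == "ASB" & s$threshold == t])
    # no_id is criterion-independent: same reference set is empty
    expect_identical(asb == "no_id", bcm == "no_id")
  }
})

test_that("BCM and ASB coincide when only one species falls within threshold", {
  cf <- synth_config(seed = 21, n_families = 2, genera_per_family = 2,
                     species_per_genus = 2, specimens_per_species = 3,
                     target_intra = 0.004, planted_shared_pairs = 0,
                     planted_deep_species = list())
  g <- generate_dataset(cf)
  dm <- pairwise_matrix(g$dataset)
  # threshold below half the congeneric distance: at most one species close
  sim <- simulate_identification(g$dataset, dm, criteria = c("BCM", "ASB"),
                                 thresholds = c(t = 0.03))
  pq <- sim$per_query
  expect_identical(pq$outcome[pq$criterion == "BCM"],
                   pq$outcome[pq$criterion == "ASB"])
})

test_that("cumulative-error threshold scan matches exhaustive evaluation", {
  f <- .id_fixture()
  grid <- seq(0.001, 0.15, by = 0.001)
  scan <- optimize_threshold_cumulative(f$dm, f$sp, grid)
  want <- oracle_scan(f$dm$distance, unname(f$sp), grid)
  expect_equal(scan$false_positive, want$fp)
  expect_equal(scan$false_negative, want$fn)
  expect_equal(scan$cumulative, want$cum)
  # clean fixture: zero-error interval strictly between intra and inter
  expect_equal(min(scan$cumulative), 0)
  expect_gt(scan$optimal_interval[1], 0.008)
  expect_lte(scan$optimal_interval[2], 0.10)
  expect_true(scan$selected >= scan$optimal_interval[1] &&
              scan$selected <= scan$optimal_interval[2])
  # random fixture: oracle equivalence under ties and mixed labels
  set.seed(3)
  n <- 20
  sp <- paste("G", sample(sprintf("sp%d", 1:6), n, TRUE))
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- sample(seq(0.001, 0.2, 0.001), n * (n - 1) / 2, TRUE)
  d <- d + t(d)
  ids <- sprintf("s%02d", 1:n)
  dimnames(d) <- list(ids, ids)
  scan2 <- optimize_threshold_cumulative(fake_matrix(d, ids),
                                         stats::setNames(sp, ids), grid)
  want2 <- oracle_scan(d, sp, grid)
  expect_equal(scan2$cumulative, want2$cum)
  expect_error(optimize_threshold_cumulative(f$dm, f$sp, numeric()), "empty")
})

test_that("grid below all intraspecific distances maximises false positives", {
  f <- .id_fixture()
  grid <- seq(0.001, 0.004, by = 0.001)  # below intra distances 0.005/0.008
  scan <- optimize_threshold_cumulative(f$dm, f$sp, grid)
  # every non-singleton query fails to find its conspecific at every t
  expect_true(all(scan$false_positive == 4))
  expect_true(all(scan$false_negative == 0))
})

test_that("density local minima separate intra- from interspecific modes", {
  x <- c(0, 0.005, 0.01, 0.015, 0.02, 0.10, 0.105, 0.11)
  # pad to the 10-value minimum with values inside the same two modes
  x <- c(x, 0.008, 0.102)
  mins <- density_local_minima(x)
  expect_equal(length(mins), 1L)
  expect_gt(mins[1], 0.02)
  expect_lt(mins[1], 0.10)
  # unimodal: no interior minimum
  set.seed(1)
  expect_warning(m0 <- density_local_minima(stats::rnorm(50, 0.1, 0.01)),
                 "no interior")
  expect_equal(length(m0), 0L)
  # three well-separated groups: two minima in ascending order
  y <- c(stats::rnorm(40, 0.01, 0.001), stats::rnorm(40, 0.10, 0.002),
         stats::rnorm(40, 0.25, 0.002))
  m2 <- density_local_minima(y)
  expect_equal(length(m2), 2L)
  expect_true(all(diff(m2) > 0))
  expect_true(m2[1] > 0.015 && m2[1] < 0.095)
  expect_true(m2[2] > 0.11 && m2[2] < 0.24)
  expect_error(density_local_minima(1:5 / 100), "at least 10")
})
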