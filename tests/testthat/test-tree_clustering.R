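test_that("NJ reproduces additive distances exactly", {
  # hand-solved additive matrix: split AB|CD with internal branch 1
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(ids, ids))
  tree <- neighbor_joining(fake_matrix(d, ids))
  expect_equal(sort(tree$edge.length), c(1, 1, 2, 3, 4))
  expect_equal(as.matrix(stats::cophenetic(tree))[ids, ids], d,
               tolerance = 1e-9)
  # 3 leaves: closed-form star resolution
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(fake_matrix(d3))
  expect_equal(as.matrix(stats::cophenetic(t3))[c("x", "y", "z"),
                                                c("x", "y", "z")], d3,
               tolerance = 1e-9)
})

test_that("NJ path lengths are exact on random additive matrices", {
  for (seed in 1:5) {
    d <- random_additive_matrix(12, seed)
    tree <- neighbor_joining(fake_matrix(d))
    ids <- rownames(d)
    expect_equal(as.matrix(stats::cophenetic(tree))[ids, ids], d,
                 tolerance = 1e-9)
  }
})

test_that("NJ drops specimens with undefined entries, or errors when asked", {
  d <- random_additive_matrix(6, 1)
  d[1, 3] <- d[3, 1] <- NA
  dm <- fake_matrix(d)
  expect_error(neighbor_joining(dm, drop_undefined = FALSE), "undefined")
  expect_message(tree <- neighbor_joining(dm), "dropped 1")
  expect_equal(ape::Ntip(tree), 5L)
  expect_false(attr(tree, "dropped") %in% tree$tip.label)
})

test_that("ultrametric two-cluster matrix separates the clusters", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.02
  d["b1", "b2"] <- d["b2", "b1"] <- 0.02
  tree <- neighbor_joining(fake_matrix(d, ids))
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(tips[p]))
  has <- function(s) any(vapply(sets, identical, logical(1), s))
  expect_true(has(c("a1", "a2")) || has(c("b1", "b2")))
})

test_that("bootstrap support is 100 on a clean deep split and deterministic", {
  # two clades of identical sequences, strongly divergent
  block <- function(ch, n) strrep(ch, n)
  x <- paste0(block("A", 120), block("T", 80))
  y <- paste0(block("G", 60), block("A", 60), block("T", 80))
  ds <- make_dataset(c(x1 = x, x2 = x, y1 = y, y2 = y),
                     c("G spX", "G spX", "G spY", "G spY"))
  tree <- bootstrap_support(ds, n_reps = 50, seed = 4)
  expect_equal(max(tree$node.label, na.rm = TRUE), 100)
  tree2 <- bootstrap_support(ds, n_reps = 50, seed = 4)
  expect_identical(tree$node.label, tree2$node.label)
  expect_error(bootstrap_support(ds, n_reps = 0), "n_reps")
})

test_that("species-cluster assessment: distinct, paraphyletic, shared", {
  sp <- c(a1 = "G spA", a2 = "G spA", b1 = "G spB", b2 = "G spB")
  # reciprocally monophyletic
  t1 <- ape::read.tree(text = "((a1:1,a2:1):2,(b1:1,b2:1):2);")
  s1 <- assess_species_clusters(t1, sp)
  expect_true(all(s1$status == "distinct_cluster"))
  # A paraphyletic around a monophyletic B
  t2 <- ape::read.tree(text = "((a1:1,(b1:1,b2:1):2):1,a2:3);")
  s2 <- assess_species_clusters(t2, sp)
  expect_equal(unname(s2$status["G spA"]), "paraphyletic")
  expect_equal(unname(s2$status["G spB"]), "distinct_cluster")
  # interleaved shared cluster: mutual overlap of minimal clades
  t3 <- ape::read.tree(text = "((a1:0.1,b1:0.1):1,(a2:0.1,b2:0.1):1);")
  s3 <- assess_species_clusters(t3, sp)
  expect_true(all(s3$status[c("G spA", "G spB")] == "shared_cluster"))
  expect_equal(s3$shared_groups, list(c("G spA", "G spB")))
  # singletons reported separately
  sp5 <- c(sp, c1 = "G spC")
  t5 <- ape::read.tree(text = "(((a1:1,a2:1):2,(b1:1,b2:1):2):1,c1:4);")
  s5 <- assess_species_clusters(t5, sp5)
  expect_equal(unname(s5$status["G spC"]), "singleton_unassessable")
  expect_equal(sum(s5$counts), 3L)
  expect_error(assess_species_clusters(t5, sp), "unlabelled")
  # known haplotype sharing forces shared_cluster over paraphyly
  s2f <- assess_species_clusters(t2, sp,
                                 shared_haplotype_pairs = cbind("G spA",
                                                                "G spB"))
  expect_equal(unname(s2f$status["G spA"]), "shared_cluster")
})

test_that("haplotype collapsing is exact and flags between-species sharing", {
  ds <- make_dataset(c(a1 = "ACGT-", a2 = "ACGT-", b1 = "ACGT-",
                       b2 = "ACNT-", c1 = "AGGT-"),
                     c("G spA", "G spA", "G spB", "G spB", "G spC"))
  h <- collapse_haplotypes(ds)
  expect_equal(nrow(h), 3L)
  shared <- h[h$shared, ]
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$species, "G spA,G spB")
  # N must match exactly: b2 is its own haplotype
  expect_true(any(h$specimen_ids == "b2"))
  pairs <- shared_haplotype_pairs(h)
  expect_equal(unname(pairs[1, ]), c("G spA", "G spB"))
})

test_that("deep lineages: cutoff is strict and order-invariant", {
  ids <- c("x1", "x2", "x3", "x4")
  sp <- rep("G spX", 4)
  # two tight groups, between-group mean 0.08
  d <- matrix(0.08, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["x1", "x2"] <- d["x2", "x1"] <- 0.004
  d["x3", "x4"] <- d["x4", "x3"] <- 0.004
  ds <- fake_dataset_for(ids, sp)
  lp <- deep_lineages(fake_matrix(d, ids), ds, "G spX")
  expect_equal(lp$n_lineages, 2L)
  expect_equal(lp$clusters, list(c("x1", "x2"), c("x3", "x4")))
  expect_true(all(lp$between_means[upper.tri(lp$between_means)] > 0.02))
  # all pairs <= 1%: single lineage
  d1 <- matrix(0.01, 4, 4, dimnames = list(ids, ids)); diag(d1) <- 0
  expect_equal(deep_lineages(fake_matrix(d1, ids), ds, "G spX")$n_lineages, 1L)
  # between-group mean exactly at the cutoff still merges (strictly 'over')
  d2 <- d; d2[d2 == 0.08] <- 0.02
  expect_equal(deep_lineages(fake_matrix(d2, ids), ds, "G spX")$n_lineages, 1L)
  # specimen order must not matter
  perm <- c(3, 1, 4, 2)
  dp <- d[perm, perm]
  dsp <- fake_dataset_for(ids[perm], sp)
  lpp <- deep_lineages(fake_matrix(dp, ids[perm]), dsp, "G spX")
  expect_equal(lpp$n_lineages, 2L)
  expect_equal(lpp$clusters, lp$clusters)
  expect_error(deep_lineages(fake_matrix(d, ids),
                             fake_dataset_for(ids, c(sp[1:3], "G spY")),
                             "G spY"), "singleton")
})

test_that("deep-lineage cut agrees with brute-force bipartition checking", {
  # every valid partition must have all between-cluster means > cutoff and
  # be unmergeable; verify the returned 2-cluster cut on a 5-point fixture
  ids <- sprintf("x%d", 1:5)
  d <- matrix(0.09, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) d[p[1], p[2]] <- d[p[2], p[1]] <- 0.006
  d["x4", "x5"] <- d["x5", "x4"] <- 0.006
  ds <- fake_dataset_for(ids, rep("G spX", 5))
  lp <- deep_lineages(fake_matrix(d, ids), ds, "G spX")
  expect_equal(lp$n_lineages, 2L)
  expect_equal(lp$clusters, list(c("x1", "x2", "x3"), c("x4", "x5")))
  # brute force: mean divergence across the returned cut
  cut_mean <- mean(d[lp$clusters[[1]], lp$clusters[[2]]])
  expect_gt(cut_mean, lp$cutoff)
})

test_that("family summary conserves lineage counts", {
  ids <- sprintf("s%d", 1:6)
  sp <- c("GA spA", "GA spA", "GA spB", "GA spB", "GB spC", "GB spC")
  d <- matrix(0.2, 6, 6, dimnames = list(ids, ids)); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.08   # spA deep split
  d[3, 4] <- d[4, 3] <- 0.005
  d[5, 6] <- d[6, 5] <- 0.005
  ds <- make_dataset(stats::setNames(rep(strrep("A", 10), 6), ids), sp,
                     family = c(rep("FamX", 4), rep("FamY", 2)))
  dm <- fake_matrix(d, ids)
  parts <- lapply(unique(sp), function(s) deep_lineages(dm, ds, s))
  fam <- candidate_species_summary(parts, ds)
  tot <- attr(fam, "totals")
  expect_equal(tot$species_total, 3L)
  expect_equal(tot$deep_species_total, 1L)
  expect_equal(tot$candidate_lineages_total, 2L)
  # conservation: sum over species of (n_lineages - 1) = lineages - deep
  n_lin <- vapply(parts, `[[`, integer(1), "n_lineages")
  expect_equal(sum(n_lin - 1L),
               tot$candidate_lineages_total - tot$deep_species_total)
  expect_equal(tot$percent_increase, round(100 * (2 - 1) / 3))
})

test_that("recovery: simulated reciprocal monophyly yields distinct clusters", {
  cf <- synth_config(seed = 12, n_families = 2, genera_per_family = 2,
                     species_per_genus = 2, specimens_per_species = 3,
                     target_intra = 0.004, planted_shared_pairs = 0,
                     planted_deep_species = list())
  g <- generate_dataset(cf)
  dm <- pairwise_matrix(g$dataset)
  tree <- neighbor_joining(dm)
  assess <- assess_species_clusters(tree, species_labels(g$dataset))
  expect_true(all(assess$status == "distinct_cluster"))
})
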