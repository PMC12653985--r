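test_that("Bruvo distance matches hand-enumerated matchings", {
  expect_equal(bruvo_pair(c(10, 10), c(10, 10)), 0)
  expect_equal(bruvo_pair(c(10, 10), c(10, 11)), 0.25)
  # {8,10} vs {9,11}: straight matching 0.5 beats crossed 0.6875
  expect_equal(bruvo_pair(c(8, 10), c(9, 11)), 0.5)
})

test_that("Bruvo distance equals the brute-force matching oracle", {
  set.seed(99)
  for (i in seq_len(1000)) {
    g1 <- sort(sample(5:15, 2, replace = TRUE))
    g2 <- sort(sample(5:15, 2, replace = TRUE))
    expect_equal(bruvo_pair(g1, g2), bruvo_locus_brute(g1, g2))
  }
})

test_that("Bruvo per-locus distance is a bounded semimetric empirically", {
  set.seed(100)
  for (i in seq_len(300)) {
    g <- lapply(1:3, function(k) sort(sample(5:12, 2, replace = TRUE)))
    d12 <- bruvo_pair(g[[1]], g[[2]])
    d13 <- bruvo_pair(g[[1]], g[[3]])
    d23 <- bruvo_pair(g[[2]], g[[3]])
    expect_gte(d12, 0); expect_lt(d12, 1)
    expect_equal(d12, bruvo_pair(g[[2]], g[[1]]))
    expect_lte(d12, d13 + d23 + 1e-12)
    if (identical(g[[1]], g[[2]])) expect_equal(d12, 0) else expect_gt(d12, 0)
  }
})

test_that("genotype-level Bruvo averages over mutually typed loci", {
  tab <- toy_table(list(L1 = c("10/10", "10/11"),
                        L2 = c("8/8", "NA/NA"),
                        L3 = c("7/9", "8/9")))
  D <- bruvo_distance(tab)
  # L2 missing in sample 2 -> mean over L1 and L3 only
  expect_equal(D[1, 2], mean(c(0.25, 0.25)))
  expect_equal(D[2, 1], D[1, 2])
  expect_equal(diag(D), c(S01 = 0, S02 = 0))

  # a pair sharing no typed locus is flagged undefined
  tab2 <- toy_table(list(L1 = c("8/8", "NA/NA"), L2 = c("NA/NA", "8/8")))
  D2 <- bruvo_distance(tab2)
  expect_true(is.na(D2[1, 2]))
  expect_equal(nrow(attr(D2, "undefined_pairs")), 1)
})

test_that("binary Jaccard distance follows the square-root formula", {
  # identical profiles -> 0; disjoint -> 1
  tab <- toy_table(list(L1 = c("8/9", "8/9", "10/11"),
                        L2 = c("7/7", "7/7", "6/6")))
  D <- jaccard_binary_distance(tab)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)

  # profiles sharing 2 of 4 present alleles (a=2, b+c=2): sqrt(1 - 2/4)
  tab2 <- toy_table(list(L1 = c("8/9", "8/9"), L2 = c("7/7", "6/6")))
  D2 <- jaccard_binary_distance(tab2)
  expect_equal(D2[1, 2], sqrt(0.5))
  # raw dialect
  D2r <- jaccard_binary_distance(tab2, sqrt_transform = FALSE)
  expect_equal(D2r[1, 2], 0.5)

  # sample with no present alleles is an error
  tab3 <- toy_table(list(L1 = c("8/8", "NA/NA")))
  expect_error(jaccard_binary_distance(tab3), "no present alleles")
})

test_that("the square-root Jaccard matrix is Euclidean-embeddable", {
  sim <- simulate_population(sim_config(seed = 43, n_lineages = 12,
                                        lineage_abundances = rep(3L, 12),
                                        n_loci = 10))
  D <- jaccard_binary_distance(sim$table)
  fit <- pcoa(D, n_axes = 2)
  eig <- fit$eigenvalues
  expect_gte(min(eig), -1e-8 * max(eig))
})

test_that("PCoA reproduces forced geometries and round-trips distances", {
  # two points at distance d -> coordinates +/- d/2
  D <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  fit <- suppressWarnings(pcoa(D, n_axes = 1))
  expect_equal(sort(unname(fit$coords[, 1])), c(-1.5, 1.5))

  # 10 random points in the plane: distances recovered within 1e-8
  set.seed(8)
  pts <- matrix(runif(20), 10, 2)
  D10 <- as.matrix(stats::dist(pts))
  fit10 <- pcoa(D10, n_axes = 2)
  expect_equal(as.matrix(stats::dist(fit10$coords)), D10,
               tolerance = 1e-8, ignore_attr = TRUE)
  # requesting more axes than positive eigenvalues warns and truncates
  expect_warning(res <- pcoa(D10, n_axes = 9), "truncating")
  expect_lte(ncol(res$coords), 9)
})

test_that("PCoA separates simulated lineage clusters", {
  sim <- simulate_population(sim_config(seed = 47, n_lineages = 5,
                                        lineage_abundances = rep(20L, 5),
                                        n_loci = 20))
  D <- jaccard_binary_distance(sim$table)
  fit <- pcoa(D, n_axes = 2)
  # mean silhouette of the true lineage labelling on the first two axes
  co <- fit$coords
  lab <- sim$truth$lineage
  dmat <- as.matrix(stats::dist(co))
  sil <- vapply(seq_len(nrow(co)), function(i) {
    a <- mean(dmat[i, lab == lab[i] & seq_len(nrow(co)) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(dmat[i, lab == g]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("minimum spanning tree matches exhaustive enumeration on small graphs", {
  # 3 nodes, distances 0.1/0.2/0.3: tree = {0.1, 0.2}
  D3 <- matrix(0, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  D3["a", "b"] <- D3["b", "a"] <- 0.1
  D3["a", "c"] <- D3["c", "a"] <- 0.2
  D3["b", "c"] <- D3["c", "b"] <- 0.3
  msn <- build_msn(D3)
  expect_equal(msn$total_tree_weight, 0.3)
  expect_equal(sort(msn$edges$weight), c(0.1, 0.2))

  # random graphs up to 6 nodes vs brute force over all spanning trees
  set.seed(15)
  for (n in 4:6) {
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- runif(n * (n - 1) / 2)
    M <- M + t(M)
    got <- build_msn(M)$total_tree_weight
    # brute force: all (n-1)-edge subsets that span
    pairs <- which(upper.tri(M), arr.ind = TRUE)
    best <- Inf
    for (sub in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
      es <- pairs[sub, , drop = FALSE]
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      ok <- TRUE
      for (r in seq_len(nrow(es))) {
        ri <- find(es[r, 1]); rj <- find(es[r, 2])
        if (ri == rj) { ok <- FALSE; break }
        parent[ri] <- rj
      }
      if (ok) best <- min(best, sum(M[es]))
    }
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("tied alternative edges are retained in the network", {
  # equilateral triangle: all 3 edges kept
  D <- matrix(0.2, 3, 3); diag(D) <- 0
  dimnames(D) <- rep(list(c("m1", "m2", "m3")), 2)
  msn <- build_msn(D)
  expect_equal(nrow(msn$edges), 3)
  expect_equal(sum(msn$edges$in_tree), 2)
  expect_equal(msn$n_components, 1)
})

test_that("MSN hubs coincide with dominant simulated lineages", {
  sim <- simulate_population(sim_config(seed = 53, n_lineages = 5,
                                        lineage_abundances = c(40L, 30L, 20L, 15L, 10L),
                                        n_loci = 15))
  part <- assign_mlgs(sim$table)
  expect_equal(part$n_mlg, 5)
  cc <- clone_correct(sim$table, part)
  D <- bruvo_distance(cc)
  msn <- build_msn(D, abundances = stats::setNames(part$abundance, sample_ids(cc)))
  expect_equal(sort(msn$nodes$abundance, decreasing = TRUE),
               c(40L, 30L, 20L, 15L, 10L))
  # node ids map back to the true lineages via the representatives
  expect_equal(msn$nodes$id, part$representative)
})

test_that("cluster shares reproduce printed-percentage arithmetic", {
  mlg <- c(rep(1L, 112), rep(2L, 31), rep(3L, 39), rep(4L, 9))
  part <- list(mlg = mlg,
               abundance = stats::setNames(c(112L, 31L, 39L, 9L),
                                           c("MLG.58", "MLG.x", "MLG.16", "MLG.y")),
               samples = sprintf("S%03d", seq_along(mlg)))
  class(part) <- "mlg_partition"
  clusters <- c(rep("CL", 143), rep("BR", 48))
  sh <- cluster_share(part, clusters)
  expect_equal(sh$share_pct[sh$cluster == "CL"], 78.32)
  expect_equal(sh$share_pct[sh$cluster == "BR"], 81.25)
  expect_equal(sh$dominant_mlg, c("MLG.16", "MLG.58"))

  # single-MLG cluster is 100%
  sh1 <- cluster_share(part, rep("one", 191))
  expect_equal(sh1$share_pct, round(100 * 112 / 191, 2))
})
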