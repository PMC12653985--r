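test_that("locus statistics recover hand-computed heterozygosities", {
  # HWE case: 25 AA, 50 Aa, 25 aa
  tab <- toy_table(list(L1 = c(rep("8/8", 25), rep("8/9", 50), rep("9/9", 25))))
  st <- locus_stats(tab)
  expect_equal(st$h_obs, 0.5)
  expect_equal(st$h_exp, 0.5)
  expect_equal(st$f_is, 0)
  expect_equal(st$chisq, 0, tolerance = 1e-12)
  expect_equal(st$chisq_p, 1)

  # all heterozygotes: F_IS = -1
  st2 <- locus_stats(toy_table(list(L1 = rep("8/9", 40))))
  expect_equal(st2$h_obs, 1)
  expect_equal(st2$h_exp, 0.5)
  expect_equal(st2$f_is, -1)

  # monomorphic locus: flagged F_IS, no HWE test
  st3 <- locus_stats(toy_table(list(L1 = rep("8/8", 10))))
  expect_equal(st3$n_alleles, 1L)
  expect_equal(st3$h_exp, 0)
  expect_true(is.na(st3$f_is))
  expect_true(is.na(st3$chisq))
})

test_that("Nei F_ST responds to differentiation between groups", {
  # fixed for alternative alleles in two groups: F_ST = 1
  tab <- toy_table(list(L1 = c(rep("8/8", 10), rep("9/9", 10))))
  st <- locus_stats(tab, groups = rep(c("a", "b"), each = 10))
  expect_equal(st$f_st, 1)
  # identical groups: F_ST = 0
  tab2 <- toy_table(list(L1 = rep(c("8/8", "9/9"), 10)))
  st2 <- locus_stats(tab2, groups = rep(c("a", "b"), each = 10))
  expect_equal(st2$f_st, 0)
})

test_that("multiallelic HWE chi-squared matches the hand-worked example", {
  # 50 samples all Aa: chisq = 12.5 + 25 + 12.5 = 50, df = 1
  hw <- hwe_chisq(rep(8, 50), rep(9, 50))
  expect_equal(hw$chisq, 50)
  expect_equal(hw$df, 1)
  expect_equal(hw$p, stats::pchisq(50, 1, lower.tail = FALSE))
})

test_that("HWE chi-squared holds its nominal type-I error under the null", {
  set.seed(101)
  n <- 100
  rejections <- replicate(1000, {
    a <- sample(c(8, 9), 2 * n, replace = TRUE)       # panmictic pairing
    hwe_chisq(a[1:n], a[(n + 1):(2 * n)])$p < 0.05
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rejections) - 0.05), 4 * se)
})

test_that("Monte-Carlo exact HWE test behaves at both extremes and is seeded", {
  # conforming counts: observed statistic ~0, p large
  a1 <- c(rep(8, 25), rep(8, 50), rep(9, 25))
  a2 <- c(rep(8, 25), rep(9, 50), rep(9, 25))
  p_null <- hwe_exact_mc(a1, a2, B = 500, seed = 3)
  expect_gt(p_null, 0.5)
  # all-heterozygote table: extreme tail
  p_het <- hwe_exact_mc(rep(8, 60), rep(9, 60), B = 2000, seed = 3)
  expect_lte(p_het, 0.001)
  expect_identical(hwe_exact_mc(a1, a2, B = 200, seed = 7),
                   hwe_exact_mc(a1, a2, B = 200, seed = 7))
  # agreement with the chi-squared test on clear-cut fixtures
  expect_gt(hwe_chisq(a1, a2)$p, 0.05)
  expect_lt(hwe_chisq(rep(8, 60), rep(9, 60))$p, 0.05)
})

test_that("paired global HWE tests behave under null, shift and degeneracy", {
  set.seed(55)
  h_obs <- runif(45, 0.2, 0.8)
  null_stats <- data.frame(h_obs = h_obs, h_exp = h_obs + rnorm(45, 0, 0.05))
  gh <- paired_global_hwe(null_stats)
  expect_gt(gh$t_p, 0.05)
  expect_gt(gh$wilcoxon_p, 0.05)

  shift <- data.frame(h_obs = h_obs, h_exp = h_obs + 0.2)
  gs <- paired_global_hwe(shift)
  expect_lt(gs$t_p, 0.001)
  expect_lt(gs$wilcoxon_p, 0.001)

  ident <- data.frame(h_obs = h_obs, h_exp = h_obs)
  gd <- paired_global_hwe(ident)
  expect_true(gd$degenerate)
  expect_equal(gd$t_p, 1)
})

test_that("MLG assignment groups exact profiles and treats missing strictly", {
  tab <- toy_table(list(L1 = c("8/9", "8/9", "8/9", "NA/NA"),
                        L2 = c("7/7", "7/7", "7/8", "7/7")))
  part <- assign_mlgs(tab)
  expect_equal(part$n_mlg, 3)
  expect_equal(part$mlg, c(1L, 1L, 2L, 3L))       # missing is its own token
  expect_equal(unname(part$abundance), c(2L, 1L, 1L))
  expect_equal(part$representative, c("S01", "S03", "S04"))

  # contracted mode merges via mutually non-missing agreement
  partc <- assign_mlgs(tab, contract = TRUE)
  expect_equal(partc$mlg, c(1L, 1L, 2L, 1L))
})

test_that("clone correction keeps one representative per MLG, idempotently", {
  sim <- simulate_population(sim_config(seed = 17, n_lineages = 8,
                                        lineage_abundances = rep(3L, 8),
                                        n_loci = 10))
  part <- assign_mlgs(sim$table)
  cc <- clone_correct(sim$table, part)
  expect_equal(n_samples(cc), part$n_mlg)
  cc2 <- clone_correct(cc)
  expect_equal(sample_ids(cc2), sample_ids(cc))
  # all-unique table: identity
  uniq <- clone_correct(cc)
  expect_equal(n_samples(uniq), n_samples(cc))
  expect_error(clone_correct(cc, part), "not derived")
})

test_that("diversity indices match hand computation and vegan oracles", {
  di <- diversity_indices(c(2, 1, 1))
  expect_equal(di$H, 1.0397, tolerance = 1e-4)
  expect_equal(di$G, 2.6667, tolerance = 1e-4)
  expect_equal(di$lambda, 0.625)
  expect_equal(di$E5, 0.9116, tolerance = 1e-4)

  # independent oracle: vegan's Shannon and Simpson on the same abundances
  ab <- c(112, 39, 34, 28, 25, rep(1, 20))
  di2 <- diversity_indices(ab)
  expect_equal(di2$H, unname(vegan::diversity(ab, "shannon")))
  expect_equal(di2$lambda, unname(vegan::diversity(ab, "simpson")))
  expect_equal(di2$G, unname(vegan::diversity(ab, "invsimpson")))

  # degenerate single MLG
  d1 <- diversity_indices(5)
  expect_equal(d1$H, 0)
  expect_equal(d1$G, 1)
  expect_equal(d1$lambda, 0)
  expect_equal(d1$E5, 1)
  expect_error(diversity_indices(integer(0)), "empty")
})

test_that("uniform abundances give G = n_mlg and E5 = 1 exactly", {
  for (k in c(2, 10, 97)) {
    di <- diversity_indices(rep(3L, k))
    expect_equal(di$G, k)
    expect_equal(di$E5, 1)
    expect_equal(di$H, log(k))
    expect_equal(di$lambda + 1 / di$G, 1)    # lambda + sum(p^2) = 1
  }
  # H <= ln(n_mlg) with equality iff uniform
  expect_lt(diversity_indices(c(5, 1, 1))$H, log(3))
})

test_that("rbarD equals a brute-force evaluation on a 4x2 toy table", {
  tab <- toy_table(list(L1 = c("8/8", "8/9", "9/9", "8/9"),
                        L2 = c("7/7", "7/8", "8/8", "7/7")))
  # brute force over all 6 sample pairs
  pairs <- utils::combn(4, 2)
  dmat <- sapply(1:2, function(j) {
    apply(pairs, 2, function(ik) {
      g1 <- c(tab$a1[ik[1], j], tab$a2[ik[1], j])
      g2 <- c(tab$a1[ik[2], j], tab$a2[ik[2], j])
      min((g1[1] != g2[1]) + (g1[2] != g2[2]),
          (g1[1] != g2[2]) + (g1[2] != g2[1]))
    })
  })
  D <- rowSums(dmat)
  V_O <- stats::var(D)
  vars <- apply(dmat, 2, stats::var)
  V_E <- sum(vars)
  want <- (V_O - V_E) / (2 * sqrt(vars[1] * vars[2]))
  got <- ia_rbarD(tab, n_perm = 0)
  expect_equal(got$rbarD, want)
  expect_equal(got$Ia, V_O / V_E - 1)
})

test_that("perfectly duplicated loci give rbarD = 1", {
  g <- c("8/8", "8/9", "9/9", "8/9", "8/8", "9/9")
  tab <- toy_table(list(L1 = g, L2 = g))
  expect_equal(ia_rbarD(tab, n_perm = 0)$rbarD, 1)
})

test_that("rbarD is invariant under allele relabelling and sample order", {
  set.seed(77)
  sim <- simulate_population(sim_config(seed = 19, n_lineages = 6,
                                        lineage_abundances = rep(5L, 6),
                                        n_loci = 6))
  base <- ia_rbarD(sim$table, n_perm = 0)$rbarD
  # relabel alleles (affine map preserves identity structure)
  rel <- sim$table
  rel$a1 <- rel$a1 * 3 + 100; rel$a2 <- rel$a2 * 3 + 100
  expect_equal(ia_rbarD(rel, n_perm = 0)$rbarD, base)
  # permute samples
  perm <- sample(n_samples(sim$table))
  shuf <- subset_table(sim$table, samples = perm)
  expect_equal(ia_rbarD(shuf, n_perm = 0)$rbarD, base)
  # permute loci
  shufl <- subset_table(sim$table, loci = sample(n_loci(sim$table)))
  expect_equal(ia_rbarD(shufl, n_perm = 0)$rbarD, base)
})

test_that("rbarD separates panmictic from clonal populations", {
  # panmictic: every sample an independent random union of gametes
  set.seed(23)
  n <- 120; L <- 8
  a1 <- a2 <- matrix(0, n, L)
  for (j in seq_len(L)) {
    pool <- sample(6:11, 2 * n, replace = TRUE)
    a1[, j] <- pmin(pool[1:n], pool[(n + 1):(2 * n)])
    a2[, j] <- pmax(pool[1:n], pool[(n + 1):(2 * n)])
  }
  pan <- genotype_table(a1, a2, data.frame(sample = sprintf("P%03d", 1:n)),
                        toy_panel(sprintf("L%d", 1:L)))
  res_pan <- ia_rbarD(pan, n_perm = 199, seed = 5)
  perm_sd <- stats::sd(res_pan$perm_values)
  expect_lt(abs(res_pan$rbarD), 3 * perm_sd)
  expect_gt(res_pan$p, 0.05)

  # clonal: few lineages, many copies
  sim <- simulate_population(sim_config(seed = 29, n_lineages = 8,
                                        lineage_abundances = rep(15L, 8),
                                        n_loci = 8))
  res_clone <- ia_rbarD(sim$table, n_perm = 199, seed = 5)
  expect_gt(res_clone$rbarD, 0)
  expect_lt(res_clone$p, 0.05)

  # clone correction reduces the association signal
  res_cc <- ia_rbarD(sim$table, n_perm = 0, clone_corrected = TRUE)
  expect_lt(res_cc$rbarD, res_clone$rbarD)
})

test_that("pairwise rbarD matrix is symmetric with unit diagonal", {
  sim <- simulate_population(sim_config(seed = 37, n_lineages = 10,
                                        lineage_abundances = rep(4L, 10),
                                        n_loci = 5))
  res <- ia_rbarD(sim$table, n_perm = 0, pairwise = TRUE)
  pw <- res$pairwise
  expect_true(isSymmetric(pw))
  expect_equal(unname(diag(pw)), rep(1, 5))
  expect_equal(nrow(pw), 5)
})
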