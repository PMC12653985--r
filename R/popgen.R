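#' Per-locus descriptive statistics
#'
#' For each locus: number of alleles (`n_alleles`), observed heterozygosity
#' `h_obs` (fraction of heterozygotes among non-missing genotypes), expected
#' heterozygosity (gene diversity) `h_exp = 1 - sum(p^2)`, their difference
#' `h_delta`, the inbreeding coefficient `f_is = 1 - h_obs / h_exp`
#' (negative under heterozygote excess, the clonal signature), and HWE tests
#' (chi-squared and, optionally, a Monte-Carlo exact test). When `groups` is
#' supplied, a Nei-style `f_st = (h_t - h_s) / h_t` is added, with `h_s` the
#' unweighted mean within-group gene diversity and `h_t` the gene diversity
#' of the unweighted mean allele frequencies.
#'
#' `h_exp` is the plain `1 - sum(p^2)`; set `unbiased = TRUE` for the
#' small-sample `n/(n-1)` correction.
#'
#' @param x A `genotype_table`.
#' @param groups Optional per-sample group labels (for `f_st`).
#' @param hwe_mc Number of Monte-Carlo permutations for the exact HWE test
#'   (0 to skip).
#' @param seed Seed for the Monte-Carlo test.
#' @param unbiased Apply the `n/(n-1)` correction to `h_exp`.
#' @return Data frame of class `locus_stats`, one row per locus. Loci with
#'   no data are flagged (`defined = FALSE`) and carry `NA` statistics;
#'   `f_is` is `NA` when `h_exp = 0`.
#' @export
locus_stats <- function(x, groups = NULL, hwe_mc = 0L, seed = 1L,
                        unbiased = FALSE) {
  L <- n_loci(x)
  out <- data.frame(
    locus = locus_names(x), n = 0L, n_alleles = NA_integer_,
    h_obs = NA_real_, h_exp = NA_real_, h_delta = NA_real_, f_is = NA_real_,
    chisq = NA_real_, chisq_df = NA_integer_, chisq_p = NA_real_,
    defined = FALSE, stringsAsFactors = FALSE
  )
  if (hwe_mc > 0L) out$exact_p <- NA_real_
  if (!is.null(groups)) {
    stopifnot(length(groups) == n_samples(x))
    out$f_st <- NA_real_
  }
  for (j in seq_len(L)) {
    a1 <- x$a1[, j]; a2 <- x$a2[, j]
    ok <- !is.na(a1) & !is.na(a2)
    if (!any(ok)) next
    a1 <- a1[ok]; a2 <- a2[ok]
    tab <- base::table(c(a1, a2))
    p <- as.numeric(tab) / sum(tab)
    n <- sum(ok)
    h_exp <- 1 - sum(p^2)
    if (unbiased && n > 1) h_exp <- h_exp * (2 * n) / (2 * n - 1)
    h_obs <- mean(a1 != a2)
    out$n[j] <- n
    out$n_alleles[j] <- length(p)
    out$h_obs[j] <- h_obs
    out$h_exp[j] <- h_exp
    out$h_delta[j] <- h_exp - h_obs
    out$f_is[j] <- if (h_exp > 0) 1 - h_obs / h_exp else NA_real_
    out$defined[j] <- TRUE
    if (length(p) >= 2) {
      hw <- hwe_chisq(a1, a2)
      out$chisq[j] <- hw$chisq; out$chisq_df[j] <- hw$df; out$chisq_p[j] <- hw$p
      if (hwe_mc > 0L) out$exact_p[j] <- hwe_exact_mc(a1, a2, B = hwe_mc,
                                                      seed = seed + j)
    }
    if (!is.null(groups)) {
      g <- groups[ok]
      freq_by_g <- lapply(split(seq_along(g), g), function(i) {
        t2 <- base::table(factor(c(a1[i], a2[i]), levels = names(tab)))
        as.numeric(t2) / sum(t2)
      })
      freq_by_g <- freq_by_g[vapply(freq_by_g, function(q) !anyNA(q), TRUE)]
      if (length(freq_by_g) >= 2) {
        h_s <- mean(vapply(freq_by_g, function(q) 1 - sum(q^2), 0))
        pbar <- Reduce(`+`, freq_by_g) / length(freq_by_g)
        h_t <- 1 - sum(pbar^2)
        out$f_st[j] <- if (h_t > 0) (h_t - h_s) / h_t else NA_real_
      }
    }
  }
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' Chi-squared test of Hardy-Weinberg equilibrium (multiallelic)
#'
#' Expected genotype counts are `n p_a^2` for homozygotes and `2 n p_a p_b`
#' for heterozygotes, from the observed allele frequencies; the statistic
#' sums `(O - E)^2 / E` over all k(k+1)/2 genotype categories with
#' `df = k(k-1)/2`.
#'
#' @param a1,a2 Non-missing allele vectors of a locus's genotypes.
#' @return List with `chisq`, `df`, `p`; `NA`s when the locus is
#'   monomorphic (test undefined).
#' @export
hwe_chisq <- function(a1, a2) {
  stopifnot(length(a1) == length(a2), !anyNA(a1), !anyNA(a2))
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2) return(list(chisq = NA_real_, df = NA_integer_, p = NA_real_))
  n <- length(a1)
  tab <- base::table(factor(c(a1, a2), levels = alleles))
  p <- as.numeric(tab) / (2 * n)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  obs <- matrix(0, k, k)
  for (g in seq_len(n)) obs[lo[g], hi[g]] <- obs[lo[g], hi[g]] + 1
  chisq <- 0
  for (a in seq_len(k)) {
    for (b in a:k) {
      e <- if (a == b) n * p[a]^2 else 2 * n * p[a] * p[b]
      if (e > 0) chisq <- chisq + (obs[a, b] - e)^2 / e
    }
  }
  df <- k * (k - 1) / 2
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Pools the 2n observed alleles and re-pairs them at random `B` times;
#' the p-value is `(1 + #{simulated chi-squared >= observed}) / (B + 1)`.
#' Allele frequencies (hence expected counts) are invariant under
#' re-pairing, so only the genotype configuration is resampled.
#'
#' @param a1,a2 Non-missing allele vectors.
#' @param B Number of permutations (default 10000).
#' @param seed Seed (reproducible).
#' @return Permutation p-value (never exactly 0).
#' @export
hwe_exact_mc <- function(a1, a2, B = 10000L, seed = 1L) {
  stopifnot(B >= 1)
  obs <- hwe_chisq(a1, a2)$chisq
  if (is.na(obs)) return(NA_real_)
  pool <- c(a1, a2)
  n <- length(a1)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- pool[sample.int(2 * n)]
    s <- hwe_chisq(perm[seq_len(n)], perm[seq.int(n + 1L, 2L * n)])$chisq
    if (s >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

#' Global (panel-wide) paired tests of Hardy-Weinberg equilibrium
#'
#' Tests whether expected and observed heterozygosity differ systematically
#' across loci: a paired t-test and a Wilcoxon signed-rank test on the
#' per-locus differences `h_exp - h_obs` (zero differences discarded for
#' Wilcoxon), plus a Shapiro-Wilk normality check on the differences.
#'
#' @param stats A `locus_stats` data frame (or any data frame with `h_exp`,
#'   `h_obs`).
#' @return List with `t_p`, `wilcoxon_p`, `shapiro_p`, the mean difference,
#'   and `degenerate = TRUE` (with `t_p = 1`) when all differences are zero.
#' @export
paired_global_hwe <- function(stats) {
  ok <- !is.na(stats$h_exp) & !is.na(stats$h_obs)
  d <- stats$h_exp[ok] - stats$h_obs[ok]
  if (length(d) < 3) stop("need at least 3 loci with defined heterozygosities")
  if (all(d == 0)) {
    return(list(t_p = 1, wilcoxon_p = NA_real_, shapiro_p = NA_real_,
                mean_delta = 0, degenerate = TRUE))
  }
  # constant differences (up to fp noise) carry no within-sample variance:
  # the paired t-test degenerates, so report the floor p-value directly
  t_p <- if (stats::sd(d) < 1e-10 * max(abs(d))) {
    .Machine$double.eps
  } else {
    stats::t.test(d)$p.value
  }
  dn0 <- d[d != 0]
  w_p <- if (length(dn0)) {
    suppressWarnings(stats::wilcox.test(dn0)$p.value)
  } else NA_real_
  s_p <- if (length(unique(d)) > 2) stats::shapiro.test(d)$p.value else NA_real_
  list(t_p = t_p, wilcoxon_p = w_p, shapiro_p = s_p, mean_delta = mean(d),
       degenerate = FALSE)
}

# ---- multilocus genotypes ---------------------------------------------------

#' Assign multilocus genotypes (MLGs)
#'
#' Groups samples by exact equality of the full multilocus profile. Missing
#' genotypes count as their own token, so two samples must agree on
#' missingness as well as on alleles — a strict, order-independent rule.
#' `contract = TRUE` instead merges samples whose profiles agree on all
#' mutually non-missing loci (single-linkage over that relation); this is
#' more tolerant of dropouts but can chain distinct genotypes together.
#'
#' @param x A `genotype_table`.
#' @param contract Use the contracted (missing-tolerant) matching rule.
#' @return List of class `mlg_partition`: `mlg` (integer id per sample, in
#'   order of first appearance), `abundance` (named vector per MLG),
#'   `representative` (first sample of each MLG), `n_mlg`.
#' @export
assign_mlgs <- function(x, contract = FALSE) {
  key <- apply(cbind(x$a1, x$a2), 1, function(r) {
    paste(ifelse(is.na(r), ".", format(r, trim = TRUE)), collapse = "|")
  })
  ids <- match(key, unique(key))
  if (contract) {
    n <- n_samples(x)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n - 1)) {
      for (k in seq.int(i + 1, n)) {
        both <- !is.na(x$a1[i, ]) & !is.na(x$a1[k, ])
        if (any(both) &&
            all(x$a1[i, both] == x$a1[k, both]) &&
            all(x$a2[i, both] == x$a2[k, both], na.rm = TRUE)) {
          ri <- find(i); rk <- find(k)
          if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
        }
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    ids <- match(roots, unique(roots))
  }
  ab <- base::table(ids)
  mlg_names <- sprintf("MLG.%d", seq_len(max(ids)))
  abundance <- as.integer(ab[as.character(seq_len(max(ids)))])
  names(abundance) <- mlg_names
  representative <- sample_ids(x)[match(seq_len(max(ids)), ids)]
  structure(list(mlg = ids, abundance = abundance,
                 representative = representative, n_mlg = max(ids),
                 samples = sample_ids(x)),
            class = "mlg_partition")
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat(sprintf("%d MLGs among %d samples (MLG/N = %.2f)\n",
              x$n_mlg, length(x$mlg), x$n_mlg / length(x$mlg)))
  top <- sort(x$abundance, decreasing = TRUE)[seq_len(min(5, x$n_mlg))]
  cat("  top MLG abundances:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Clone-correct a genotype table
#'
#' Keeps one representative sample (the first in input order) per MLG.
#' Idempotent: re-correcting a corrected table changes nothing.
#'
#' @param x A `genotype_table`.
#' @param partition An `mlg_partition` derived from `x` (default computed).
#' @return The clone-corrected `genotype_table`.
#' @export
clone_correct <- function(x, partition = assign_mlgs(x)) {
  if (!identical(partition$samples, sample_ids(x))) {
    stop("partition was not derived from this table")
  }
  subset_table(x, samples = partition$representative)
}

#' Clonal diversity indices of an MLG abundance distribution
#'
#' With `p_i` the relative abundance of MLG `i`: Shannon-Weaver
#' `H = -sum(p log p)` (nats), Stoddart-Taylor `G = 1 / sum(p^2)`, Simpson
#' `lambda = 1 - sum(p^2)`, and evenness `E5 = (G - 1) / (exp(H) - 1)`.
#' `G = n_mlg` and `E5 = 1` exactly when abundances are uniform; for a
#' single MLG `E5` is 1 by the limit convention.
#'
#' @param abundances Positive integer vector of MLG abundances (or an
#'   `mlg_partition`).
#' @return List of class `diversity_indices` with `H`, `G`, `lambda`, `E5`,
#'   `n_mlg`, `n`.
#' @export
diversity_indices <- function(abundances) {
  if (inherits(abundances, "mlg_partition")) abundances <- abundances$abundance
  if (length(abundances) == 0L) stop("empty abundance vector")
  if (any(abundances <= 0)) stop("abundances must be positive")
  p <- abundances / sum(abundances)
  H <- -sum(p * log(p))
  sp2 <- sum(p^2)
  G <- 1 / sp2
  E5 <- if (length(p) == 1L) 1 else (G - 1) / (exp(H) - 1)
  structure(list(H = H, G = G, lambda = 1 - sp2, E5 = E5,
                 n_mlg = length(p), n = sum(abundances)),
            class = "diversity_indices")
}

#' @export
print.diversity_indices <- function(x, ...) {
  cat(sprintf("H = %.2f  G = %.2f  lambda = %.3f  E5 = %.3f  (%d MLGs, n = %d)\n",
              x$H, x$G, x$lambda, x$E5, x$n_mlg, x$n))
  invisible(x)
}

# ---- index of association ---------------------------------------------------

# per-locus pairwise distance vectors: d[pair] = multiset allele differences
# (0, 1, 2) between the two genotypes; NA when either genotype is missing
pairwise_locus_distances <- function(x) {
  n <- n_samples(x)
  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]; k <- pairs[2, ]
  lapply(seq_len(n_loci(x)), function(j) {
    a1 <- x$a1[, j]; a2 <- x$a2[, j]
    direct <- (a1[i] != a1[k]) + (a2[i] != a2[k])
    crossed <- (a1[i] != a2[k]) + (a2[i] != a1[k])
    d <- pmin(direct, crossed)
    d[is.na(a1[i]) | is.na(a1[k]) | is.na(a2[i]) | is.na(a2[k])] <- NA
    d
  })
}

rbard_from_distances <- function(dlist) {
  # complete-pair analysis: drop pairs with any NA so variances share a basis
  keep <- Reduce(`&`, lapply(dlist, function(d) !is.na(d)))
  dmat <- vapply(dlist, function(d) d[keep], numeric(sum(keep)))
  vars <- apply(dmat, 2, stats::var)
  nz <- which(vars > 0)
  if (length(nz) < 2 || sum(keep) < 2) {
    return(list(Ia = NA_real_, rbarD = NA_real_, excluded = which(vars == 0)))
  }
  dmat <- dmat[, nz, drop = FALSE]
  vars <- vars[nz]
  D <- rowSums(dmat)
  V_O <- stats::var(D)
  V_E <- sum(vars)
  cv <- stats::cov(dmat)
  denom <- 0
  m <- length(vars)
  for (j in seq_len(m - 1)) {
    for (k in seq.int(j + 1, m)) denom <- denom + sqrt(vars[j] * vars[k])
  }
  list(Ia = V_O / V_E - 1,
       rbarD = (V_O - V_E) / (2 * denom),
       excluded = setdiff(seq_along(dlist), nz),
       cov = cv, vars = vars, kept_loci = nz)
}

#' Index of association and standardized r-bar-D
#'
#' Multilocus linkage-disequilibrium statistics for (partially) clonal
#' populations. For every sample pair and locus, the distance is the number
#' of allele differences between the two genotypes' multisets (0, 1 or 2);
#' with `D` the per-pair sum over loci, `V_O = var(D)`, and
#' `V_E = sum(var_j)`, then `I_A = V_O / V_E - 1` and
#' `rbarD = (V_O - V_E) / (2 sum_{j<k} sqrt(var_j var_k))`. Under free
#' recombination rbarD is near 0; clonal propagation drives it up, and
#' clone correction is expected to reduce it. Zero-variance loci are
#' excluded (flagged); pairs with a missing genotype at any analysed locus
#' are dropped so all variances share one pair basis.
#'
#' The permutation test shuffles genotype columns independently per locus
#' (breaking between-locus association, preserving per-locus composition);
#' `p = (1 + #{perm rbarD >= observed}) / (n_perm + 1)`.
#'
#' @param x A `genotype_table`.
#' @param n_perm Number of permutations (default 999; 0 skips the test).
#' @param seed Seed for permutations.
#' @param clone_corrected Analyse the clone-corrected table instead.
#' @param pairwise Also compute the per-locus-pair rbarD matrix.
#' @return List of class `association_stats`: `Ia`, `rbarD`, `p`,
#'   `n_perm`, `excluded_loci`, and (if requested) `pairwise`, a symmetric
#'   matrix of two-locus rbarD values.
#' @export
ia_rbarD <- function(x, n_perm = 999L, seed = 1L, clone_corrected = FALSE,
                     pairwise = FALSE) {
  if (n_loci(x) < 2 || n_samples(x) < 3) stop("need >= 2 loci and >= 3 samples")
  if (clone_corrected) x <- clone_correct(x)
  dlist <- pairwise_locus_distances(x)
  obs <- rbard_from_distances(dlist)
  pw <- NULL
  if (pairwise && length(obs$kept_loci) >= 2) {
    m <- length(dlist)
    pw <- matrix(NA_real_, m, m, dimnames = list(locus_names(x), locus_names(x)))
    diag(pw) <- 1
    cv <- obs$cov; vars <- obs$vars; kl <- obs$kept_loci
    for (aj in seq_along(kl)) {
      for (bk in seq_along(kl)) {
        if (aj < bk) {
          v <- cv[aj, bk] / sqrt(vars[aj] * vars[bk])
          pw[kl[aj], kl[bk]] <- pw[kl[bk], kl[aj]] <- v
        }
      }
    }
  }
  p <- NA_real_
  perm_vals <- NULL
  if (n_perm > 0L && !is.na(obs$rbarD)) {
    set.seed(seed)
    n <- n_samples(x)
    perm_vals <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      xp <- x
      for (j in seq_len(n_loci(x))) {
        o <- sample.int(n)
        xp$a1[, j] <- x$a1[o, j]
        xp$a2[, j] <- x$a2[o, j]
      }
      perm_vals[b] <- rbard_from_distances(pairwise_locus_distances(xp))$rbarD
    }
    p <- (1 + sum(perm_vals >= obs$rbarD, na.rm = TRUE)) / (n_perm + 1)
  }
  structure(list(Ia = obs$Ia, rbarD = obs$rbarD, p = p, n_perm = n_perm,
                 excluded_loci = locus_names(x)[obs$excluded],
                 pairwise = pw, perm_values = perm_vals),
            class = "association_stats")
}

#' @export
print.association_stats <- function(x, ...) {
  cat(sprintf("I_A = %.3f  rbarD = %.3f", x$Ia, x$rbarD))
  if (!is.na(x$p)) cat(sprintf("  p = %.3g (%d permutations)", x$p, x$n_perm))
  cat("\n")
  if (length(x$excluded_loci)) {
    cat("  zero-variance loci excluded:", paste(x$excluded_loci, collapse = ", "), "\n")
  }
  invisible(x)
}
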