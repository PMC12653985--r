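#' Missing-data profile of a genotype table
#'
#' @param x A `genotype_table`.
#' @return List of class `missing_report`: `per_marker` (missing samples at
#'   each marker / n samples), `per_sample` (missing markers in each sample /
#'   n markers), and their means and medians.
#' @export
missing_report <- function(x) {
  if (n_samples(x) == 0L || n_loci(x) == 0L) stop("empty genotype table")
  miss <- is_missing_geno(x)
  per_marker <- colMeans(miss)
  per_sample <- rowMeans(miss)
  structure(list(
    per_marker = per_marker, per_sample = per_sample,
    marker_mean = mean(per_marker), marker_median = stats::median(per_marker),
    sample_mean = mean(per_sample), sample_median = stats::median(per_sample)
  ), class = "missing_report")
}

#' @export
print.missing_report <- function(x, ...) {
  cat(sprintf("missing per marker: mean %.1f%% median %.1f%% range %.1f-%.1f%%\n",
              100 * x$marker_mean, 100 * x$marker_median,
              100 * min(x$per_marker), 100 * max(x$per_marker)))
  cat(sprintf("missing per sample: mean %.1f%% median %.1f%% range %.1f-%.1f%%\n",
              100 * x$sample_mean, 100 * x$sample_median,
              100 * min(x$per_sample), 100 * max(x$per_sample)))
  invisible(x)
}

#' Drop samples with too many missing markers
#'
#' Retains samples with at most `max_missing_markers` missing loci on the
#' current panel (the comparison is "no more than", i.e. a sample missing
#' exactly the threshold is kept).
#'
#' @param x A `genotype_table`.
#' @param max_missing_markers Maximum tolerated missing loci per sample.
#' @return List with `table` (filtered) and `removed`, a data frame of
#'   removed sample ids with their missing-marker counts.
#' @export
filter_samples_by_missing <- function(x, max_missing_markers = 4L) {
  stopifnot(max_missing_markers >= 0)
  n_miss <- rowSums(is_missing_geno(x))
  drop <- n_miss > max_missing_markers
  removed <- data.frame(sample = sample_ids(x)[drop],
                        n_missing = n_miss[drop], row.names = NULL)
  list(table = subset_table(x, samples = !drop), removed = removed)
}

#' Replicate-based genotyping error rates
#'
#' Computes the three Taberlet-style error metrics from paired
#' reference/replicate profiles. Per locus, only pairs with both genotypes
#' non-missing are compared; alleles are matched as multisets (so
#' `{120,123}` vs `{123,120}` is concordant). `e_a` = mismatched alleles /
#' compared alleles (2 per compared genotype), `e_l` = discordant genotype
#' pairs / compared pairs, and `e_obs` = replicate pairs with at least one
#' discordant compared locus / total pairs.
#'
#' @param reps A `replicate_set`.
#' @return List of class `error_report`: per-locus data frame (`e_a`, `e_l`,
#'   with mismatch and comparison counts retained for audit), panel means
#'   and medians over loci with at least one compared pair, `e_obs`, and the
#'   locus ranking by `e_l`.
#' @export
error_rates <- function(reps) {
  ref <- reps$ref; rp <- reps$rep
  n <- n_samples(ref); L <- n_loci(ref)
  allele_mismatches <- function(r1, r2, q1, q2) {
    # multiset distance between diploid genotypes {r1,r2} and {q1,q2}: 0,1,2
    direct <- (r1 != q1) + (r2 != q2)
    crossed <- (r1 != q2) + (r2 != q1)
    pmin(direct, crossed)
  }
  per <- data.frame(locus = locus_names(ref), compared_pairs = 0L,
                    mismatch_genotypes = 0L, compared_alleles = 0L,
                    mismatch_alleles = 0L, e_a = NA_real_, e_l = NA_real_)
  disc_any <- rep(FALSE, n)
  for (j in seq_len(L)) {
    ok <- !is.na(ref$a1[, j]) & !is.na(rp$a1[, j]) &
          !is.na(ref$a2[, j]) & !is.na(rp$a2[, j])
    if (!any(ok)) next
    mm <- allele_mismatches(ref$a1[ok, j], ref$a2[ok, j],
                            rp$a1[ok, j], rp$a2[ok, j])
    per$compared_pairs[j] <- sum(ok)
    per$compared_alleles[j] <- 2L * sum(ok)
    per$mismatch_alleles[j] <- sum(mm)
    per$mismatch_genotypes[j] <- sum(mm > 0)
    per$e_a[j] <- sum(mm) / (2 * sum(ok))
    per$e_l[j] <- mean(mm > 0)
    disc_any[ok][mm > 0] <- TRUE
  }
  defined <- per$compared_pairs > 0L
  structure(list(
    per_locus = per,
    e_a_mean = mean(per$e_a[defined]), e_a_median = stats::median(per$e_a[defined]),
    e_l_mean = mean(per$e_l[defined]), e_l_median = stats::median(per$e_l[defined]),
    e_obs = mean(disc_any), n_pairs = n,
    n_discordant_pairs = sum(disc_any),
    undefined_loci = per$locus[!defined],
    ranking = per$locus[order(per$e_l, decreasing = TRUE, na.last = TRUE)]
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("e_a mean %.2f%% (median %.2f%%), e_l mean %.2f%% (median %.2f%%)\n",
              100 * x$e_a_mean, 100 * x$e_a_median,
              100 * x$e_l_mean, 100 * x$e_l_median))
  cat(sprintf("e_obs %.2f%% (%d of %d replicate pairs discordant)\n",
              100 * x$e_obs, x$n_discordant_pairs, x$n_pairs))
  invisible(x)
}

#' Stepwise exclusion of error-prone loci
#'
#' Recomputes the full error report after each successive exclusion from
#' `loci_to_drop` (an ordered list, chosen by the analyst — typically from
#' the `ranking` field of [error_rates()]; nothing is dropped
#' automatically). `e_obs` is monotone non-increasing along the sequence.
#'
#' @param reps A `replicate_set`.
#' @param loci_to_drop Character vector of locus names, in exclusion order.
#' @return List of `error_report`s: the initial report, then one per
#'   exclusion step, named by the locus just dropped.
#' @export
stepwise_exclude_error_prone <- function(reps, loci_to_drop) {
  stopifnot(all(loci_to_drop %in% locus_names(reps$ref)))
  out <- list(initial = error_rates(reps))
  keep <- locus_names(reps$ref)
  for (loc in loci_to_drop) {
    keep <- setdiff(keep, loc)
    sub <- replicate_set(subset_table(reps$ref, loci = keep),
                         subset_table(reps$rep, loci = keep))
    out[[loc]] <- error_rates(sub)
  }
  out
}

#' Per-locus allele frequencies
#'
#' @param x A `genotype_table`.
#' @return Named list (per locus) of named frequency vectors computed from
#'   non-missing calls; half-missing genotypes contribute their single
#'   allele.
#' @export
allele_freqs <- function(x) {
  out <- vector("list", n_loci(x))
  names(out) <- locus_names(x)
  for (j in seq_len(n_loci(x))) {
    v <- c(x$a1[, j], x$a2[, j]); v <- v[!is.na(v)]
    if (!length(v)) { out[[j]] <- numeric(0); next }
    tab <- base::table(v)
    out[[j]] <- as.numeric(tab) / sum(tab)
    names(out[[j]]) <- names(tab)
  }
  out
}

#' Remove loci below a minor-allele-frequency threshold
#'
#' MAF is the frequency of the second most common allele, from non-missing
#' calls. The comparison is strict: a locus is removed only when its MAF is
#' below `threshold`; monomorphic loci (MAF 0) are always removed.
#'
#' @param x A `genotype_table`.
#' @param threshold MAF threshold in `(0, 0.5)` (default 0.01).
#' @return List with `table` (filtered), `removed` (locus names) and `maf`
#'   (named vector over the input panel).
#' @export
maf_filter <- function(x, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 0.5)
  fr <- allele_freqs(x)
  maf <- vapply(fr, function(p) {
    if (length(p) < 2L) 0 else sort(p, decreasing = TRUE)[2L]
  }, 0)
  drop <- maf < threshold
  list(table = subset_table(x, loci = !drop),
       removed = locus_names(x)[drop], maf = maf)
}
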