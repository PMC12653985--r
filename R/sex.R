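#' Infer sex from X-linked homozygosity
#'
#' Aphid males are hemizygous (X0), so every X-linked marker reads as a
#' homozygote; females (XX) are expected to be heterozygous at some X loci.
#' A sample is called `male-consistent` when it is homozygous at every typed
#' X-linked locus and at least `min_typed` X loci are typed; `undetermined`
#' when fewer are typed; otherwise `female`. The minimum-typed guard exists
#' because a handful of homozygous loci is weak evidence; heterozygote
#' dropout additionally inflates homozygosity, so calls on samples that
#' failed QC should be treated with caution.
#'
#' @param x A `genotype_table`.
#' @param x_loci Character vector of X-linked locus names (default: the
#'   panel's `x_linked` flags).
#' @param min_typed Minimum typed X loci for a confident call (default 6).
#' @return List of class `sex_report`: per-sample data frame (`sample`,
#'   `n_typed`, `n_homozygous`, `call`), the homozygous-count distribution,
#'   and summary counts per call.
#' @export
infer_sex <- function(x, x_loci = locus_names(x)[x$panel$x_linked],
                      min_typed = 6L) {
  if (length(x_loci) == 0L) stop("no X-linked loci in panel")
  if (!all(x_loci %in% locus_names(x))) stop("x_loci not all present in panel")
  xs <- subset_table(x, loci = x_loci)
  typed <- !is_missing_geno(xs) & !is_half_missing(xs)
  hom <- typed & (xs$a1 == xs$a2)
  n_typed <- rowSums(typed)
  n_hom <- rowSums(hom, na.rm = TRUE)
  call <- ifelse(n_typed < min_typed, "undetermined",
                 ifelse(n_hom == n_typed, "male-consistent", "female"))
  per_sample <- data.frame(sample = sample_ids(x), n_typed = n_typed,
                           n_homozygous = n_hom, call = call,
                           row.names = NULL)
  structure(list(
    per_sample = per_sample,
    hom_distribution = base::table(factor(n_hom, levels = 0:length(x_loci))),
    n_female = sum(call == "female"),
    n_male_consistent = sum(call == "male-consistent"),
    n_undetermined = sum(call == "undetermined"),
    x_loci = x_loci, min_typed = min_typed
  ), class = "sex_report")
}

#' @export
print.sex_report <- function(x, ...) {
  cat(sprintf("sex calls over %d X-linked loci (min %d typed):\n",
              length(x$x_loci), x$min_typed))
  cat(sprintf("  female %d, male-consistent %d, undetermined %d\n",
              x$n_female, x$n_male_consistent, x$n_undetermined))
  cat(sprintf("  homozygous X loci per sample: mean %.1f, range %d-%d\n",
              mean(x$per_sample$n_homozygous),
              min(x$per_sample$n_homozygous), max(x$per_sample$n_homozygous)))
  invisible(x)
}

#' Probability a random-mating female is homozygous at all X loci
#'
#' The false-male probability of the hemizygosity rule under panmixia: the
#' product over X loci of the expected homozygosity `sum(p^2)`. Monomorphic
#' loci contribute a factor of 1. Under clonal propagation genotypes are
#' correlated across loci, so this product is an optimistic (lower) bound on
#' the real false-male rate.
#'
#' @param freqs Named list of per-locus allele frequency vectors (e.g. from
#'   [allele_freqs()]); each vector is renormalised to sum to 1.
#' @param x_loci Names of the X-linked loci to use.
#' @return A single probability.
#' @export
female_false_male_prob <- function(freqs, x_loci = names(freqs)) {
  if (!all(x_loci %in% names(freqs))) stop("x_loci not all present in freqs")
  prod(vapply(freqs[x_loci], function(p) {
    if (length(p) == 0L) return(1)
    p <- p / sum(p)
    sum(p^2)
  }, 0))
}
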