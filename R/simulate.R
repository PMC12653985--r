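#' Configuration for the clonal-population simulator
#'
#' Defines the study conditions the generator emulates: a field sample of a
#' cyclically parthenogenetic aphid population founded by a modest number of
#' clonal lineages (fundatrices), sampled at two localities over one growing
#' season. Defaults mirror the reference study design: 97 lineages and 365
#' samples, with the five dominant lineages at abundances 112, 39, 34, 28 and
#' 25 and the remaining 127 samples spread over 92 minor lineages by a
#' geometric-decay scheme; 45 autosomal-and-X loci with 2-8 alleles each.
#' Noise channels (stepwise mutation, heterozygote dropout, allele miscall,
#' missing data, X0 males) default to zero and are switched on explicitly.
#'
#' @param seed Integer seed; every stochastic draw descends from it.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Integer range (length 2) of allele counts per
#'   locus, sampled uniformly.
#' @param allele_freq_prior Dirichlet concentration for per-locus founder
#'   allele frequencies.
#' @param n_lineages Number of founder lineages.
#' @param lineage_abundances Explicit per-lineage sample counts; default is
#'   the skewed study distribution (see [default_abundances()]).
#' @param het_excess Probability that a founder genotype is forced
#'   heterozygous (0 = plain random union of gametes); models the
#'   heterozygote excess that accumulates in clonal lineages.
#' @param mutation_rate Per (sampled clone, locus) probability of a stepwise
#'   mutation of +/-1 repeat on one random allele.
#' @param error_dropout Probability that a heterozygous genotype is read as a
#'   homozygote for one of its alleles; scalar or per-locus vector (real
#'   panels concentrate error in a few stutter-prone loci).
#' @param error_miscall Probability that a read allele shifts by +/-1 repeat;
#'   scalar or per-locus vector.
#' @param missing_rate Per (sample, locus) missing probability; scalar or
#'   per-locus vector.
#' @param male_fraction Proportion of samples that are hemizygous X0 males.
#' @param x_linked Indices of X-linked loci (default: last 11 loci).
#' @param localities Locality labels, assigned round-robin.
#' @param date_range Start/end dates of the sampling season.
#' @param base_repeats Repeat count of the lowest allele at each locus.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 45L,
                       alleles_per_locus = c(2L, 8L),
                       allele_freq_prior = 0.5,
                       n_lineages = 97L,
                       lineage_abundances = default_abundances(n_lineages),
                       het_excess = 0.2,
                       mutation_rate = 0,
                       error_dropout = 0,
                       error_miscall = 0,
                       missing_rate = 0,
                       male_fraction = 0,
                       x_linked = NULL,
                       localities = c("Humpolec", "Valecov"),
                       date_range = c("2024-05-15", "2024-09-30"),
                       base_repeats = 7L) {
  if (length(lineage_abundances) != n_lineages) {
    stop("lineage_abundances must have one entry per lineage")
  }
  rates <- c(het_excess, mutation_rate, error_dropout, error_miscall,
             missing_rate, male_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (is.null(x_linked)) x_linked <- seq.int(max(1L, n_loci - 10L), n_loci)
  structure(list(
    seed = as.integer(seed), n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    allele_freq_prior = allele_freq_prior,
    n_lineages = as.integer(n_lineages),
    lineage_abundances = as.integer(lineage_abundances),
    het_excess = het_excess, mutation_rate = mutation_rate,
    error_dropout = error_dropout, error_miscall = error_miscall,
    missing_rate = missing_rate, male_fraction = male_fraction,
    x_linked = as.integer(x_linked), localities = localities,
    date_range = as.Date(date_range), base_repeats = as.integer(base_repeats)
  ), class = "sim_config")
}

#' Default skewed lineage-abundance distribution
#'
#' The five dominant lineages take 112, 39, 34, 28 and 25 samples; the
#' remaining samples (127 when `total = 365`) are spread over the minor
#' lineages by geometric decay (ratio 0.95) on top of one sample each, using
#' largest-remainder rounding so the counts are integers summing exactly.
#'
#' @param n_lineages Total number of lineages (>= 6).
#' @param top Abundances of the dominant lineages.
#' @param total Total number of samples.
#' @param ratio Geometric decay ratio for the minor-lineage extras.
#' @return Integer vector of length `n_lineages` summing to `total`.
#' @export
default_abundances <- function(n_lineages = 97L,
                               top = c(112L, 39L, 34L, 28L, 25L),
                               total = 365L, ratio = 0.95) {
  n_minor <- n_lineages - length(top)
  if (n_minor < 0L) stop("n_lineages smaller than the number of dominant lineages")
  rem <- total - sum(top)
  if (rem < n_minor) stop("total too small for one sample per minor lineage")
  extra <- rem - n_minor
  w <- ratio^(seq_len(n_minor) - 1L)
  share <- extra * w / sum(w)
  base <- floor(share)
  left <- extra - sum(base)
  if (left > 0) {
    up <- order(share - base, decreasing = TRUE)[seq_len(left)]
    base[up] <- base[up] + 1L
  }
  c(top, 1L + as.integer(base))
}

#' Simulate a clonally structured genotype table
#'
#' Founder lineages draw genotypes from per-locus allele frequencies
#' (Dirichlet-distributed over a uniform number of alleles per locus, on a
#' contiguous repeat-count grid). Every sampled clone inherits its lineage
#' genotype, then optionally receives stepwise mutations, read errors
#' (heterozygote dropout, +/-1 miscall), and missing data. Males are
#' hemizygous: their single X allele is reported as a homozygote at every
#' X-linked locus. Allele values are repeat counts.
#'
#' @param config A [sim_config()].
#' @return List with `table` (a `genotype_table`) and `truth` (a list of
#'   class `truth_record` holding per-sample lineage ids, the pre-error
#'   genotype matrices, true sex, per-locus founder allele frequencies, and
#'   logical event matrices for mutation/dropout/miscall/missing).
#' @export
simulate_population <- function(config = sim_config()) {
  cf <- config
  if (sum(cf$lineage_abundances) < 1L) stop("no samples requested")
  set.seed(cf$seed)
  n <- sum(cf$lineage_abundances)
  L <- cf$n_loci
  k_alleles <- sample(seq.int(cf$alleles_per_locus[1], cf$alleles_per_locus[2]),
                      L, replace = TRUE)
  freqs <- lapply(k_alleles, function(k) {
    g <- stats::rgamma(k, shape = cf$allele_freq_prior)
    p <- g / sum(g)
    names(p) <- as.character(cf$base_repeats + seq_len(k) - 1L)
    p
  })
  # founder lineage genotypes (repeat counts)
  f1 <- f2 <- matrix(NA_real_, cf$n_lineages, L)
  draw <- function(vals, size, prob) vals[sample.int(length(vals), size, replace = TRUE, prob = prob)]
  for (j in seq_len(L)) {
    vals <- as.numeric(names(freqs[[j]]))
    a <- draw(vals, cf$n_lineages, freqs[[j]])
    b <- draw(vals, cf$n_lineages, freqs[[j]])
    if (cf$het_excess > 0 && length(vals) > 1) {
      force_het <- stats::runif(cf$n_lineages) < cf$het_excess & a == b
      for (i in which(force_het)) {
        alt <- setdiff(vals, a[i])
        b[i] <- alt[sample.int(length(alt), 1L)]
      }
    }
    f1[, j] <- pmin(a, b); f2[, j] <- pmax(a, b)
  }
  lineage <- rep(seq_len(cf$n_lineages), times = cf$lineage_abundances)
  t1 <- f1[lineage, , drop = FALSE]
  t2 <- f2[lineage, , drop = FALSE]
  # stepwise mutation in the sampled clone
  mut <- matrix(stats::runif(n * L) < cf$mutation_rate, n, L)
  if (any(mut)) {
    for (idx in which(mut)) {
      step <- sample(c(-1, 1), 1L)
      if (stats::runif(1) < 0.5) t1[idx] <- max(1, t1[idx] + step)
      else t2[idx] <- max(1, t2[idx] + step)
    }
    sw <- t1 > t2
    tmp <- t1[sw]; t1[sw] <- t2[sw]; t2[sw] <- tmp
  }
  # sex: X0 males carry one X allele, reported homozygous
  male <- stats::runif(n) < cf$male_fraction
  if (any(male)) {
    for (j in cf$x_linked) {
      keep_first <- stats::runif(n) < 0.5
      x <- ifelse(keep_first, t1[, j], t2[, j])
      t1[male, j] <- x[male]; t2[male, j] <- x[male]
    }
  }
  read <- apply_read_errors(t1, t2, cf)
  sids <- sprintf("S%03d", seq_len(n))
  dates <- seq(cf$date_range[1], cf$date_range[2], length.out = n)
  samples <- data.frame(
    sample = sids,
    locality = rep_len(cf$localities, n),
    date = as.Date(dates),
    species_label = "Myzus persicae",
    stringsAsFactors = FALSE
  )
  panel <- synthetic_panel(L, cf$x_linked)
  tab <- genotype_table(read$a1, read$a2, samples, panel)
  truth <- structure(list(
    lineage = lineage, true_a1 = t1, true_a2 = t2, male = male,
    allele_freqs = freqs, config = cf,
    mutated = mut, dropout = read$dropout, miscall = read$miscall,
    missing = read$missing
  ), class = "truth_record")
  list(table = tab, truth = truth)
}

# read-error model shared by simulate_population and make_replicates;
# rates may be scalar or per-locus vectors of length L
apply_read_errors <- function(t1, t2, cf) {
  n <- nrow(t1); L <- ncol(t1)
  rate_mat <- function(r) matrix(rep(rep_len(r, L), each = n), n, L)
  a1 <- t1; a2 <- t2
  het <- a1 != a2
  drop <- het & matrix(stats::runif(n * L), n, L) < rate_mat(cf$error_dropout)
  if (any(drop)) {
    keep_first <- matrix(stats::runif(n * L) < 0.5, n, L)
    a1[drop] <- ifelse(keep_first[drop], t1[drop], t2[drop])
    a2[drop] <- a1[drop]
  }
  mis <- matrix(stats::runif(n * L), n, L) < rate_mat(cf$error_miscall)
  if (any(mis)) {
    for (idx in which(mis)) {
      step <- sample(c(-1, 1), 1L)
      if (stats::runif(1) < 0.5) a1[idx] <- max(1, a1[idx] + step)
      else a2[idx] <- max(1, a2[idx] + step)
    }
    sw <- a1 > a2
    tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  }
  miss <- matrix(stats::runif(n * L), n, L) < rate_mat(cf$missing_rate)
  a1[miss] <- NA_real_; a2[miss] <- NA_real_
  list(a1 = a1, a2 = a2, dropout = drop, miscall = mis, missing = miss)
}

synthetic_panel <- function(L, x_linked) {
  motifs <- rep_len(c("TAT", "ATT", "CAA", "AAT", "CCG", "CTG"), L)
  panel <- data.frame(
    name = sprintf("Sim-%03d", seq_len(L)),
    assay = rep_len(1:4, L),
    concentration = 0.2,
    dye = rep_len(c("6-FAM", "VIC", "NED", "PET"), L),
    chromosome = ifelse(seq_len(L) %in% x_linked, "chrX",
                        paste0("chr", rep_len(1:5, L))),
    hit_from = seq_len(L) * 1e5,
    hit_to = seq_len(L) * 1e5 + 30,
    strand = "plus",
    motif = motifs,
    ref_repeats = 8L,
    x_linked = seq_len(L) %in% x_linked,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Build a technical-replicate set for error-rate estimation
#'
#' Selects `k` samples (seeded) and generates replicate profiles by
#' re-applying the configured read-error model to the samples' true
#' genotypes, mimicking an independent re-amplification. The original
#' observed profiles serve as the reference.
#'
#' @param table `genotype_table` from [simulate_population()].
#' @param truth Matching `truth_record`.
#' @param k Number of replicated samples (default 22).
#' @param seed Seed for sample selection and replicate noise.
#' @return A `replicate_set` (see [replicate_set()]); its `truth_discordant`
#'   attribute marks loci where reference and replicate genuinely differ.
#' @export
make_replicates <- function(table, truth, k = 22L, seed = truth$config$seed + 1L) {
  if (k > n_samples(table)) stop("k exceeds number of samples")
  set.seed(seed)
  sel <- sort(sample(n_samples(table), k))
  cf <- truth$config
  rep_read <- apply_read_errors(truth$true_a1[sel, , drop = FALSE],
                                truth$true_a2[sel, , drop = FALSE], cf)
  ref <- subset_table(table, samples = sel)
  repl <- genotype_table(rep_read$a1, rep_read$a2, ref$samples, ref$panel)
  rs <- replicate_set(ref, repl)
  attr(rs, "selected") <- sel
  rs
}

#' Pair reference and replicate genotype tables
#'
#' @param ref,rep `genotype_table`s over the same samples and panel.
#' @return A list of class `replicate_set`.
#' @export
replicate_set <- function(ref, rep) {
  stopifnot(identical(dim(ref$a1), dim(rep$a1)),
            identical(locus_names(ref), locus_names(rep)))
  structure(list(ref = ref, rep = rep), class = "replicate_set")
}

#' Append foreign-species samples with partial marker amplification
#'
#' Emulates cross-species transferability tests: appended samples amplify
#' only a fraction of the panel (the first `round(amplify_fraction * n_loci)`
#' loci in panel order); the rest are missing. Amplifying loci receive the
#' locus's modal allele.
#'
#' @param table A `genotype_table`.
#' @param n_foreign Number of samples to append.
#' @param amplify_fraction Fraction of panel loci that amplify, in `[0, 1]`.
#' @param species Species label for the appended samples.
#' @return The extended `genotype_table`.
#' @export
spike_foreign_species <- function(table, n_foreign = 1L, amplify_fraction = 0,
                                  species = "Phorodon humuli") {
  stopifnot(amplify_fraction >= 0, amplify_fraction <= 1)
  L <- n_loci(table)
  n_amp <- round(amplify_fraction * L)
  a1 <- a2 <- matrix(NA_real_, n_foreign, L)
  if (n_amp > 0) {
    for (j in seq_len(n_amp)) {
      v <- c(table$a1[, j], table$a2[, j]); v <- v[!is.na(v)]
      modal <- if (length(v)) as.numeric(names(which.max(base::table(v)))) else 1
      a1[, j] <- modal; a2[, j] <- modal
    }
  }
  meta <- table$samples[rep(1L, n_foreign), , drop = FALSE]
  meta$sample <- sprintf("F%03d", n_samples(table) + seq_len(n_foreign))
  meta$species_label <- species
  genotype_table(rbind(table$a1, a1), rbind(table$a2, a2),
                 rbind(table$samples, meta), table$panel)
}
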