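#' Run the full clonal population-genetics workflow
#'
#' Orchestrates the analysis stages in a fixed order on a genotype table
#' (simulated or read from file): (1) drop the designated error-prone loci,
#' (2) filter samples by missing markers, (3) MAF-filter loci, (4) sex
#' inference, (5) per-locus statistics and diversity/LD before clone
#' correction, (6) clone correction, (7) the same statistics after, and
#' (8) distances, PCoA and the minimum spanning network over MLGs. Every
#' stochastic step descends from `seed`, so reruns are byte-identical.
#'
#' @param table A `genotype_table`.
#' @param error_prone_loci Locus names to drop up front (analyst's choice,
#'   e.g. from a replicate-based [error_rates()] ranking).
#' @param max_missing_markers Per-sample missing-marker threshold
#'   (default 4).
#' @param maf MAF threshold (default 0.01).
#' @param n_perm Permutations for the rbarD test (default 999).
#' @param hwe_mc Monte-Carlo permutations for the exact HWE test
#'   (default 0 = skip; the per-locus chi-squared test always runs).
#' @param seed Seed for all stochastic steps.
#' @param out_dir Optional directory; when given, stage tables are written
#'   as TSV/JSON with stage-named files.
#' @param verbose Log each filter's effect.
#' @return List of class `pipeline_result` with the filtered table, stage
#'   logs, sex report, B_cc/A_cc locus stats, diversity indices,
#'   association stats, MLG partition, PCoA and MSN, plus a `summary` list
#'   (the JSON-ready digest).
#' @export
run_pipeline <- function(table,
                         error_prone_loci = character(),
                         max_missing_markers = 4L,
                         maf = 0.01,
                         n_perm = 999L,
                         hwe_mc = 0L,
                         seed = 1L,
                         out_dir = NULL,
                         verbose = TRUE) {
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (verbose) message(msg)
    log <<- c(log, msg)
  }
  l0 <- n_loci(table); s0 <- n_samples(table)

  keep <- setdiff(locus_names(table), error_prone_loci)
  tab <- subset_table(table, loci = keep)
  say("error-prone locus drop: %d -> %d loci", l0, n_loci(tab))

  mf <- filter_samples_by_missing(tab, max_missing_markers)
  tab <- mf$table
  say("missing-marker sample filter (<= %d): N = %d -> %d retained",
      max_missing_markers, s0, n_samples(tab))

  mafres <- maf_filter(tab, maf)
  tab <- mafres$table
  say("MAF filter (< %g): %d -> %d loci%s", maf, length(mafres$maf), n_loci(tab),
      if (length(mafres$removed)) paste0(" (dropped ", paste(mafres$removed, collapse = ", "), ")") else "")

  sex <- if (any(tab$panel$x_linked)) infer_sex(tab) else NULL
  if (!is.null(sex)) {
    say("sex inference: %d female, %d male-consistent, %d undetermined",
        sex$n_female, sex$n_male_consistent, sex$n_undetermined)
  }

  stats_b <- locus_stats(tab, hwe_mc = hwe_mc, seed = seed)
  global_hwe_b <- paired_global_hwe(stats_b)
  part <- assign_mlgs(tab)
  div_b <- diversity_indices(part$abundance)
  assoc_b <- ia_rbarD(tab, n_perm = n_perm, seed = seed)
  say("MLGs: %d among %d samples (MLG/N = %.2f); B_cc rbarD = %.3f",
      part$n_mlg, n_samples(tab), part$n_mlg / n_samples(tab), assoc_b$rbarD)

  cc <- clone_correct(tab, part)
  stats_a <- locus_stats(cc, hwe_mc = hwe_mc, seed = seed + 1L)
  global_hwe_a <- paired_global_hwe(stats_a)
  div_a <- diversity_indices(rep(1L, part$n_mlg))
  assoc_a <- ia_rbarD(cc, n_perm = n_perm, seed = seed + 1L)
  say("after clone correction: %d samples; A_cc rbarD = %.3f",
      n_samples(cc), assoc_a$rbarD)

  bruvo <- bruvo_distance(cc)
  msn <- build_msn(bruvo, abundances = stats::setNames(part$abundance,
                                                       sample_ids(cc)))
  jac <- jaccard_binary_distance(tab)
  ord <- pcoa(jac, n_axes = 2L)

  summary <- list(
    loci_input = l0, loci_after_error_drop = length(keep),
    loci_final = n_loci(tab),
    samples_input = s0, samples_retained = n_samples(tab),
    n_mlg = part$n_mlg, mlg_over_n = part$n_mlg / n_samples(tab),
    sex = if (is.null(sex)) NULL else list(female = sex$n_female,
                                           male_consistent = sex$n_male_consistent,
                                           undetermined = sex$n_undetermined),
    diversity = list(
      B_cc = list(H = div_b$H, G = div_b$G, lambda = div_b$lambda, E5 = div_b$E5),
      A_cc = list(H = div_a$H, G = div_a$G, lambda = div_a$lambda, E5 = div_a$E5)
    ),
    association = list(
      B_cc = list(rbarD = assoc_b$rbarD, Ia = assoc_b$Ia, p = assoc_b$p),
      A_cc = list(rbarD = assoc_a$rbarD, Ia = assoc_a$Ia, p = assoc_a$p)
    ),
    global_hwe = list(
      B_cc = list(t_p = global_hwe_b$t_p, wilcoxon_p = global_hwe_b$wilcoxon_p),
      A_cc = list(t_p = global_hwe_a$t_p, wilcoxon_p = global_hwe_a$wilcoxon_p)
    ),
    heterozygosity = list(
      B_cc = list(h_obs_mean = mean(stats_b$h_obs, na.rm = TRUE),
                  h_exp_mean = mean(stats_b$h_exp, na.rm = TRUE),
                  f_is_mean = mean(stats_b$f_is, na.rm = TRUE)),
      A_cc = list(h_obs_mean = mean(stats_a$h_obs, na.rm = TRUE),
                  h_exp_mean = mean(stats_a$h_exp, na.rm = TRUE),
                  f_is_mean = mean(stats_a$f_is, na.rm = TRUE))
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(stats_b, file.path(out_dir, "locus_stats_Bcc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(stats_a, file.path(out_dir, "locus_stats_Acc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(msn$edges, file.path(out_dir, "msn_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(sample = rownames(ord$coords), ord$coords),
                       file.path(out_dir, "pcoa_coords.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }

  structure(list(table = tab, clone_corrected = cc, partition = part,
                 sex = sex, locus_stats_bcc = stats_b, locus_stats_acc = stats_a,
                 diversity_bcc = div_b, diversity_acc = div_a,
                 association_bcc = assoc_b, association_acc = assoc_a,
                 global_hwe_bcc = global_hwe_b, global_hwe_acc = global_hwe_a,
                 bruvo = bruvo, msn = msn, jaccard = jac, pcoa = ord,
                 removed_samples = mf$removed, removed_loci = mafres$removed,
                 log = log, summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("clonepop pipeline result\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
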