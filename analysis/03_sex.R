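#!/usr/bin/env Rscript
# Stage 3 — sex inference from X-linked hemizygosity.
#
# X0 males are homozygous at every X-linked marker; XX females usually are
# not. Classifies every filtered sample, reports the distribution of
# homozygous X loci per sample (the basis of the female/male call), and the
# panmictic false-male probability implied by the X allele frequencies.

suppressMessages(library(clonepop))

seed <- 20240612L
out_dir <- "results"

sim <- simulate_population(sim_config(seed = seed))
tab <- filter_samples_by_missing(sim$table, 4L)$table

sexrep <- infer_sex(tab)
print(sexrep)
cat("Distribution of homozygous X-linked loci per sample:\n")
print(sexrep$hom_distribution)

p_fm <- female_false_male_prob(allele_freqs(tab),
                               x_loci = sexrep$x_loci)
cat(sprintf("panmictic false-male probability over %d X loci: %.2e\n",
            length(sexrep$x_loci), p_fm))

utils::write.table(sexrep$per_sample, file.path(out_dir, "sex_calls.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/sex_calls.tsv\n")
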