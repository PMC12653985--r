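#!/usr/bin/env Rscript
# Stage 5 — population structure: distances, ordination, network.
#
# Binary-Jaccard PCoA over all filtered samples, Bruvo distances and the
# minimum spanning network over clone-corrected MLGs, and the dominant-MLG
# share per PCoA-derived cluster (clusters delimited here by k-medoids-like
# assignment to the 5 dominant lineage centroids on the first two axes —
# cluster delimitation is an explicit analyst step, never inferred
# silently).

suppressMessages(library(clonepop))

seed <- 20240612L
out_dir <- "results"

sim <- simulate_population(sim_config(seed = seed))
tab <- maf_filter(filter_samples_by_missing(sim$table, 4L)$table)$table

jac <- jaccard_binary_distance(tab)
ord <- pcoa(jac, n_axes = 2)
cat(sprintf("PCoA: first two axes explain %.1f%% + %.1f%% of positive-eigenvalue variance\n",
            100 * ord$var_explained[1], 100 * ord$var_explained[2]))
utils::write.table(data.frame(sample = rownames(ord$coords), ord$coords),
                   file.path(out_dir, "pcoa_coords.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

part <- assign_mlgs(tab)
cc <- clone_correct(tab, part)
bruvo <- bruvo_distance(cc)
msn <- build_msn(bruvo, abundances = stats::setNames(part$abundance,
                                                     rownames(cc$a1)))
print(msn)
utils::write.table(msn$edges, file.path(out_dir, "msn_edges.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(msn$nodes, file.path(out_dir, "msn_nodes.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

# cluster samples by nearest dominant-MLG centroid on the PCoA plane
dom <- order(part$abundance, decreasing = TRUE)[1:5]
centroids <- t(vapply(dom, function(m) {
  colMeans(ord$coords[part$mlg == m, , drop = FALSE])
}, numeric(2)))
lab <- apply(ord$coords, 1, function(z) {
  which.min(colSums((t(centroids) - z)^2))
})
clusters <- paste0("CL", lab)
shares <- cluster_share(part, clusters)
cat("Dominant MLG per cluster:\n")
print(shares)
utils::write.table(shares, file.path(out_dir, "cluster_shares.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/pcoa_coords.tsv, msn_edges.tsv, msn_nodes.tsv, cluster_shares.tsv\n")
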