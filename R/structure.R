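#' Bruvo distance between two diploid genotypes
#'
#' Stepwise-mutation-aware microsatellite distance. Per allele pair,
#' `d(a, b) = 1 - 2^(-|a - b|)` with alleles in repeat units; per locus, the
#' minimum over the two perfect matchings of the mean per-allele distance;
#' per genotype pair, the mean over loci typed in both genotypes (loci
#' missing in either are excluded). `NA` when no locus is shared.
#'
#' @param g1,g2 Lists with numeric vectors `a1`, `a2` of per-locus alleles
#'   (repeat counts), or single-locus length-2 vectors.
#' @return Distance in `[0, 1)`.
#' @export
bruvo_pair <- function(g1, g2) {
  if (is.numeric(g1)) g1 <- list(a1 = g1[1], a2 = g1[2])
  if (is.numeric(g2)) g2 <- list(a1 = g2[1], a2 = g2[2])
  d <- bruvo_locus_vec(g1$a1, g1$a2, g2$a1, g2$a2)
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

# vectorised per-locus Bruvo distance; NA where either genotype is missing
bruvo_locus_vec <- function(p1, p2, q1, q2) {
  step <- function(a, b) 1 - 2^(-abs(a - b))
  direct <- (step(p1, q1) + step(p2, q2)) / 2
  crossed <- (step(p1, q2) + step(p2, q1)) / 2
  out <- pmin(direct, crossed)
  out[is.na(p1) | is.na(p2) | is.na(q1) | is.na(q2)] <- NA_real_
  out
}

#' Pairwise Bruvo distance matrix
#'
#' @param x A `genotype_table` whose values are repeat counts (convert
#'   fragment sizes first with [table_to_repeats()]).
#' @return A symmetric `dist_matrix` (samples x samples) with metric tag
#'   `"bruvo"`. Pairs sharing no typed locus are `NA` (flagged via the
#'   `undefined_pairs` attribute).
#' @export
bruvo_distance <- function(x) {
  n <- n_samples(x)
  D <- matrix(0, n, n, dimnames = list(sample_ids(x), sample_ids(x)))
  for (i in seq_len(max(0, n - 1))) {
    for (k in seq.int(i + 1, n)) {
      d <- bruvo_locus_vec(x$a1[i, ], x$a2[i, ], x$a1[k, ], x$a2[k, ])
      D[i, k] <- D[k, i] <- if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }
  }
  und <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  structure(D, class = c("dist_matrix", "matrix"), metric = "bruvo",
            undefined_pairs = und)
}

#' Binary Jaccard distance over allele presence/absence
#'
#' Expands the table into a samples x (locus, allele) presence/absence
#' matrix and computes, for samples i and j with `a` shared present alleles
#' and `b + c` mismatched present alleles,
#' `d = sqrt(1 - a / (a + b + c))`. The square-root form is Euclidean-
#' embeddable, which keeps the subsequent PCoA free of negative eigenvalues
#' (up to numerical noise). The underlying Jaccard similarity is computed
#' with `vegan::vegdist`.
#'
#' @param x A `genotype_table`.
#' @param sqrt_transform Use the Euclidean-embeddable square-root form
#'   (default); `FALSE` gives the raw `1 - similarity` dialect.
#' @return A `dist_matrix` with metric tag `"jaccard-binary"`.
#' @export
jaccard_binary_distance <- function(x, sqrt_transform = TRUE) {
  pa <- presence_absence(x)
  if (any(rowSums(pa) == 0)) {
    stop("sample(s) with no present alleles: ",
         paste(rownames(pa)[rowSums(pa) == 0], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(pa, method = "jaccard", binary = TRUE))
  if (sqrt_transform) d <- sqrt(d)
  diag(d) <- 0
  structure(d, class = c("dist_matrix", "matrix"), metric = "jaccard-binary")
}

# samples x (locus, allele) 0/1 matrix
presence_absence <- function(x) {
  cols <- list()
  for (j in seq_len(n_loci(x))) {
    vals <- sort(unique(c(x$a1[, j], x$a2[, j])))
    vals <- vals[!is.na(vals)]
    for (v in vals) {
      cols[[paste0(locus_names(x)[j], ".", v)]] <-
        as.integer(!is.na(x$a1[, j]) & (x$a1[, j] == v | x$a2[, j] == v))
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- sample_ids(x)
  out
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres `-D^2/2` and eigendecomposes it (via [stats::cmdscale()]);
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues, axes ordered by decreasing eigenvalue. Negative eigenvalues
#' are reported but carry no coordinates.
#'
#' @param D A symmetric zero-diagonal distance matrix (`dist_matrix`,
#'   `dist` or plain matrix).
#' @param n_axes Number of axes requested (truncated with a warning if it
#'   exceeds the number of positive eigenvalues).
#' @return List of class `pcoa_result`: `coords` (entities x axes),
#'   `eigenvalues` (all), `var_explained` (fraction of positive-eigenvalue
#'   variance per retained axis).
#' @export
pcoa <- function(D, n_axes = 2L) {
  M <- as.matrix(D)
  stopifnot(isSymmetric(unname(M)), all(abs(diag(M)) < 1e-12))
  n <- nrow(M)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(M), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > pos) {
    warning("only ", pos, " positive eigenvalue(s); truncating axes")
    n_axes <- pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(coords = coords, eigenvalues = eig,
                 var_explained = eig[seq_len(n_axes)] / sum(eig[eig > 0])),
            class = "pcoa_result")
}

# ---- minimum spanning network ----------------------------------------------

# Kruskal MST with lexicographic tie-breaking; edges as (i, j, w) data frame
kruskal_mst <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  e <- data.frame(i = pairs[, 1], j = pairs[, 2], w = D[pairs])
  e <- e[is.finite(e$w), , drop = FALSE]
  e <- e[order(e$w, e$i, e$j), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    ri <- find(e$i[r]); rj <- find(e$j[r])
    if (ri != rj) { parent[min(ri, rj)] <- min(ri, rj); parent[max(ri, rj)] <- min(ri, rj); keep[r] <- TRUE }
  }
  list(tree = e[keep, , drop = FALSE], all_edges = e)
}

#' Minimum spanning network over MLGs
#'
#' Computes the minimum spanning tree of the distance matrix (Kruskal with
#' deterministic lexicographic tie-breaking) and then adds every non-tree
#' edge whose weight is within `tie_tolerance` of the heaviest tree edge on
#' the path between its endpoints — the tied alternatives that make the
#' result a network rather than an arbitrary tree. Nodes carry MLG
#' abundances for plotting. With infinite distances the network decomposes
#' into one spanning forest per connected block (flagged).
#'
#' @param D A `dist_matrix` over MLG representatives (typically Bruvo).
#' @param abundances Named abundance per node (default 1).
#' @param tie_tolerance Absolute tolerance for tied edges (default `1e-8`:
#'   exact ties only).
#' @return List of class `msn_graph`: `edges` (data frame `from`, `to`,
#'   `weight`, `in_tree`), `nodes` (data frame `id`, `abundance`),
#'   `total_tree_weight`, `n_components`.
#' @export
build_msn <- function(D, abundances = NULL, tie_tolerance = 1e-8) {
  M <- as.matrix(D)
  n <- nrow(M)
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(abundances)) abundances <- stats::setNames(rep(1L, n), ids)
  ms <- kruskal_mst(M)
  tree <- ms$tree
  # adjacency of the tree for path queries
  adj <- vector("list", n)
  for (r in seq_len(nrow(tree))) {
    adj[[tree$i[r]]] <- rbind(adj[[tree$i[r]]], c(tree$j[r], tree$w[r]))
    adj[[tree$j[r]]] <- rbind(adj[[tree$j[r]]], c(tree$i[r], tree$w[r]))
  }
  # max edge weight on the tree path between a and b (NA if disconnected)
  path_max <- function(a, b) {
    seen <- rep(FALSE, n); seen[a] <- TRUE
    frontier <- list(list(node = a, mx = -Inf))
    while (length(frontier)) {
      nxt <- list()
      for (f in frontier) {
        nb <- adj[[f$node]]
        if (is.null(nb)) next
        for (r in seq_len(nrow(nb))) {
          v <- nb[r, 1]; w <- nb[r, 2]
          if (!seen[v]) {
            mx <- max(f$mx, w)
            if (v == b) return(mx)
            seen[v] <- TRUE
            nxt[[length(nxt) + 1L]] <- list(node = v, mx = mx)
          }
        }
      }
      frontier <- nxt
    }
    NA_real_
  }
  extra <- ms$all_edges[!rownames(ms$all_edges) %in% rownames(tree), , drop = FALSE]
  tie <- logical(nrow(extra))
  for (r in seq_len(nrow(extra))) {
    pm <- path_max(extra$i[r], extra$j[r])
    tie[r] <- !is.na(pm) && extra$w[r] <= pm + tie_tolerance
  }
  edges <- rbind(
    data.frame(from = ids[tree$i], to = ids[tree$j], weight = tree$w,
               in_tree = rep(TRUE, nrow(tree)), stringsAsFactors = FALSE),
    data.frame(from = ids[extra$i[tie]], to = ids[extra$j[tie]],
               weight = extra$w[tie], in_tree = rep(FALSE, sum(tie)),
               stringsAsFactors = FALSE)
  )
  # connected components under finite distances
  comp <- rep(0L, n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cc <- cc + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cc
      nb <- adj[[v]]
      if (!is.null(nb)) stack <- c(stack, nb[, 1])
    }
  }
  structure(list(
    edges = edges,
    nodes = data.frame(id = ids, abundance = as.integer(abundances[ids]),
                       component = comp, stringsAsFactors = FALSE),
    total_tree_weight = sum(tree$w),
    n_components = cc
  ), class = "msn_graph")
}

#' @export
print.msn_graph <- function(x, ...) {
  cat(sprintf("MSN: %d nodes, %d edges (%d tree + %d tied), tree weight %.4f",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_tree),
              sum(!x$edges$in_tree), x$total_tree_weight))
  if (x$n_components > 1) cat(sprintf("  [%d components]", x$n_components))
  cat("\n")
  invisible(x)
}

#' Dominant-MLG share per cluster
#'
#' For each cluster of samples, reports the most abundant MLG, its clone
#' count within the cluster, and its percentage share (2 dp).
#'
#' @param partition An `mlg_partition`.
#' @param clusters Cluster label per sample (same order as the partition's
#'   samples). Empty clusters are excluded.
#' @return Data frame with `cluster`, `n`, `dominant_mlg`, `clone_count`,
#'   `share_pct`.
#' @export
cluster_share <- function(partition, clusters) {
  stopifnot(length(clusters) == length(partition$mlg))
  if (anyNA(clusters)) stop("every sample must be labelled")
  res <- lapply(split(seq_along(clusters), clusters), function(i) {
    tab <- sort(base::table(partition$mlg[i]), decreasing = TRUE)
    data.frame(n = length(i),
               dominant_mlg = names(partition$abundance)[as.integer(names(tab)[1])],
               clone_count = as.integer(tab[1]),
               share_pct = round(100 * as.integer(tab[1]) / length(i), 2))
  })
  out <- do.call(rbind, res)
  out <- cbind(cluster = names(res), out)
  rownames(out) <- NULL
  out
}
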