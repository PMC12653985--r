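# Small in-code fixtures shared across tests.

# Build a genotype_table from a list of per-locus genotype string vectors,
# e.g. list(L1 = c("120/126", "NA/NA"), L2 = c("8/8", "8/9")).
toy_table <- function(geno, localities = NULL, dates = NULL) {
  loci <- names(geno)
  n <- length(geno[[1]])
  parse <- function(s) {
    if (s == "NA/NA") return(c(NA_real_, NA_real_))
    as.numeric(strsplit(s, "/")[[1]])
  }
  a1 <- a2 <- matrix(NA_real_, n, length(loci))
  for (j in seq_along(loci)) {
    for (i in seq_len(n)) {
      p <- parse(geno[[j]][i])
      a1[i, j] <- p[1]; a2[i, j] <- p[2]
    }
  }
  samples <- data.frame(sample = sprintf("S%02d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(localities)) samples$locality <- localities
  if (!is.null(dates)) samples$date <- as.Date(dates)
  genotype_table(a1, a2, samples, toy_panel(loci))
}

toy_panel <- function(loci, x_linked = rep(FALSE, length(loci))) {
  panel <- data.frame(
    name = loci, assay = 1L, concentration = 0.1, dye = "6-FAM",
    chromosome = "chr1", hit_from = 100, hit_to = 130, strand = "plus",
    motif = "TAT", ref_repeats = 8L, x_linked = x_linked,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

shipped_panel_path <- function() {
  system.file("extdata", "myzper_panel.csv", package = "clonepop")
}

# Replicate set where `flip` names samples whose first-locus genotype is
# altered in the replicate (guaranteed discordant).
toy_replicates <- function(n_pairs, n_loci = 3, flip = integer(0)) {
  geno <- stats::setNames(
    lapply(seq_len(n_loci), function(j) rep(sprintf("%d/%d", 7 + j, 8 + j), n_pairs)),
    sprintf("L%d", seq_len(n_loci)))
  ref <- toy_table(geno)
  rp <- ref
  for (i in flip) rp$a1[i, 1] <- rp$a1[i, 1] + 5
  rp <- genotype_table(rp$a1, rp$a2, rp$samples, rp$panel)
  replicate_set(ref, rp)
}

# Brute-force Bruvo distance for one diploid locus: enumerate both perfect
# matchings explicitly.
bruvo_locus_brute <- function(g1, g2) {
  d <- function(a, b) 1 - 2^(-abs(a - b))
  m1 <- (d(g1[1], g2[1]) + d(g1[2], g2[2])) / 2
  m2 <- (d(g1[1], g2[2]) + d(g1[2], g2[1])) / 2
  min(m1, m2)
}

# Brute-force perfect-SSR scan: test every (start, period) pair.
find_ssrs_brute <- function(seq, min_motif = 2, max_motif = 6, min_repeats = 5) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  hits <- list()
  for (p in min_motif:max_motif) {
    for (start in seq_len(max(0, n - p * min_repeats + 1))) {
      # count complete repeats of s[start..start+p-1] from start
      motif <- s[start:(start + p - 1)]
      if (any(!motif %in% c("A", "C", "G", "T"))) next
      reps <- 1
      while (start + (reps + 1) * p - 1 <= n &&
             all(s[start + reps * p + 0:(p - 1)] == motif)) reps <- reps + 1
      if (reps < min_repeats) next
      # maximal: no full extra copy before start
      if (start - p >= 1 && all(s[(start - p):(start - 1)] == motif)) next
      # drop if the motif has a smaller period (incl. homopolymers)
      periodic <- FALSE
      for (q in seq_len(p - 1)) {
        if (p %% q == 0 && all(motif == rep_len(motif[1:q], p))) periodic <- TRUE
      }
      if (periodic) next
      # drop if extendable to an earlier phase of the same smallest period:
      # keep only runs whose start is the leftmost position of the run
      if (start > 1 && !(s[start - 1] %in% c("A", "C", "G", "T"))) {
        # N breaks the run; fine
      } else if (start > 1 && s[start - 1] == s[start + p - 1]) next
      hits[[length(hits) + 1]] <- data.frame(
        start = start, end = start + p * reps - 1,
        motif = paste(motif, collapse = ""), n_repeats = reps,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), n_repeats = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
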