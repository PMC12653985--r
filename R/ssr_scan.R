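#' Find perfect microsatellites in a nucleotide sequence
#'
#' Scans the forward strand for maximal perfect tandem repeats with motif
#' length between `min_motif` and `max_motif` and at least `min_repeats` full
#' repetitions. Each run is reported once, at its smallest period, with the
#' motif read off the first period at the run start (so AT and TA runs are
#' distinct motifs). Homopolymer runs are never reported, and runs containing
#' `N` are broken at the `N`. Partial trailing repeats are truncated: the
#' repeat count is the number of complete motif copies and `end` is the last
#' base of the last complete copy.
#'
#' @param seq A single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @param min_motif,max_motif Motif length bounds (defaults 2 and 6).
#' @param min_repeats Minimum number of full repetitions (default 5).
#' @param seqid Sequence identifier for the output.
#' @return Data frame with columns `seqid`, `start`, `end` (1-based
#'   inclusive), `motif`, `n_repeats`.
#' @export
find_perfect_ssrs <- function(seq, min_motif = 2L, max_motif = 6L,
                              min_repeats = 5L, seqid = "seq") {
  if (min_motif > max_motif) stop("min_motif must be <= max_motif")
  stopifnot(length(seq) == 1L)
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  bad <- !(s %in% c("A", "C", "G", "T"))   # N or anything else breaks runs
  out <- list()
  for (p in seq.int(min_motif, max_motif)) {
    if (n < p * min_repeats) break
    # eq[i] TRUE when s[i] == s[i + p] and both are unambiguous bases
    eq <- s[seq_len(n - p)] == s[seq.int(p + 1L, n)] &
      !bad[seq_len(n - p)] & !bad[seq.int(p + 1L, n)]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      start <- pos[k]
      run_len <- r$lengths[k] + p          # total perfectly repeated stretch
      n_rep <- run_len %/% p
      if (n_rep < min_repeats) next
      motif <- paste(s[seq.int(start, start + p - 1L)], collapse = "")
      if (smallest_period(motif) < p) next # reported at its true period
      out[[length(out) + 1L]] <- data.frame(
        seqid = seqid, start = start, end = start + p * n_rep - 1L,
        motif = motif, n_repeats = n_rep, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seqid = character(), start = integer(), end = integer(),
                      motif = character(), n_repeats = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, nchar(res$motif)), , drop = FALSE]
}

# length of the shortest unit u such that motif is u repeated (1 => homopolymer)
smallest_period <- function(motif) {
  L <- nchar(motif)
  ch <- strsplit(motif, "")[[1]]
  for (p in seq_len(L)) {
    if (L %% p == 0L && all(ch == rep_len(ch[seq_len(p)], L))) return(p)
  }
  L
}

#' Scan a FASTA file for perfect microsatellites
#'
#' @param path FASTA path (read with Biostrings).
#' @param ... Passed to [find_perfect_ssrs()].
#' @return Combined data frame of loci over all sequences.
#' @export
scan_fasta <- function(path, ...) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("scan_fasta requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  res <- lapply(seq_along(seqs), function(i) {
    find_perfect_ssrs(as.character(seqs[[i]]), seqid = names(seqs)[i], ...)
  })
  do.call(rbind, res)
}

#' Filter SSR loci to marker-candidate criteria
#'
#' Retains tri- to hexanucleotide loci with at least `min_repeats`
#' repetitions — the screening rule that discards the abundant but
#' stutter-prone dinucleotide class before marker development.
#'
#' @param loci Data frame from [find_perfect_ssrs()].
#' @param min_motif,max_motif Motif-length bounds (defaults 3 and 6).
#' @param min_repeats Minimum repetitions (default 7).
#' @return The qualifying subset, input order preserved.
#' @export
filter_candidate_loci <- function(loci, min_motif = 3L, max_motif = 6L,
                                  min_repeats = 7L) {
  mlen <- nchar(loci$motif)
  loci[mlen >= min_motif & mlen <= max_motif & loci$n_repeats >= min_repeats, ,
       drop = FALSE]
}

#' Summarise the motif distribution of a set of SSR loci
#'
#' Motifs are counted as read (no canonicalisation across rotations or
#' reverse complements, so AT and TA stay distinct).
#'
#' @param loci Data frame from [find_perfect_ssrs()].
#' @return List with `by_motif` and `by_length` count tables (decreasing)
#'   and `mean_repeats` / `median_repeats`.
#' @export
motif_summary <- function(loci) {
  if (nrow(loci) == 0L) {
    return(list(by_motif = integer(0), by_length = integer(0),
                mean_repeats = NA_real_, median_repeats = NA_real_))
  }
  list(
    by_motif = sort(table(loci$motif), decreasing = TRUE),
    by_length = table(nchar(loci$motif)),
    mean_repeats = mean(loci$n_repeats),
    median_repeats = stats::median(loci$n_repeats)
  )
}
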