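#' Read a microsatellite marker panel
#'
#' Parses a panel definition CSV into a `marker_panel` data frame, one row per
#' SSR locus. The panel describes each marker's multiplex assay, fluorescent
#' dye, primer concentration, chromosomal position, repeat motif and reference
#' repeat count, plus an explicit X-linked flag used by [infer_sex()].
#'
#' @param path Path to a CSV with columns `Assay`, `Marker`, `c`, `Dye`,
#'   `Chromosome`, `HitFrom`, `HitTo`, `Strand`, `Motif`, `Repeats`,
#'   `XLinked`. An optional `Na` column (observed allele counts) is carried
#'   through when present.
#' @return A data frame of class `marker_panel` with columns `name`, `assay`,
#'   `concentration`, `dye`, `chromosome`, `hit_from`, `hit_to`, `strand`,
#'   `motif`, `ref_repeats`, `x_linked` and optionally `n_alleles`.
#' @export
read_panel <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Assay", "Marker", "c", "Dye", "Chromosome", "HitFrom", "HitTo",
            "Strand", "Motif", "Repeats", "XLinked")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  }
  panel <- data.frame(
    name          = as.character(raw$Marker),
    assay         = as.integer(raw$Assay),
    concentration = as.numeric(raw$c),
    dye           = as.character(raw$Dye),
    chromosome    = as.character(raw$Chromosome),
    hit_from      = as.numeric(raw$HitFrom),
    hit_to        = as.numeric(raw$HitTo),
    strand        = tolower(as.character(raw$Strand)),
    motif         = toupper(as.character(raw$Motif)),
    ref_repeats   = as.integer(raw$Repeats),
    x_linked      = as.logical(raw$XLinked),
    stringsAsFactors = FALSE
  )
  if ("Na" %in% names(raw)) panel$n_alleles <- as.integer(raw$Na)
  validate_panel(panel)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (nrow(panel) == 0L) return(invisible(panel))
  dup <- panel$name[duplicated(panel$name)]
  if (length(dup)) stop("duplicate marker name(s): ", paste(unique(dup), collapse = ", "))
  bad <- grepl("[^ACGT]", panel$motif)
  if (any(bad)) {
    stop("motif with non-ACGT characters at marker(s): ",
         paste(panel$name[bad], collapse = ", "))
  }
  mlen <- nchar(panel$motif)
  if (any(mlen < 2L | mlen > 6L)) stop("motif length must be in [2, 6]")
  if (any(panel$ref_repeats < 5L)) stop("reference repeat count must be >= 5")
  if (any(c(panel$hit_from, panel$hit_to) <= 0, na.rm = TRUE)) {
    stop("genome hit coordinates must be positive")
  }
  invisible(panel)
}

#' Construct a genotype table
#'
#' The central container: diploid allele calls for `n` samples at the loci of
#' a marker panel, plus per-sample metadata. Allele pairs are stored
#' unordered (canonically sorted ascending); a genotype is missing iff both
#' slots are `NA`. Values may be fragment sizes in bp or repeat counts; the
#' two are interconverted by [size_to_repeats()] / [repeats_to_size()].
#'
#' @param a1,a2 Numeric matrices (samples x loci) holding the smaller and
#'   larger allele of each genotype; homozygotes carry the value twice.
#' @param samples Data frame of per-sample metadata with at least a `sample`
#'   column; `locality`, `date` and `species_label` are used when present.
#' @param panel A `marker_panel` (see [read_panel()]); column order of
#'   `a1`/`a2` must match `panel$name`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, samples, panel) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)), nrow(a1) == nrow(samples),
            ncol(a1) == nrow(panel))
  if (!"sample" %in% names(samples)) stop("samples must have a 'sample' column")
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  # canonical unordered storage: sort each pair ascending, half-missing keeps
  # its value in slot 1
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  one <- is.na(a1) != is.na(a2)
  if (any(one)) {
    v <- ifelse(is.na(a1[one]), a2[one], a1[one])
    lo[one] <- v; hi[one] <- NA_real_
  }
  dimnames(lo) <- dimnames(hi) <- list(samples$sample, panel$name)
  if (!"season" %in% names(samples) && "date" %in% names(samples)) {
    samples$season <- derive_season(samples$date)
  }
  structure(list(a1 = lo, a2 = hi, samples = samples, panel = panel),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$a1), "samples x", ncol(x$a1), "loci\n")
  cat("  missing genotypes:", sum(is.na(x$a1)), "of", length(x$a1), "\n")
  if ("locality" %in% names(x$samples)) {
    cat("  localities:", paste(unique(x$samples$locality), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$a1)

n_samples <- function(x) nrow(x$a1)
n_loci <- function(x) ncol(x$a1)
locus_names <- function(x) x$panel$name
sample_ids <- function(x) x$samples$sample

is_missing_geno <- function(x) is.na(x$a1)
is_half_missing <- function(x) !is.na(x$a1) & is.na(x$a2)

#' Subset a genotype table
#'
#' @param x A `genotype_table`.
#' @param samples,loci Character, logical or integer index of samples / loci
#'   to keep; `NULL` keeps all.
#' @return A `genotype_table` restricted to the selection.
#' @export
subset_table <- function(x, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(x)) else resolve_idx(samples, sample_ids(x))
  li <- if (is.null(loci)) seq_len(n_loci(x)) else resolve_idx(loci, locus_names(x))
  genotype_table(x$a1[si, li, drop = FALSE], x$a2[si, li, drop = FALSE],
                 x$samples[si, , drop = FALSE],
                 x$panel[li, , drop = FALSE])
}

resolve_idx <- function(idx, ids) {
  if (is.character(idx)) {
    i <- match(idx, ids)
    if (anyNA(i)) stop("unknown id(s): ", paste(idx[is.na(i)], collapse = ", "))
    i
  } else if (is.logical(idx)) which(idx) else as.integer(idx)
}

#' Map calendar dates to seasons
#'
#' Meteorological bins: Mar-May spring, Jun-Aug summer, Sep-Nov autumn,
#' Dec-Feb winter. The mapping is configurable because season definitions are
#' a sampling-design choice.
#'
#' @param dates Dates or ISO date strings.
#' @param bins Named list mapping season names to month numbers.
#' @return Character vector of season labels.
#' @export
derive_season <- function(dates,
                          bins = list(spring = 3:5, summer = 6:8,
                                      autumn = 9:11, winter = c(12, 1, 2))) {
  m <- as.integer(format(as.Date(dates), "%m"))
  out <- rep(NA_character_, length(m))
  for (s in names(bins)) out[m %in% bins[[s]]] <- s
  out
}

# ---- genotype CSV I/O -------------------------------------------------------

MISSING_CODES <- c("NA", "", "0")

parse_allele <- function(v) {
  v <- trimws(as.character(v))
  v[v %in% MISSING_CODES | is.na(v)] <- NA_character_
  as.numeric(v)
}

#' Read a genotype table from CSV
#'
#' Two dialects are accepted. Long: one row per (sample, locus) with columns
#' `sample, locality, date, locus, allele1, allele2`. Wide: one row per
#' sample with `sample, locality, date` followed by two columns per locus
#' named `<locus>.1`, `<locus>.2`. Missing calls may be encoded `NA`, `0` or
#' an empty field; on write only `NA` is emitted.
#'
#' A single non-missing allele in a pair is interpreted as a homozygote by
#' default (the usual capillary-electrophoresis single-peak convention);
#' `single_peak = "half_missing"` instead keeps the second slot missing, for
#' dropout-sensitivity analyses.
#'
#' @param path CSV path.
#' @param panel `marker_panel` giving locus order; loci in the file but not
#'   in the panel are dropped with a warning.
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param single_peak `"homozygote"` or `"half_missing"`.
#' @return A `genotype_table` with loci ordered as in `panel`.
#' @export
read_genotypes <- function(path, panel, format = c("auto", "long", "wide"),
                           single_peak = c("homozygote", "half_missing")) {
  format <- match.arg(format)
  single_peak <- match.arg(single_peak)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto") {
    format <- if (all(c("locus", "allele1", "allele2") %in% names(raw))) "long" else "wide"
  }
  if (format == "long") {
    need <- c("sample", "locus", "allele1", "allele2")
    if (!all(need %in% names(raw))) stop("long dialect needs columns: ", paste(need, collapse = ", "))
    key <- paste(raw$sample, raw$locus, sep = "\r")
    if (anyDuplicated(key)) {
      d <- raw[duplicated(key), , drop = FALSE][1, ]
      stop("sample ", d$sample, " lists locus ", d$locus, " more than once")
    }
    unknown <- setdiff(unique(raw$locus), panel$name)
    if (length(unknown)) {
      warning("dropping loci absent from panel: ", paste(unknown, collapse = ", "))
      raw <- raw[raw$locus %in% panel$name, , drop = FALSE]
    }
    sids <- unique(raw$sample)
    a1 <- a2 <- matrix(NA_real_, length(sids), nrow(panel),
                       dimnames = list(sids, panel$name))
    ri <- match(raw$sample, sids); ci <- match(raw$locus, panel$name)
    a1[cbind(ri, ci)] <- parse_allele(raw$allele1)
    a2[cbind(ri, ci)] <- parse_allele(raw$allele2)
    meta_cols <- intersect(c("sample", "locality", "date", "species_label"), names(raw))
    samples <- unique(raw[meta_cols])
    if (anyDuplicated(samples$sample)) stop("inconsistent metadata within sample")
    samples <- samples[match(sids, samples$sample), , drop = FALSE]
  } else {
    if (!"sample" %in% names(raw)) stop("wide dialect needs a 'sample' column")
    acols <- grep("\\.[12]$", names(raw), value = TRUE)
    loci_in <- unique(sub("\\.[12]$", "", acols))
    unknown <- setdiff(loci_in, panel$name)
    if (length(unknown)) warning("dropping loci absent from panel: ", paste(unknown, collapse = ", "))
    a1 <- a2 <- matrix(NA_real_, nrow(raw), nrow(panel),
                       dimnames = list(raw$sample, panel$name))
    for (loc in intersect(loci_in, panel$name)) {
      a1[, loc] <- parse_allele(raw[[paste0(loc, ".1")]])
      a2[, loc] <- parse_allele(raw[[paste0(loc, ".2")]])
    }
    samples <- raw[setdiff(names(raw), acols)]
  }
  rownames(samples) <- NULL
  if (single_peak == "homozygote") {
    one <- is.na(a1) != is.na(a2)
    v <- ifelse(is.na(a1), a2, a1)
    a1[one] <- v[one]; a2[one] <- v[one]
  }
  genotype_table(a1, a2, samples, panel)
}

#' Write a genotype table to CSV
#'
#' @param x A `genotype_table`.
#' @param path Output CSV path.
#' @param format `"long"` or `"wide"` (see [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  meta_cols <- intersect(c("sample", "locality", "date", "species_label"),
                         names(x$samples))
  meta <- x$samples[meta_cols]
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, trim = TRUE, scientific = FALSE))
  if (format == "long") {
    n <- n_samples(x); L <- n_loci(x)
    out <- meta[rep(seq_len(n), times = L), , drop = FALSE]
    out$locus <- rep(locus_names(x), each = n)
    out$allele1 <- fmt(as.vector(x$a1))
    out$allele2 <- fmt(as.vector(x$a2))
  } else {
    out <- meta
    for (j in seq_len(n_loci(x))) {
      loc <- locus_names(x)[j]
      out[[paste0(loc, ".1")]] <- fmt(x$a1[, j])
      out[[paste0(loc, ".2")]] <- fmt(x$a2[, j])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- allelic ladder and binning --------------------------------------------

#' Read an allelic-ladder definition
#'
#' @param path CSV with columns `locus`, `size` (one row per reference
#'   allele).
#' @return Named list of strictly increasing numeric vectors, one per locus,
#'   of class `allelic_ladder`.
#' @export
read_ladder <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "size") %in% names(raw))) stop("ladder needs columns locus, size")
  ladder <- lapply(split(as.numeric(raw$size), raw$locus), sort)
  as_ladder(ladder)
}

#' @rdname read_ladder
#' @param x Named list of per-locus reference allele sizes.
#' @export
as_ladder <- function(x) {
  for (loc in names(x)) {
    v <- x[[loc]]
    if (is.unsorted(v, strictly = TRUE)) stop("ladder for ", loc, " not strictly increasing")
    if (length(v) > 1 && min(diff(v)) < 1) stop("ladder bins for ", loc, " closer than 1 bp")
  }
  structure(x, class = "allelic_ladder")
}

#' Bin allele calls against an allelic ladder
#'
#' Snaps each non-missing fragment-size call to the nearest reference allele
#' of the per-plate ladder when within `tol` bp; calls farther than `tol`
#' from every ladder allele are retained unchanged but flagged off-ladder.
#' Binning is idempotent and never changes the number of non-missing calls.
#'
#' @param x A `genotype_table` with fragment-size calls.
#' @param ladder An `allelic_ladder` covering every locus of `x`.
#' @param tol Positive tolerance in bp, below half the minimum ladder gap.
#' @return `x` with snapped values and an `off_ladder` attribute (a logical
#'   samples x loci matrix marking genotypes with at least one off-ladder
#'   call).
#' @export
bin_alleles <- function(x, ladder, tol = 0.5) {
  stopifnot(tol > 0)
  missing_loci <- setdiff(locus_names(x), names(ladder))
  if (length(missing_loci)) {
    stop("no ladder for locus/loci: ", paste(missing_loci, collapse = ", "))
  }
  gaps <- vapply(ladder[locus_names(x)],
                 function(v) if (length(v) > 1) min(diff(v)) else Inf, 0)
  if (tol >= min(gaps) / 2) stop("tol must be < half the minimum ladder gap")
  off <- matrix(FALSE, n_samples(x), n_loci(x),
                dimnames = dimnames(x$a1))
  snap <- function(v, ref) {
    out <- v; flag <- logical(length(v))
    ok <- !is.na(v)
    if (any(ok)) {
      i <- vapply(v[ok], function(z) which.min(abs(ref - z)), 0L)
      near <- abs(ref[i] - v[ok]) <= tol
      out[ok][near] <- ref[i][near]
      flag[ok][!near] <- TRUE
    }
    list(v = out, flag = flag)
  }
  for (j in seq_len(n_loci(x))) {
    ref <- ladder[[locus_names(x)[j]]]
    s1 <- snap(x$a1[, j], ref); s2 <- snap(x$a2[, j], ref)
    x$a1[, j] <- s1$v; x$a2[, j] <- s2$v
    off[, j] <- s1$flag | s2$flag
  }
  # restore canonical order in case snapping reordered a pair
  res <- genotype_table(x$a1, x$a2, x$samples, x$panel)
  attr(res, "off_ladder") <- off
  res
}

# ---- fragment size <-> repeat count ----------------------------------------

#' Convert fragment size to repeat count (and back)
#'
#' Repeat count = (size - offset) / motif length, where `offset` is the
#' locus's flanking (non-repeat) amplicon length. Exactly invertible; repeat
#' counts may be fractional for off-grid sizes.
#'
#' @param size Fragment size(s) in bp.
#' @param marker One row of a `marker_panel`.
#' @param offset Flanking length in bp.
#' @return Repeat count(s); see also [infer_offsets()] to calibrate `offset`
#'   so that the modal allele maps to the marker's reference repeat count.
#' @export
size_to_repeats <- function(size, marker, offset) {
  r <- (size - offset) / nchar(marker$motif)
  if (any(r < 0, na.rm = TRUE)) stop("negative repeat count for marker ", marker$name)
  r
}

#' @rdname size_to_repeats
#' @param repeats Repeat count(s).
#' @export
repeats_to_size <- function(repeats, marker, offset) {
  offset + repeats * nchar(marker$motif)
}

#' Infer per-locus flanking offsets from the data
#'
#' Chooses each locus's offset so that its modal (most frequent) allele size
#' maps exactly to the panel's reference repeat count.
#'
#' @param x A `genotype_table` with fragment-size calls.
#' @return Named numeric vector of offsets (bp) per locus.
#' @export
infer_offsets <- function(x) {
  vapply(seq_len(n_loci(x)), function(j) {
    v <- c(x$a1[, j], x$a2[, j]); v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    modal <- as.numeric(names(which.max(table(v))))
    modal - x$panel$ref_repeats[j] * nchar(x$panel$motif[j])
  }, 0)
}

#' Convert a whole table from sizes to repeat counts
#'
#' @param x A `genotype_table` with fragment-size calls.
#' @param offsets Named per-locus offsets (default from [infer_offsets()]).
#' @return A `genotype_table` whose values are repeat counts.
#' @export
table_to_repeats <- function(x, offsets = infer_offsets(x)) {
  for (j in seq_len(n_loci(x))) {
    mlen <- nchar(x$panel$motif[j])
    x$a1[, j] <- (x$a1[, j] - offsets[j]) / mlen
    x$a2[, j] <- (x$a2[, j] - offsets[j]) / mlen
  }
  if (any(c(x$a1, x$a2) < 0, na.rm = TRUE)) stop("negative repeat count after conversion")
  x
}
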