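#' Genome specification for binned tracks
#'
#' Defines an ordered set of chromosomes, their lengths in bins, and the bin
#' size in bp. All binned containers (counts, log-ratios, scores) carry a
#' `genome_spec` so that operations can verify they are working on compatible
#' coordinate systems. Bin indices are 1-based and inclusive inside R;
#' exported BED/bedGraph records use 0-based half-open bp coordinates.
#'
#' @param chromosomes character vector of chromosome names (unique, ordered).
#' @param n_bins integer vector of chromosome lengths in bins (same length).
#' @param bin_size bin width in bp (single positive integer).
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(500, 300), bin_size = 10000)
#' @export
genome_spec <- function(chromosomes, n_bins, bin_size = 10000) {
  assert_that(is.character(chromosomes) && length(chromosomes) >= 1L &&
                !anyDuplicated(chromosomes),
              "`chromosomes` must be a non-empty vector of unique names")
  assert_that(length(n_bins) == length(chromosomes) && all(n_bins >= 1),
              "`n_bins` must match `chromosomes` with all lengths >= 1")
  assert_scalar_number(bin_size, "bin_size", lower = 1)
  structure(list(chromosomes = chromosomes,
                 n_bins = setNames(as.integer(n_bins), chromosomes),
                 bin_size = as.integer(bin_size)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), bin_size=%d bp, %d bins total\n",
              length(x$chromosomes), x$bin_size, sum(x$n_bins)))
  invisible(x)
}

same_genome <- function(a, b) {
  identical(a$chromosomes, b$chromosomes) &&
    identical(a$n_bins, b$n_bins) && identical(a$bin_size, b$bin_size)
}

#' Binned count track
#'
#' Integer read counts per genomic bin, one vector per chromosome of a
#' [genome_spec()].
#'
#' @param genome a `genome_spec`.
#' @param counts named list of non-negative integer vectors, one per
#'   chromosome, each of the chromosome's bin length.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(genome, counts) {
  assert_that(inherits(genome, "genome_spec"), "`genome` must be a genome_spec")
  assert_that(is.list(counts) && identical(names(counts), genome$chromosomes),
              "`counts` must be a list named exactly by the genome's chromosomes")
  for (chrom in genome$chromosomes) {
    v <- counts[[chrom]]
    assert_that(length(v) == genome$n_bins[[chrom]],
                sprintf("counts for %s must have %d bins", chrom,
                        genome$n_bins[[chrom]]))
    assert_that(all(v >= 0) && all(v == round(v)),
                sprintf("counts for %s must be non-negative integers", chrom))
    counts[[chrom]] <- as.integer(round(v))
  }
  structure(list(genome = genome, counts = counts), class = "binned_track")
}

track_total <- function(track) sum(vapply(track$counts, sum, numeric(1)))

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d bins, total count %.0f\n",
              sum(x$genome$n_bins), track_total(x)))
  invisible(x)
}

#' Log2 ChIP/input ratio track
#'
#' Real-valued log2 ratio per bin plus a mask for bins where the ratio is
#' undefined (both chip and input counts zero).
#'
#' @param genome a `genome_spec`.
#' @param ratio named list of numeric vectors per chromosome.
#' @param mask named list of logical vectors per chromosome (`TRUE` = masked).
#' @return An object of class `ratio_track`.
#' @export
ratio_track <- function(genome, ratio, mask) {
  structure(list(genome = genome, ratio = ratio, mask = mask),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  n <- sum(x$genome$n_bins)
  nm <- sum(vapply(x$mask, sum, numeric(1)))
  cat(sprintf("ratio_track: %d bins (%d masked)\n", n, nm))
  invisible(x)
}

# ---- file formats -----------------------------------------------------------

#' Write a binned track as bedGraph
#'
#' One line per bin, 0-based half-open bp coordinates, optionally preceded by
#' `#` header comments recording tool version, config hash and seed.
#'
#' @param track a `binned_track` (or `ratio_track`, written with masked bins
#'   omitted).
#' @param path output path.
#' @param header character vector of `#`-prefixed header lines (optional).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, header = character(0)) {
  g <- track$genome
  lines <- character(0)
  for (chrom in g$chromosomes) {
    n <- g$n_bins[[chrom]]
    start <- (seq_len(n) - 1L) * g$bin_size
    if (inherits(track, "ratio_track")) {
      keep <- !track$mask[[chrom]]
      val <- trimws(formatC(track$ratio[[chrom]][keep], format = "g", digits = 8))
      start <- start[keep]
    } else {
      val <- as.character(track$counts[[chrom]])
    }
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom, start,
                              start + g$bin_size, val))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a bedGraph file into a binned track
#'
#' The file must tile each chromosome of `genome` with fixed-width bins equal
#' to `genome$bin_size`; `#` comment and `track` lines are ignored.
#'
#' @param path bedGraph file path.
#' @param genome the `genome_spec` the track is defined on.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, genome) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  counts <- lapply(setNames(nm = genome$chromosomes), function(chrom) {
    sel <- gr[GenomicRanges::seqnames(gr) == chrom]
    v <- integer(genome$n_bins[[chrom]])
    if (length(sel)) {
      bin <- (GenomicRanges::start(sel) - 1L) %/% genome$bin_size + 1L
      ok <- bin >= 1L & bin <= length(v)
      v[bin[ok]] <- as.integer(round(S4Vectors::mcols(sel)$score[ok]))
    }
    v
  })
  binned_track(genome, counts)
}

#' Write intervals as BED
#'
#' @param df data.frame with columns `chrom`, `start`, `end` in bp (0-based
#'   half-open) and optionally `name` and `score`.
#' @param path output path.
#' @param header character vector of `#` header lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, header = character(0)) {
  name <- if ("name" %in% names(df)) df$name else "."
  cols <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                  as.integer(df$end), name)
  if ("score" %in% names(df)) {
    cols <- sprintf("%s\t%s", cols,
                    trimws(formatC(df$score, format = "g", digits = 8)))
  }
  writeLines(c(header, cols), path)
  invisible(path)
}

#' Read a BED (3+) file of named intervals
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (bp, 0-based half-open)
#'   and `name`.
#' @export
read_bed <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep(".", length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}

# Convert a bin-indexed interval data.frame (1-based inclusive bins) to bp.
bins_to_bp <- function(df, genome) {
  data.frame(chrom = df$chrom,
             start = (df$start - 1L) * genome$bin_size,
             end = df$end * genome$bin_size,
             stringsAsFactors = FALSE)
}
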