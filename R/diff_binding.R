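#' Per-chromosome domain coverage profile
#'
#' Fraction of each chromosome's bins covered by called domains; with a
#' second domain set, also the coverage difference (B - A), the summary used
#' to describe chromosome-scale redistribution of Lamin B1 binding.
#'
#' @param domains data.frame of domains (`chrom`, `start`, `end` bins).
#' @param genome the `genome_spec`.
#' @param domains_b optional second condition's domains.
#' @return data.frame with `chrom`, `n_bins`, `covered`, `fraction` and,
#'   when `domains_b` is given, `covered_b`, `fraction_b`, `delta`.
#' @export
chromosome_binding_profile <- function(domains, genome, domains_b = NULL) {
  cover <- function(dom) {
    assert_that(all(dom$chrom %in% genome$chromosomes),
                "domains reference chromosomes absent from the genome")
    vapply(genome$chromosomes, function(chrom) {
      d <- dom[dom$chrom == chrom, , drop = FALSE]
      if (!nrow(d)) return(0)
      assert_that(all(d$start >= 1) && all(d$end <= genome$n_bins[[chrom]]),
                  sprintf("domain outside bounds of %s", chrom))
      covered <- logical(genome$n_bins[[chrom]])
      for (i in seq_len(nrow(d))) covered[d$start[i]:d$end[i]] <- TRUE
      sum(covered)
    }, numeric(1))
  }
  res <- data.frame(chrom = genome$chromosomes,
                    n_bins = as.integer(genome$n_bins),
                    covered = as.integer(cover(domains)),
                    stringsAsFactors = FALSE)
  res$fraction <- res$covered / res$n_bins
  if (!is.null(domains_b)) {
    res$covered_b <- as.integer(cover(domains_b))
    res$fraction_b <- res$covered_b / res$n_bins
    res$delta <- res$fraction_b - res$fraction
  }
  rownames(res) <- NULL
  res
}

#' Detect canyons and mesas between two binding ratio tracks
#'
#' The delta track is `ratio_b - ratio_a` per bin (masked wherever either
#' input is masked). Canyons — areas of decreased binding in condition B —
#' are maximal runs of at least `min_width` consecutive bins with
#' `delta <= -delta_threshold`; mesas (increased binding) are the symmetric
#' runs with `delta >= +delta_threshold`. Working at bin level rather than
#' on domain calls lets a canyon be detected even when it sits inside a
#' larger region of increased binding.
#'
#' @param ratio_a,ratio_b `ratio_track`s on the same genome (A = baseline).
#' @param delta_threshold minimum absolute mean log2-ratio change.
#' @param min_width minimum run length in bins.
#' @return data.frame with `chrom`, `start`, `end` (bins, 1-based
#'   inclusive), `type` (`"canyon"`/`"mesa"`), `mean_delta`, `width`.
#' @export
detect_canyons_mesas <- function(ratio_a, ratio_b, delta_threshold = 0.5,
                                 min_width = 3) {
  assert_that(inherits(ratio_a, "ratio_track") && inherits(ratio_b, "ratio_track"),
              "`ratio_a` and `ratio_b` must be ratio_tracks")
  assert_that(same_genome(ratio_a$genome, ratio_b$genome),
              "`ratio_a` and `ratio_b` are on different genome specifications")
  assert_that(delta_threshold > 0, "`delta_threshold` must be > 0")
  assert_that(min_width >= 1, "`min_width` must be >= 1")
  out <- list()
  for (chrom in ratio_a$genome$chromosomes) {
    delta <- ratio_b$ratio[[chrom]] - ratio_a$ratio[[chrom]]
    masked <- ratio_a$mask[[chrom]] | ratio_b$mask[[chrom]]
    state <- rep("none", length(delta))
    state[!masked & delta <= -delta_threshold] <- "canyon"
    state[!masked & delta >= delta_threshold] <- "mesa"
    runs <- rle(state)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != "none" & runs$lengths >= min_width
    for (i in which(keep)) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = starts[i], end = ends[i],
        type = runs$values[i], mean_delta = mean(delta[idx]),
        width = runs$lengths[i], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), type = character(0),
                         mean_delta = numeric(0), width = integer(0))
  rownames(res) <- NULL
  res
}

# Total overlap in bp between two interval sets on one chromosome
# (half-open coordinates; the first set must be internally disjoint).
interval_overlap_bp <- function(s1, e1, s2, e2) {
  if (!length(s1) || !length(s2)) return(0)
  lo <- outer(s1, s2, pmax)
  hi <- outer(e1, e2, pmin)
  sum(pmax(0, hi - lo))
}

regions_to_granges <- function(regions, genome, in_bins = TRUE) {
  if (!nrow(regions)) {
    return(GenomicRanges::GRanges())
  }
  if (in_bins) {
    bp <- bins_to_bp(regions, genome)
  } else {
    bp <- regions[, c("chrom", "start", "end")]
  }
  GenomicRanges::GRanges(bp$chrom,
                         IRanges::IRanges(start = bp$start + 1L, end = bp$end))
}

#' Overlap called regions with an annotation set
#'
#' Overlap in bp and Jaccard index between a region set (domains or
#' canyons/mesas, bin coordinates) and annotated intervals (bp, BED
#' semantics), plus a circular-permutation enrichment test: regions are
#' rotated within their chromosome by uniform random offsets `n_perm` times,
#' preserving their lengths and spacing; enrichment is observed / mean
#' permuted overlap and the empirical p-value is
#' `(1 + #permutations >= observed) / (n_perm + 1)`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` in bin indices
#'   (1-based inclusive), e.g. from [maximal_segments()] or
#'   [detect_canyons_mesas()].
#' @param annotation data.frame with `chrom`, `start`, `end` in bp (0-based
#'   half-open) and optional `name`, e.g. from [read_bed()].
#' @param genome the `genome_spec` of the regions.
#' @param n_perm number of circular permutations.
#' @param seed integer seed.
#' @return List of class `overlap_report`: `overlap_bp`, `jaccard`,
#'   `enrichment`, `expected_bp`, `p`, `per_annotation` (data.frame with
#'   per-interval overlap and Jaccard).
#' @export
overlap_annotation <- function(regions, annotation, genome, n_perm = 1000,
                               seed = NULL) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    return(structure(list(overlap_bp = 0, jaccard = 0, enrichment = NA_real_,
                          expected_bp = NA_real_, p = NA_real_,
                          per_annotation = NULL), class = "overlap_report"))
  }
  assert_that(all(annotation$start < annotation$end),
              "annotation intervals must have start < end")
  assert_that(all(annotation$chrom %in% genome$chromosomes),
              "annotation references chromosomes absent from the genome")
  ann_gr <- regions_to_granges(annotation, genome, in_bins = FALSE)
  reg_gr <- GenomicRanges::reduce(regions_to_granges(regions, genome))
  ovl <- function(gr) {
    sum(IRanges::width(GenomicRanges::intersect(gr, ann_gr,
                                                ignore.strand = TRUE)))
  }
  obs <- ovl(reg_gr)
  union_bp <- sum(IRanges::width(GenomicRanges::reduce(c(reg_gr, ann_gr))))
  jaccard <- if (union_bp > 0) obs / union_bp else 0
  nm <- if ("name" %in% names(annotation)) annotation$name
        else sprintf("ann%02d", seq_len(nrow(annotation)))
  per_ann <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(i) {
    one <- regions_to_granges(annotation[i, , drop = FALSE], genome,
                              in_bins = FALSE)
    o <- sum(IRanges::width(GenomicRanges::intersect(reg_gr, one,
                                                     ignore.strand = TRUE)))
    # Jaccard against the regions that intersect this locus, so recovery of
    # one annotation is not diluted by calls elsewhere in the genome
    hit <- reg_gr[IRanges::overlapsAny(reg_gr, one)]
    u <- sum(IRanges::width(GenomicRanges::reduce(c(hit, one))))
    data.frame(name = nm[i], chrom = annotation$chrom[i],
               start = annotation$start[i], end = annotation$end[i],
               overlap_bp = o, jaccard = if (u > 0) o / u else 0,
               stringsAsFactors = FALSE)
  }))
  perm_ovl <- if (length(reg_gr) == 0) rep(0, n_perm) else {
    reg_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(reg_gr)),
      start = GenomicRanges::start(reg_gr) - 1L,
      end = GenomicRanges::end(reg_gr), stringsAsFactors = FALSE)
    chrom_bp <- genome$n_bins * genome$bin_size
    chroms <- unique(reg_df$chrom)
    by_chrom <- lapply(setNames(nm = chroms), function(chrom) {
      list(s = reg_df$start[reg_df$chrom == chrom],
           e = reg_df$end[reg_df$chrom == chrom],
           as = annotation$start[annotation$chrom == chrom],
           ae = annotation$end[annotation$chrom == chrom],
           L = chrom_bp[[chrom]])
    })
    with_seed_if(seed, vapply(seq_len(n_perm), function(r) {
      total <- 0
      for (d in by_chrom) {
        if (!length(d$as)) next
        off <- floor(runif(1, 0, d$L))
        s <- (d$s + off) %% d$L
        e <- s + (d$e - d$s)
        wrap <- e > d$L
        rs <- c(s, rep(0, sum(wrap)))
        re <- c(pmin(e, d$L), e[wrap] - d$L)
        total <- total + interval_overlap_bp(rs, re, d$as, d$ae)
      }
      total
    }, numeric(1)))
  }
  expected <- mean(perm_ovl)
  structure(list(
    overlap_bp = obs,
    jaccard = jaccard,
    enrichment = if (expected > 0) obs / expected else NA_real_,
    expected_bp = expected,
    p = (1 + sum(perm_ovl >= obs)) / (n_perm + 1),
    per_annotation = per_ann), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %d bp overlap, Jaccard %.3f, enrichment %.3g, p = %.3g\n",
              x$overlap_bp, x$jaccard, x$enrichment, x$p))
  invisible(x)
}

#' Locus-level binding fold change between two ratio tracks
#'
#' Mean linear-scale binding ratio over the interval in each condition,
#' reported as `mean(2^ratio_a) / mean(2^ratio_b)`: values above 1 are an
#' x-fold reduction of binding in condition B relative to A.
#'
#' @param ratio_a,ratio_b `ratio_track`s on the same genome.
#' @param interval one-row data.frame (or list) with `chrom`, `start`, `end`
#'   in bp (0-based half-open); all bins overlapping the interval are used.
#' @return List of class `locus_fold_change`: `fold` (A over B),
#'   `direction` (`"reduction"`/`"increase"`/`"none"`), `n_bins`,
#'   `mean_linear_a`, `mean_linear_b`; `fold` is `NA` (flagged `undefined`)
#'   when every overlapping bin is masked.
#' @export
locus_fold_change <- function(ratio_a, ratio_b, interval) {
  assert_that(same_genome(ratio_a$genome, ratio_b$genome),
              "`ratio_a` and `ratio_b` are on different genome specifications")
  interval <- as.list(interval)
  chrom <- interval$chrom
  assert_that(chrom %in% ratio_a$genome$chromosomes,
              sprintf("unknown chromosome '%s'", chrom))
  bs <- ratio_a$genome$bin_size
  first <- floor(interval$start / bs) + 1
  last <- ceiling(interval$end / bs)
  assert_that(first >= 1 && last <= ratio_a$genome$n_bins[[chrom]] &&
                first <= last, "interval outside genome bounds")
  idx <- first:last
  ok <- !(ratio_a$mask[[chrom]][idx] | ratio_b$mask[[chrom]][idx])
  if (!any(ok)) {
    return(structure(list(fold = NA_real_, direction = "undefined",
                          n_bins = 0L, mean_linear_a = NA_real_,
                          mean_linear_b = NA_real_),
                     class = "locus_fold_change"))
  }
  a <- mean(2^ratio_a$ratio[[chrom]][idx][ok])
  b <- mean(2^ratio_b$ratio[[chrom]][idx][ok])
  fold <- a / b
  structure(list(fold = fold,
                 direction = if (fold > 1) "reduction"
                             else if (fold < 1) "increase" else "none",
                 n_bins = sum(ok), mean_linear_a = a, mean_linear_b = b),
            class = "locus_fold_change")
}

#' @export
print.locus_fold_change <- function(x, ...) {
  if (is.na(x$fold)) {
    cat("locus_fold_change: undefined (all bins masked)\n")
  } else {
    cat(sprintf("locus_fold_change: %.3g-fold %s over %d bins\n",
                if (x$fold >= 1) x$fold else 1 / x$fold, x$direction,
                x$n_bins))
  }
  invisible(x)
}
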