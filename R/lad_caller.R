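#' Match sequencing depth between ChIP and input tracks
#'
#' The deeper of the two tracks is subsampled without replacement
#' (multivariate hypergeometric across all bins of the genome) so that both
#' totals equal `min(total_chip, total_input)` exactly; the shallower track
#' passes through unchanged. Subsampling reads rather than rescaling keeps
#' counts integral and preserves per-bin proportions in expectation,
#' mirroring read-level downsampling of the larger library.
#'
#' @param chip,input `binned_track`s on the same `genome_spec`.
#' @param seed integer seed.
#' @return List with depth-matched `chip` and `input` tracks.
#' @export
match_depth <- function(chip, input, seed = NULL) {
  assert_that(inherits(chip, "binned_track") && inherits(input, "binned_track"),
              "`chip` and `input` must be binned_tracks")
  assert_that(same_genome(chip$genome, input$genome),
              "`chip` and `input` are on different genome specifications")
  t_chip <- track_total(chip)
  t_input <- track_total(input)
  if (t_chip == t_input) return(list(chip = chip, input = input))
  target <- min(t_chip, t_input)
  deeper <- if (t_chip > t_input) chip else input
  thinned <- with_seed_if(seed, thin_track(deeper, target))
  if (t_chip > t_input) list(chip = thinned, input = input)
  else list(chip = chip, input = thinned)
}

# Draw a multivariate hypergeometric sample: `target` reads kept out of the
# track's total, sequentially bin by bin.
thin_track <- function(track, target) {
  counts <- unlist(track$counts, use.names = FALSE)
  remaining <- target
  left <- sum(counts)
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (remaining == 0L) break
    ci <- counts[i]
    out[i] <- rhyper(1L, ci, left - ci, remaining)
    remaining <- remaining - out[i]
    left <- left - ci
  }
  counts_list <- split(out, rep(seq_along(track$counts),
                                lengths(track$counts)))
  names(counts_list) <- names(track$counts)
  binned_track(track$genome, counts_list)
}

#' Compute the per-bin log2 ChIP/input ratio
#'
#' `log2((chip + pseudocount) / (input + pseudocount))` per bin; bins where
#' both counts are zero carry no evidence and are masked.
#'
#' @param chip,input depth-matched `binned_track`s.
#' @param pseudocount positive stabiliser added to both counts.
#' @return A `ratio_track`.
#' @export
compute_log_ratio <- function(chip, input, pseudocount = 1) {
  assert_that(same_genome(chip$genome, input$genome),
              "`chip` and `input` are on different genome specifications")
  assert_that(is.numeric(pseudocount) && length(pseudocount) == 1 &&
                pseudocount > 0, "`pseudocount` must be > 0")
  g <- chip$genome
  ratio <- mask <- list()
  for (chrom in g$chromosomes) {
    c_i <- chip$counts[[chrom]]
    i_i <- input$counts[[chrom]]
    ratio[[chrom]] <- log2((c_i + pseudocount) / (i_i + pseudocount))
    mask[[chrom]] <- c_i == 0L & i_i == 0L
  }
  ratio_track(g, ratio, mask)
}

#' Discretise a ratio track into segment scores
#'
#' Bins at or above the threshold score `+1`, all others (including masked
#' bins) score `-gap_penalty`. The threshold is either given directly or as a
#' genome-wide percentile of the unmasked ratios (linear-interpolation
#' percentile). Masked bins can be absorbed into a domain by strong flanks
#' but can never seed one.
#'
#' @param ratio a `ratio_track`.
#' @param threshold numeric log2-ratio cutoff, or `NULL` to use `percentile`.
#' @param percentile genome-wide percentile (0-100) of unmasked ratios used
#'   when `threshold` is `NULL`. The default (66.7) treats the top third of
#'   bins as lamina-associated candidates.
#' @param gap_penalty positive penalty `g` for sub-threshold bins.
#' @return A `score_track`: per-chromosome scores in `{+1, -g}` plus the
#'   resolved `threshold` and `gap_penalty`.
#' @export
score_bins <- function(ratio, threshold = NULL, percentile = 66.7,
                       gap_penalty = 3) {
  assert_that(inherits(ratio, "ratio_track"), "`ratio` must be a ratio_track")
  assert_that(is.numeric(gap_penalty) && length(gap_penalty) == 1 &&
                gap_penalty > 0, "`gap_penalty` must be > 0")
  if (is.null(threshold)) {
    assert_scalar_number(percentile, "percentile", lower = 0, upper = 100)
    vals <- unlist(ratio$ratio, use.names = FALSE)
    masked <- unlist(ratio$mask, use.names = FALSE)
    assert_that(any(!masked), "all bins are masked; no threshold can be set")
    threshold <- unname(quantile(vals[!masked], percentile / 100, type = 7))
  }
  scores <- lapply(setNames(nm = ratio$genome$chromosomes), function(chrom) {
    s <- ifelse(!ratio$mask[[chrom]] & ratio$ratio[[chrom]] >= threshold,
                1, -gap_penalty)
    s
  })
  structure(list(genome = ratio$genome, scores = scores,
                 threshold = threshold, gap_penalty = gap_penalty),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  np <- sum(vapply(x$scores, function(s) sum(s > 0), numeric(1)))
  cat(sprintf("score_track: threshold %.4g, gap penalty %g, %d/%d positive bins\n",
              x$threshold, x$gap_penalty, np, sum(x$genome$n_bins)))
  invisible(x)
}

# All maximal scoring subsequences of a numeric vector (Ruzzo-Tompa).
# Returns a data.frame(start, end, score) with 1-based inclusive indices,
# sorted by coordinate; segments are disjoint and each starts/ends on a
# positive score. Ties (an extension with equal score) do not merge.
rt_maximal_segments <- function(x) {
  n <- length(x)
  starts <- ends <- Ls <- Rs <- numeric(0)
  k <- 0L
  cum <- 0
  i <- 1L
  while (i <= n) {
    if (x[i] <= 0) {
      cum <- cum + x[i]
      i <- i + 1L
      next
    }
    L <- cum
    j <- i
    while (j <= n && x[j] > 0) {
      cum <- cum + x[j]
      j <- j + 1L
    }
    seg_start <- i; seg_end <- j - 1L; seg_L <- L; seg_R <- cum
    i <- j
    repeat {
      idx <- k
      while (idx >= 1L && Ls[idx] >= seg_L) idx <- idx - 1L
      if (idx == 0L || Rs[idx] >= seg_R) {
        k <- k + 1L
        starts[k] <- seg_start; ends[k] <- seg_end
        Ls[k] <- seg_L; Rs[k] <- seg_R
        break
      }
      # merge leftward: segment idx extends to absorb everything up to here
      seg_start <- starts[idx]
      seg_L <- Ls[idx]
      k <- idx - 1L
      length(starts) <- length(ends) <- length(Ls) <- length(Rs) <- k
    }
  }
  data.frame(start = as.integer(starts[seq_len(k)]),
             end = as.integer(ends[seq_len(k)]),
             score = Rs[seq_len(k)] - Ls[seq_len(k)])
}

# Maximum segment score of a numeric vector (single best subarray), used for
# the permutation null. Vectorised Kadane via cumulative sums.
max_segment_score <- function(x) {
  cs <- cumsum(x)
  max(cs - cummin(c(0, cs[-length(cs)])))
}

#' Find all maximal-scoring segments of a score track
#'
#' Classic all-maximal-scoring-subsequences decomposition per chromosome: a
#' reported segment is a contiguous run with positive total score that
#' cannot be improved by extension or trimming and is not contained in a
#' higher-scoring overlapping segment. These segments are the candidate
#' lamina-associated domains.
#'
#' @param scores a `score_track` (or a plain numeric vector for one
#'   chromosome).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive bin
#'   indices), `score`; segments on a chromosome are disjoint and sorted.
#' @examples
#' maximal_segments(c(1, -2, 1, 1, -2, 1, 1, 1, -2))
#' @export
maximal_segments <- function(scores) {
  if (is.numeric(scores)) {
    seg <- rt_maximal_segments(scores)
    return(cbind(chrom = rep("seq", nrow(seg)), seg))
  }
  assert_that(inherits(scores, "score_track"),
              "`scores` must be a score_track or numeric vector")
  segs <- lapply(scores$genome$chromosomes, function(chrom) {
    seg <- rt_maximal_segments(scores$scores[[chrom]])
    if (nrow(seg)) cbind(chrom = chrom, seg) else NULL
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs)) {
    segs <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), score = numeric(0))
  }
  rownames(segs) <- NULL
  segs
}

#' Assign permutation significance to candidate domains
#'
#' Bin scores are permuted uniformly within each chromosome `n_perm` times;
#' a domain's empirical p-value is
#' `(1 + #permutations whose maximal segment score >= observed) / (n_perm + 1)`,
#' with Benjamini-Hochberg adjustment across all domains. Permuting within
#' chromosomes respects each chromosome's own score composition, so
#' chromosome-scale binding shifts do not leak into the null.
#'
#' @param scores the `score_track` the domains were called from.
#' @param domains data.frame from [maximal_segments()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return `domains` with added `p` and `q` columns.
#' @export
assign_significance <- function(scores, domains, n_perm = 1000, seed = NULL) {
  assert_that(inherits(scores, "score_track"), "`scores` must be a score_track")
  assert_that(is.numeric(n_perm) && n_perm >= 100,
              "`n_perm` must be at least 100")
  n_perm <- as.integer(n_perm)
  if (nrow(domains) == 0) {
    domains$p <- numeric(0)
    domains$q <- numeric(0)
    return(domains)
  }
  null_max <- with_seed_if(seed, {
    lapply(setNames(nm = unique(domains$chrom)), function(chrom) {
      x <- scores$scores[[chrom]]
      vapply(seq_len(n_perm),
             function(r) max_segment_score(sample(x)), numeric(1))
    })
  })
  domains$p <- vapply(seq_len(nrow(domains)), function(i) {
    nm <- null_max[[domains$chrom[i]]]
    (1 + sum(nm >= domains$score[i])) / (n_perm + 1)
  }, numeric(1))
  domains$q <- p.adjust(domains$p, method = "BH")
  domains
}

#' Call lamina-associated domains from ChIP and input tracks
#'
#' Convenience wrapper chaining [match_depth()], [compute_log_ratio()],
#' [score_bins()], [maximal_segments()] and [assign_significance()].
#'
#' @param chip,input `binned_track`s.
#' @param pseudocount see [compute_log_ratio()].
#' @param threshold,percentile,gap_penalty see [score_bins()].
#' @param n_perm,seed see [assign_significance()].
#' @param q_threshold domains with `q` below this are flagged `significant`.
#' @return List with `domains` (data.frame incl. `p`, `q`, `significant`),
#'   `ratio` (the `ratio_track`) and `scores` (the `score_track`).
#' @export
call_lads <- function(chip, input, pseudocount = 1, threshold = NULL,
                      percentile = 66.7, gap_penalty = 3, n_perm = 2000,
                      q_threshold = 0.05, seed = NULL) {
  matched <- match_depth(chip, input, seed = if (is.null(seed)) NULL
                         else seed + 1L)
  ratio <- compute_log_ratio(matched$chip, matched$input, pseudocount)
  scores <- score_bins(ratio, threshold = threshold, percentile = percentile,
                       gap_penalty = gap_penalty)
  domains <- maximal_segments(scores)
  domains <- assign_significance(scores, domains, n_perm = n_perm,
                                 seed = if (is.null(seed)) NULL else seed + 2L)
  domains$significant <- domains$q < q_threshold
  list(domains = domains, ratio = ratio, scores = scores)
}
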