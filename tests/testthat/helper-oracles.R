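# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate a sequence at `k` random positions (substitutions only).
mutate_seq <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(length(b), k)
  for (j in pos) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
  paste(b, collapse = "")
}

# Position-wise substitution oracle for equal-length, gap-free pairs.
oracle_substitutions <- function(ref, clone) {
  rb <- strsplit(ref, "")[[1]]
  cb <- strsplit(clone, "")[[1]]
  mm <- which(rb != cb)
  data.frame(ref_position = mm, ref_base = rb[mm], alt_base = cb[mm])
}

# Exhaustive motif-string scan for hotspot labels: enumerate all 8 WRCY and
# all 8 RGYW words and locate them with gregexpr, labelling the mutable C/G.
oracle_hotspots <- function(seqs) {
  expand_words <- function(classes) {
    apply(expand.grid(classes, stringsAsFactors = FALSE), 1, paste,
          collapse = "")
  }
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  wrcy_words <- expand_words(list(W, R, "C", Y))
  rgyw_words <- expand_words(list(R, "G", Y, W))
  hit_positions <- function(words, offset) {
    hits <- vector("list", length(seqs))
    for (w in words) {
      # lookahead so overlapping occurrences of the same word are found
      m <- gregexpr(paste0("(?=", w, ")"), seqs, perl = TRUE)
      for (i in seq_along(seqs)) {
        p <- m[[i]]
        if (p[1] != -1) hits[[i]] <- c(hits[[i]], as.integer(p) + offset)
      }
    }
    hits
  }
  wrcy_hits <- hit_positions(wrcy_words, 2L)  # C is the 3rd base
  rgyw_hits <- hit_positions(rgyw_words, 1L)  # G is the 2nd base
  lapply(seq_along(seqs), function(i) {
    lab <- rep("none", nchar(seqs[i]))
    lab[unique(rgyw_hits[[i]])] <- "RGYW"
    lab[unique(wrcy_hits[[i]])] <- "WRCY"
    lab
  })
}

# Brute-force global affine alignment score by exhaustive recursion
# (tiny strings only). Gap of length L costs gap_open + L * gap_extend.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -4, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    # state: 0 = last column was base-base, 1 = gap in a, 2 = gap in b
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (j <= length(bv)) {  # gap in a (consume b)
      pen <- gap_extend + if (state == 1) 0 else gap_open
      best <- max(best, pen + rec(i, j + 1, 1))
    }
    if (i <= length(av)) {  # gap in b (consume a)
      pen <- gap_extend + if (state == 2) 0 else gap_open
      best <- max(best, pen + rec(i + 1, j, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# Brute-force all-maximal-scoring-segments by interval enumeration over
# cumulative sums. With cs[t + 1] = sum(x[1..t]), call [i, j] "proper" when
# trimming strictly decreases its score, i.e. every cumulative level inside
# lies strictly above the start level (all suffixes score less) and the end
# level lies strictly above every earlier level in the span (all prefixes
# score less). The maximal scoring segments are exactly the proper intervals
# not strictly contained in another proper interval.
oracle_maximal_segments <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  starts <- integer(0)
  ends <- integer(0)
  for (i in 1:n) {
    S0 <- cs[i]
    interior_max <- S0              # max level over cs[i .. j]
    for (j in i:n) {
      S1 <- cs[j + 1]
      if (S1 <= S0) break           # some suffix would score >= whole
      if (S1 > interior_max) {      # end level clears all previous levels
        starts <- c(starts, i)
        ends <- c(ends, j)
      }
      interior_max <- max(interior_max, S1)
    }
  }
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  # containment-maximal sweep: order by (start asc, end desc); an interval is
  # strictly contained iff an earlier one in this order reaches at least as
  # far right
  ord <- order(starts, -ends)
  starts <- starts[ord]; ends <- ends[ord]
  keep <- logical(length(starts))
  max_end <- -Inf
  for (k in seq_along(starts)) {
    if (ends[k] > max_end) {
      keep[k] <- TRUE
      max_end <- ends[k]
    }
  }
  df <- data.frame(start = starts[keep], end = ends[keep])
  df$score <- cs[df$end + 1] - cs[df$start]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# One-chromosome genome and ratio-track builders for hand-constructed cases.
toy_genome <- function(n_bins, bin_size = 1, chrom = "chr1") {
  genome_spec(chrom, n_bins, bin_size = bin_size)
}

toy_ratio <- function(values, bin_size = 1, mask = NULL, chrom = "chr1") {
  g <- toy_genome(length(values), bin_size, chrom)
  if (is.null(mask)) mask <- rep(FALSE, length(values))
  ratio_track(g, setNames(list(values), chrom), setNames(list(mask), chrom))
}

toy_counts <- function(values, bin_size = 1, chrom = "chr1") {
  g <- toy_genome(length(values), bin_size, chrom)
  binned_track(g, setNames(list(values), chrom))
}

# Reduced pipeline configuration for fast end-to-end tests.
small_config <- function(seed = 1) {
  config <- default_config(seed)
  config$shm$n_clones <- 18            # 18 x 565 bp > 10,000 bp rule
  config$shm$conditions <- config$shm$conditions[c("unstimulated",
                                                   "stimulated")]
  config$genome$n_bins <- c(150, 150, 150, 150)
  config$tracks$domains <- list(
    list(chrom = "chr1", start = 31, end = 55,
         enrichment = list(control = 6, shm_induced = 2)),
    list(chrom = "chr2", start = 61, end = 90,
         enrichment = list(control = 4, shm_induced = 4)),
    list(chrom = "chr3", start = 11, end = 40,
         enrichment = list(control = 6, shm_induced = 2)),
    list(chrom = "chr4", start = 101, end = 130,
         enrichment = list(control = 1, shm_induced = 4)))
  config$tracks$ig_clusters <- list(
    list(name = "IGH_synthetic", chrom = "chr1", start = 31, end = 55),
    list(name = "IGL_synthetic", chrom = "chr3", start = 11, end = 40))
  config$lads$n_perm <- 2000
  config$diff$n_perm <- 200
  config
}
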