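#' Generate a random reference amplicon
#'
#' Produces a reference V-region sequence with i.i.d. bases at a target GC
#' content, standing in for a cloned immunoglobulin V-gene amplicon (the
#' default length matches the 565 bp reporter fragment analysed by the SHM
#' module).
#'
#' @param length sequence length in bp (>= 4).
#' @param gc target GC fraction in \[0, 1\]; G and C (and A and T) are
#'   equiprobable within their class.
#' @param seed integer seed; the same (length, gc, seed) always yields the
#'   same sequence.
#' @param id sequence identifier.
#' @return A list of class `reference_sequence` with fields `id` and `seq`.
#' @examples
#' ref <- generate_reference(565, gc = 0.5, seed = 7)
#' nchar(ref$seq)
#' @export
generate_reference <- function(length = 565, gc = 0.5, seed = NULL,
                               id = "Vref") {
  assert_scalar_number(length, "length", lower = 4)
  assert_scalar_number(gc, "gc", lower = 0, upper = 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_seed_if(seed, paste(
    sample(DNA_BASES, size = as.integer(length), replace = TRUE, prob = p),
    collapse = ""))
  structure(list(id = id, seq = seq), class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("reference_sequence %s: %d bp, GC %.3f\n", x$id, nchar(x$seq),
              gc_fraction(x$seq)))
  invisible(x)
}

gc_fraction <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  mean(b %in% c("G", "C"))
}

as_reference <- function(ref) {
  if (inherits(ref, "reference_sequence")) {
    ref$seq <- assert_dna(ref$seq, "ref$seq")
    return(ref)
  }
  structure(list(id = "ref", seq = assert_dna(ref, "ref")),
            class = "reference_sequence")
}

#' Parameters of the AID-biased substitution model
#'
#' Each clone acquires independent per-site substitutions: non-hotspot
#' positions mutate with probability `mu_background` per bp, positions inside
#' an AID hotspot (the C of WRCY or the G of RGYW on the reference, see
#' [classify_hotspot()]) with probability `hotspot_multiplier * mu_background`.
#' When `aid_active` is `FALSE` every rate is multiplied by
#' `aid_null_multiplier`, emulating the near-complete loss of both background
#' and induced mutation in AID-deficient cells. The substituted base is drawn
#' from the row of `spectrum_weights` for the reference base.
#'
#' @param mu_background substitutions per bp per clone at non-hotspot sites.
#' @param hotspot_multiplier rate multiplier (>= 1) at AID hotspot positions.
#' @param aid_active logical; `FALSE` models an AID-null background.
#' @param aid_null_multiplier residual rate fraction under AID loss.
#' @param indel_rate per-bp probability of a single-base indel (default 0;
#'   events are 1 bp deletions or insertions with equal probability).
#' @param spectrum_weights 4x4 non-negative matrix (rows/cols A,C,G,T, zero
#'   diagonal); rows are renormalised over the three non-identity bases.
#'   Default is uniform; see [aid_spectrum_weights()] for a deamination-biased
#'   preset.
#' @return An object of class `shm_params`.
#' @export
shm_params <- function(mu_background = 8e-4, hotspot_multiplier = 8,
                       aid_active = TRUE, aid_null_multiplier = 0.02,
                       indel_rate = 0, spectrum_weights = NULL) {
  assert_scalar_number(mu_background, "mu_background", lower = 0)
  assert_scalar_number(hotspot_multiplier, "hotspot_multiplier", lower = 1)
  assert_scalar_number(aid_null_multiplier, "aid_null_multiplier",
                       lower = 0, upper = 1)
  assert_scalar_number(indel_rate, "indel_rate", lower = 0, upper = 1)
  if (is.null(spectrum_weights)) {
    spectrum_weights <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    diag(spectrum_weights) <- 0
  }
  assert_that(is.matrix(spectrum_weights) &&
                all(dim(spectrum_weights) == c(4, 4)) &&
                all(spectrum_weights >= 0) &&
                all(diag(spectrum_weights) == 0) &&
                all(rowSums(spectrum_weights) > 0),
              "`spectrum_weights` must be a 4x4 non-negative matrix with zero diagonal and positive row sums")
  dimnames(spectrum_weights) <- list(DNA_BASES, DNA_BASES)
  structure(list(mu_background = mu_background,
                 hotspot_multiplier = hotspot_multiplier,
                 aid_active = isTRUE(aid_active),
                 aid_null_multiplier = aid_null_multiplier,
                 indel_rate = indel_rate,
                 spectrum_weights = spectrum_weights),
            class = "shm_params")
}

#' AID-like substitution spectrum preset
#'
#' Upweights C->T and G->A changes (cytidine deamination and its
#' complementary-strand read-out) relative to the other substitutions.
#'
#' @param deamination_weight weight of C->T and G->A relative to weight-1
#'   alternatives.
#' @return 4x4 weight matrix suitable for [shm_params()].
#' @export
aid_spectrum_weights <- function(deamination_weight = 4) {
  w <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(w) <- 0
  w["C", "T"] <- deamination_weight
  w["G", "A"] <- deamination_weight
  w
}

#' Expected hotspot fraction of substitutions under the model
#'
#' Closed form: with `n_h` hotspot positions among `n`, and hotspot rate
#' multiplier `h`, the expected fraction of substitutions falling in hotspots
#' is `n_h * h / (n_h * h + n - n_h)`.
#'
#' @param ref reference sequence (string or `reference_sequence`).
#' @param hotspot_multiplier the rate multiplier `h`.
#' @return Expected hotspot fraction in \[0, 1\].
#' @export
expected_hotspot_fraction <- function(ref, hotspot_multiplier) {
  ref <- as_reference(ref)
  n <- nchar(ref$seq)
  n_h <- sum(hotspot_labels(ref$seq) != "none")
  n_h * hotspot_multiplier / (n_h * hotspot_multiplier + n - n_h)
}

#' Simulate a clone set under the AID-biased SHM model
#'
#' Each clone is derived independently from the reference (no clonal
#' phylogeny, mirroring sequencing of independent bacterial colonies):
#' per-site Bernoulli substitutions at the hotspot-aware rates of
#' [shm_params()], then optional single-base indels. With `indel_rate = 0`
#' every clone has the reference length.
#'
#' @param ref reference (string or `reference_sequence`).
#' @param params an `shm_params` object.
#' @param n_clones number of clones (>= 1).
#' @param seed integer seed for full determinism.
#' @param condition label attached to the clone set.
#' @return A list of class `clone_set`: `ref`, `condition`, `clones`
#'   (named character vector), `params`.
#' @examples
#' ref <- generate_reference(565, seed = 1)
#' cs <- simulate_clones(ref, shm_params(mu_background = 1e-3), 10, seed = 2)
#' length(cs$clones)
#' @export
simulate_clones <- function(ref, params, n_clones, seed = NULL,
                            condition = "cond") {
  ref <- as_reference(ref)
  assert_that(inherits(params, "shm_params"), "`params` must be shm_params")
  assert_scalar_number(n_clones, "n_clones", lower = 1)
  n_clones <- as.integer(n_clones)
  bases <- strsplit(ref$seq, "")[[1]]
  n <- length(bases)
  hot <- hotspot_labels(ref$seq) != "none"
  rate <- ifelse(hot, params$hotspot_multiplier * params$mu_background,
                 params$mu_background)
  if (!params$aid_active) rate <- rate * params$aid_null_multiplier
  p_sub <- pmin(rate, 1)
  w <- params$spectrum_weights
  clones <- with_seed_if(seed, {
    vapply(seq_len(n_clones), function(i) {
      b <- bases
      mut <- which(runif(n) < p_sub)
      for (j in mut) {
        b[j] <- sample(DNA_BASES, 1L, prob = w[bases[j], ])
      }
      if (params$indel_rate > 0) {
        ev <- which(runif(n) < params$indel_rate)
        if (length(ev)) {
          del <- runif(length(ev)) < 0.5
          ins_base <- sample(DNA_BASES, length(ev), replace = TRUE)
          # apply right-to-left so earlier positions stay valid
          for (k in order(ev, decreasing = TRUE)) {
            j <- ev[k]
            b <- if (del[k]) b[-j] else append(b, ins_base[k], after = j)
          }
        }
      }
      paste(b, collapse = "")
    }, character(1))
  })
  names(clones) <- sprintf("%s_clone%03d", condition, seq_len(n_clones))
  structure(list(ref = ref, condition = condition, clones = clones,
                 params = params),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set '%s': %d clones of %s (%d bp reference)\n",
              x$condition, length(x$clones), x$ref$id, nchar(x$ref$seq)))
  invisible(x)
}

#' Write a clone set (or reference) to FASTA
#'
#' @param x a `clone_set` or `reference_sequence`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "reference_sequence")) {
    set <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  } else if (inherits(x, "clone_set")) {
    set <- Biostrings::DNAStringSet(x$clones)
  } else {
    set <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Plan of planted enrichment domains for track simulation
#'
#' @param domains data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive bin indices) and `enrichment` (> 0 multiplier applied to the
#'   ChIP mean inside the domain).
#' @param background_mean expected input (and out-of-domain ChIP) count per
#'   bin.
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @return An object of class `planted_domain_spec`.
#' @export
planted_domain_spec <- function(domains, background_mean = 20,
                                dispersion = 10) {
  assert_that(is.data.frame(domains) &&
                all(c("chrom", "start", "end", "enrichment") %in% names(domains)),
              "`domains` needs columns chrom, start, end, enrichment")
  assert_that(all(domains$enrichment > 0), "enrichment multipliers must be > 0")
  assert_that(all(domains$start >= 1) && all(domains$end >= domains$start),
              "domain bins must satisfy 1 <= start <= end")
  assert_scalar_number(background_mean, "background_mean", lower = 0)
  assert_that(is.numeric(dispersion) && length(dispersion) == 1 && dispersion > 0,
              "`dispersion` must be a positive number (Inf for Poisson)")
  structure(list(domains = domains, background_mean = background_mean,
                 dispersion = dispersion),
            class = "planted_domain_spec")
}

rcounts <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) rpois(n, mu)
  else rnbinom(n, mu = mu, size = dispersion)
}

#' Simulate ChIP and input binned count tracks with planted domains
#'
#' Input counts are drawn around the background mean in every bin; ChIP
#' counts use the background mean multiplied by the planted enrichment inside
#' each planned domain. Counts are negative binomial with the plan's
#' dispersion (Poisson in the `dispersion = Inf` limit).
#'
#' @param genome a `genome_spec`.
#' @param plan a `planted_domain_spec`; domains must lie within the genome and
#'   not overlap on a chromosome.
#' @param seed integer seed.
#' @return List with `chip` and `input` (`binned_track`s) and `truth`
#'   (data.frame of planted domains with `enrichment != 1`, bin coordinates).
#' @export
simulate_binding_tracks <- function(genome, plan, seed = NULL) {
  assert_that(inherits(genome, "genome_spec"), "`genome` must be a genome_spec")
  assert_that(inherits(plan, "planted_domain_spec"),
              "`plan` must be a planted_domain_spec")
  dom <- plan$domains
  assert_that(all(dom$chrom %in% genome$chromosomes),
              "planted domains reference unknown chromosomes")
  for (chrom in unique(dom$chrom)) {
    d <- dom[dom$chrom == chrom, , drop = FALSE]
    assert_that(all(d$end <= genome$n_bins[[chrom]]),
                sprintf("planted domain exceeds %s bounds", chrom))
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1) {
      assert_that(all(d$start[-1] > d$end[-nrow(d)]),
                  sprintf("planted domains overlap on %s", chrom))
    }
  }
  out <- with_seed_if(seed, {
    chip <- input <- list()
    for (chrom in genome$chromosomes) {
      n <- genome$n_bins[[chrom]]
      mu_chip <- rep(plan$background_mean, n)
      d <- dom[dom$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(d))) {
        idx <- d$start[i]:d$end[i]
        mu_chip[idx] <- plan$background_mean * d$enrichment[i]
      }
      input[[chrom]] <- rcounts(n, plan$background_mean, plan$dispersion)
      chip[[chrom]] <- rcounts(n, mu_chip, plan$dispersion)
    }
    list(chip = chip, input = input)
  })
  truth <- dom[dom$enrichment != 1, c("chrom", "start", "end", "enrichment")]
  truth$start <- as.integer(truth$start)
  truth$end <- as.integer(truth$end)
  rownames(truth) <- NULL
  list(chip = binned_track(genome, out$chip),
       input = binned_track(genome, out$input),
       truth = truth)
}
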