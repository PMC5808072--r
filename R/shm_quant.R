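# Vectorised hotspot labelling of every reference position.
# WRCY labels the C (position 3 of the motif), RGYW labels the G (position 2);
# RGYW is the reverse-complement presentation of WRCY on the opposite strand.
# Windows running past either sequence end never match; WRCY wins when a
# position could carry both labels.
hotspot_labels <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  W <- b %in% c("A", "T")
  R <- b %in% c("A", "G")
  Y <- b %in% c("C", "T")
  wrcy <- rgyw <- rep(FALSE, n)
  if (n >= 4) {
    j <- 3:(n - 1)                       # candidate C positions
    wrcy[j] <- b[j] == "C" & W[j - 2] & R[j - 1] & Y[j + 1]
    k <- 2:(n - 2)                       # candidate G positions
    rgyw[k] <- b[k] == "G" & R[k - 1] & Y[k + 1] & W[k + 2]
  }
  labels <- rep("none", n)
  labels[rgyw] <- "RGYW"
  labels[wrcy] <- "WRCY"                 # WRCY precedence
  labels
}

#' Classify a reference position as an AID hotspot
#'
#' A position is a `WRCY` hotspot when it is the C of a WRCY motif
#' (W = A/T, R = A/G, Y = C/T) and an `RGYW` hotspot when it is the G of an
#' RGYW motif — the same motif read on the opposite strand. AID deaminates
#' that cytidine, so only the mutable C/G of the motif is labelled. Motif
#' windows extending past either sequence end never match, and `WRCY` takes
#' precedence if both patterns apply.
#'
#' @param ref reference sequence (string or `reference_sequence`).
#' @param position 1-based position(s) in the reference.
#' @return Character vector of labels in `{"WRCY", "RGYW", "none"}`.
#' @examples
#' classify_hotspot("TACT", 3)  # the C of TACT -> "WRCY"
#' classify_hotspot("AGCT", 2)  # the G of AGCT -> "RGYW"
#' @export
classify_hotspot <- function(ref, position) {
  ref <- as_reference(ref)
  n <- nchar(ref$seq)
  assert_that(all(position >= 1 & position <= n),
              sprintf("`position` must be in [1, %d]", n))
  hotspot_labels(ref$seq)[position]
}

#' Globally align a clone against the reference amplicon
#'
#' Optimal Needleman-Wunsch global alignment with affine gaps (a gap of
#' length L costs `gap_open + L * gap_extend`). Clones are full-length
#' amplicons of the reference, so end-to-end alignment is appropriate.
#'
#' @param ref reference (string or `reference_sequence`).
#' @param clone clone sequence (ACGT string), or a named character vector /
#'   `clone_set` to align several clones at once.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (match positive; the others are penalties given as negative scores).
#' @param clone_id identifier used when `clone` is a single string.
#' @return A `clone_alignment` (or list of them for multiple clones) with
#'   fields `ref_id`, `clone_id`, `aligned_ref`, `aligned_clone`, `score`,
#'   `aligned_bp` (base-base columns), `substitutions` (see
#'   [call_substitutions()]), `n_indel_events`, `n_indel_bp`.
#' @examples
#' aln <- align_clone("ACGT", "ACTT")
#' aln$substitutions
#' @export
align_clone <- function(ref, clone, scoring = list(match = 1, mismatch = -1,
                                                   gap_open = -4,
                                                   gap_extend = -1),
                        clone_id = "clone") {
  ref <- as_reference(ref)
  if (inherits(clone, "clone_set")) clone <- clone$clones
  if (length(clone) > 1L) {
    ids <- names(clone)
    if (is.null(ids)) ids <- sprintf("clone%03d", seq_along(clone))
    alns <- align_clones(ref, clone, scoring, ids)
    return(alns)
  }
  align_clones(ref, setNames(clone, clone_id), scoring,
               clone_id)[[1]]
}

align_clones <- function(ref, clones, scoring, ids) {
  for (i in seq_along(clones)) clones[i] <- assert_dna(clones[[i]], "clone")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch)
  fit <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(unname(clones)),
    subject = Biostrings::DNAString(ref$seq),
    substitutionMatrix = sub_mat,
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend),
    type = "global")
  ap <- as.character(Biostrings::alignedPattern(fit))
  asub <- as.character(Biostrings::alignedSubject(fit))
  out <- lapply(seq_along(clones), function(i) {
    new_clone_alignment(ref$id, ids[i], asub[i], ap[i],
                        Biostrings::score(fit)[i])
  })
  names(out) <- ids
  out
}

# Build a clone_alignment from the gapped alignment strings.
new_clone_alignment <- function(ref_id, clone_id, aligned_ref, aligned_clone,
                                score) {
  rb <- strsplit(aligned_ref, "")[[1]]
  cb <- strsplit(aligned_clone, "")[[1]]
  ref_pos <- cumsum(rb != "-")          # reference coordinate per column
  both <- rb != "-" & cb != "-"
  mm <- both & rb != cb
  subs <- data.frame(ref_position = ref_pos[mm], ref_base = rb[mm],
                     alt_base = cb[mm], clone_id = rep(clone_id, sum(mm)),
                     stringsAsFactors = FALSE)
  gap_runs <- rle(rb == "-" | cb == "-")
  structure(list(ref_id = ref_id, clone_id = clone_id,
                 aligned_ref = aligned_ref, aligned_clone = aligned_clone,
                 score = score,
                 aligned_bp = sum(both),
                 substitutions = subs,
                 n_indel_events = sum(gap_runs$values),
                 n_indel_bp = sum(rb == "-") + sum(cb == "-")),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat(sprintf("clone_alignment %s vs %s: %d aligned bp, %d substitution(s), %d indel event(s)\n",
              x$clone_id, x$ref_id, x$aligned_bp, nrow(x$substitutions),
              x$n_indel_events))
  invisible(x)
}

#' Call substitutions from a clone alignment
#'
#' One substitution per mismatched base-base column, in reference
#' coordinates (1-based). Indel columns are excluded from substitutions and
#' tracked separately on the alignment.
#'
#' @param aln a `clone_alignment`, or the reference sequence when `clone` is
#'   also supplied (the pair is aligned first).
#' @param clone optional clone sequence.
#' @param ref reference used for hotspot labelling; defaults to
#'   reconstructing it from the alignment.
#' @return data.frame with `ref_position`, `ref_base`, `alt_base`,
#'   `clone_id`, `hotspot`.
#' @export
call_substitutions <- function(aln, clone = NULL, ref = NULL) {
  if (!inherits(aln, "clone_alignment")) {
    assert_that(!is.null(clone), "supply a clone_alignment or (ref, clone)")
    aln <- align_clone(aln, clone)
  }
  if (is.null(ref)) ref <- gsub("-", "", aln$aligned_ref)
  ref <- as_reference(ref)
  subs <- aln$substitutions
  subs$hotspot <- if (nrow(subs)) classify_hotspot(ref, subs$ref_position)
                  else character(0)
  subs
}

#' Flag and filter clones that look like cloning artifacts
#'
#' Clones with more than `max_mismatch_frac` mismatches over aligned bases or
#' shorter than `min_length_frac` of the reference are discarded; exact
#' duplicate clone sequences are kept but flagged (removed when
#' `collapse_duplicates = TRUE`).
#'
#' @param alignments list of `clone_alignment`s against one reference.
#' @param max_mismatch_frac maximum substitutions / aligned_bp.
#' @param min_length_frac minimum clone length / reference length.
#' @param collapse_duplicates drop all but the first of identical clones.
#' @return List with `alignments` (kept), `qc` (per-clone data.frame with
#'   `clone_id`, `kept`, `reason`, `duplicate`).
#' @export
filter_clones <- function(alignments, max_mismatch_frac = 0.1,
                          min_length_frac = 0.8,
                          collapse_duplicates = FALSE) {
  if (inherits(alignments, "clone_alignment")) alignments <- list(alignments)
  clone_seq <- vapply(alignments, function(a) gsub("-", "", a$aligned_clone),
                      character(1))
  ref_len <- vapply(alignments, function(a) nchar(gsub("-", "", a$aligned_ref)),
                    numeric(1))
  mm_frac <- vapply(alignments, function(a) {
    if (a$aligned_bp == 0) 1 else nrow(a$substitutions) / a$aligned_bp
  }, numeric(1))
  len_frac <- nchar(clone_seq) / ref_len
  dup <- duplicated(clone_seq)
  reason <- rep("", length(alignments))
  reason[mm_frac > max_mismatch_frac] <- "mismatch_frac"
  reason[len_frac < min_length_frac] <- "short"
  kept <- reason == ""
  if (collapse_duplicates) {
    reason[kept & dup] <- "duplicate"
    kept <- kept & !dup
  }
  qc <- data.frame(
    clone_id = vapply(alignments, `[[`, character(1), "clone_id"),
    kept = kept, reason = reason, duplicate = dup,
    stringsAsFactors = FALSE)
  list(alignments = alignments[kept], qc = qc)
}

#' Summarise somatic hypermutation for one experimental condition
#'
#' Aggregates clone alignments into the mutations-per-base-pair statistic:
#' `mut_per_bp = n_substitutions / total_aligned_bp`. A condition passes QC
#' only when at least `min_assessed_bp` aligned base pairs were assessed
#' (default 10,000); summaries below the threshold are still returned,
#' flagged `qc_pass = FALSE`. Hotspot labels come from [classify_hotspot()]
#' on the shared reference.
#'
#' @param alignments list of `clone_alignment`s, all against the same
#'   reference.
#' @param ref the reference sequence the clones were aligned to.
#' @param condition condition label.
#' @param min_assessed_bp QC threshold on total aligned bp.
#' @return An object of class `mutation_summary`: `condition`, `n_clones`,
#'   `total_aligned_bp`, `n_substitutions`, `mut_per_bp`, `n_indel_events`,
#'   `spectrum` (4x4 counts), `n_hotspot`, `hotspot_fraction` (`NA` when no
#'   substitutions), `cg_fraction`, `transition_fraction`, `qc_pass`,
#'   `substitutions` (per-event table).
#' @export
summarize_condition <- function(alignments, ref, condition = "cond",
                                min_assessed_bp = 10000) {
  if (inherits(alignments, "clone_alignment")) alignments <- list(alignments)
  assert_that(length(alignments) >= 1, "need at least one alignment")
  ref <- as_reference(ref)
  ref_ids <- unique(vapply(alignments, `[[`, character(1), "ref_id"))
  assert_that(length(ref_ids) == 1,
              "alignments mix references; summarise one condition per reference")
  subs <- do.call(rbind, lapply(alignments, call_substitutions, ref = ref))
  if (is.null(subs)) {
    subs <- data.frame(ref_position = integer(0), ref_base = character(0),
                       alt_base = character(0), clone_id = character(0),
                       hotspot = character(0))
  }
  total_bp <- sum(vapply(alignments, `[[`, numeric(1), "aligned_bp"))
  n_sub <- nrow(subs)
  spectrum <- matrix(0L, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (n_sub) {
    tab <- table(factor(subs$ref_base, DNA_BASES),
                 factor(subs$alt_base, DNA_BASES))
    spectrum <- spectrum + unclass(tab)
  }
  n_hot <- sum(subs$hotspot != "none")
  transitions <- sum((subs$ref_base == "A" & subs$alt_base == "G") |
                     (subs$ref_base == "G" & subs$alt_base == "A") |
                     (subs$ref_base == "C" & subs$alt_base == "T") |
                     (subs$ref_base == "T" & subs$alt_base == "C"))
  structure(list(
    condition = condition,
    n_clones = length(alignments),
    total_aligned_bp = total_bp,
    n_substitutions = n_sub,
    mut_per_bp = if (total_bp > 0) n_sub / total_bp else NA_real_,
    n_indel_events = sum(vapply(alignments, `[[`, numeric(1),
                                "n_indel_events")),
    spectrum = spectrum,
    n_hotspot = n_hot,
    hotspot_fraction = if (n_sub) n_hot / n_sub else NA_real_,
    cg_fraction = if (n_sub) mean(subs$ref_base %in% c("C", "G")) else NA_real_,
    transition_fraction = if (n_sub) transitions / n_sub else NA_real_,
    qc_pass = total_bp >= min_assessed_bp,
    substitutions = subs), class = "mutation_summary")
}

#' @export
print.mutation_summary <- function(x, ...) {
  cat(sprintf("mutation_summary '%s': %d clones, %d bp assessed%s\n",
              x$condition, x$n_clones, x$total_aligned_bp,
              if (x$qc_pass) "" else " [QC FAIL: < min assessed bp]"))
  cat(sprintf("  %d substitutions (%.3g per bp), hotspot fraction %s\n",
              x$n_substitutions, x$mut_per_bp,
              ifelse(is.na(x$hotspot_fraction), "NA",
                     sprintf("%.3f", x$hotspot_fraction))))
  invisible(x)
}

#' Substitution spectrum of a condition summary
#'
#' @param summary a `mutation_summary`.
#' @return List with `spectrum` (4x4 counts, ref base in rows), `cg_fraction`
#'   (share of substitutions at C or G reference bases) and
#'   `transition_fraction` (share of A<->G, C<->T changes).
#' @export
substitution_spectrum <- function(summary) {
  assert_that(inherits(summary, "mutation_summary"),
              "`summary` must be a mutation_summary")
  list(spectrum = summary$spectrum,
       cg_fraction = summary$cg_fraction,
       transition_fraction = summary$transition_fraction)
}

#' Compare mutation rates between two conditions
#'
#' Exposure-normalised rate ratio `(n_b / bp_b) / (n_a / bp_a)` with an exact
#' conditional binomial test: given `N = n_a + n_b`, under the null of equal
#' per-bp rates `n_b ~ Binomial(N, bp_b / (bp_a + bp_b))`; the confidence
#' interval comes from exact inversion of that conditional distribution.
#' Small substitution counts and unequal exposures are the norm in clonal
#' SHM assays, which is why an exact conditional test is used rather than a
#' large-sample approximation.
#'
#' @param a baseline condition (`mutation_summary`).
#' @param b comparison condition (`mutation_summary`).
#' @param conf_level confidence level for the rate-ratio interval.
#' @return An object of class `fold_change_result`: `rate_ratio`, `conf_int`,
#'   `p_value`, `method`, plus the input counts/exposures.
#' @examples
#' \dontrun{
#' compare_conditions(summary_control, summary_stimulated)
#' }
#' @export
compare_conditions <- function(a, b, conf_level = 0.95) {
  assert_that(inherits(a, "mutation_summary") && inherits(b, "mutation_summary"),
              "`a` and `b` must be mutation_summary objects")
  assert_that(a$total_aligned_bp > 0 && b$total_aligned_bp > 0,
              "both conditions need total_aligned_bp > 0")
  n_a <- a$n_substitutions; n_b <- b$n_substitutions
  bp_a <- a$total_aligned_bp; bp_b <- b$total_aligned_bp
  if (n_a == 0 && n_b == 0) {
    res <- list(rate_ratio = NA_real_, conf_int = c(NA_real_, NA_real_),
                p_value = 1)
  } else {
    ht <- poisson.test(c(n_b, n_a), c(bp_b, bp_a), conf.level = conf_level)
    res <- list(rate_ratio = (n_b / bp_b) / (n_a / bp_a),
                conf_int = unname(ht$conf.int), p_value = ht$p.value)
  }
  structure(c(res, list(
    method = "exact conditional binomial rate-ratio test",
    conf_level = conf_level,
    n_a = n_a, n_b = n_b, bp_a = bp_a, bp_b = bp_b,
    condition_a = a$condition, condition_b = b$condition)),
    class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("fold change %s vs %s: %.3g (%d%% CI %.3g-%.3g), p = %.3g\n",
              x$condition_b, x$condition_a, x$rate_ratio,
              round(100 * x$conf_level), x$conf_int[1], x$conf_int[2],
              x$p_value))
  invisible(x)
}
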