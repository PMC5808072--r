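test_that("classify_hotspot follows the WRCY/RGYW motif definition", {
  expect_identical(classify_hotspot("TACT", 3), "WRCY")  # T-A-C-T
  expect_identical(classify_hotspot("AGCT", 2), "RGYW")  # A-G-C-T
  expect_identical(classify_hotspot("GGCC", 3), "none")  # G not in W
  # windows extending past the ends never match
  expect_identical(classify_hotspot("ACTT", 2), "none")
  expect_identical(classify_hotspot("TAC", 3), "none")
  expect_error(classify_hotspot("TACT", 5), "position")
  expect_error(classify_hotspot("TACT", 0), "position")
})

test_that("hotspot labels agree with the exhaustive two-strand motif scan", {
  withr::local_seed(42)
  seqs <- vapply(1:500, function(i) random_dna(200), character(1))
  expected <- oracle_hotspots(seqs)
  for (i in seq_along(seqs)) {
    expect_identical(classify_hotspot(seqs[i], 1:200), expected[[i]])
  }
})

test_that("align_clone handles identity, mismatch and deletion as specified", {
  aln <- align_clone("ACGT", "ACGT")
  expect_equal(aln$aligned_bp, 4)
  expect_equal(nrow(aln$substitutions), 0)

  aln <- align_clone("ACGT", "ACTT")
  expect_equal(aln$aligned_bp, 4)
  expect_equal(aln$substitutions$ref_position, 3)
  expect_equal(aln$substitutions$ref_base, "G")
  expect_equal(aln$substitutions$alt_base, "T")

  scoring <- list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
  aln <- align_clone("ACGT", "ACT", scoring = scoring)
  expect_equal(aln$n_indel_events, 1)
  expect_equal(aln$n_indel_bp, 1)
  expect_equal(aln$aligned_bp, 3)
  expect_equal(aln$score, oracle_global_score("ACT", "ACGT", 1, -1, -2, -1))

  expect_error(align_clone("ACGT", "ACNT"), "non-ACGT")
})

test_that("alignment scores match exhaustive enumeration on small pairs", {
  withr::local_seed(7)
  scoring <- list(match = 1, mismatch = -1, gap_open = -4, gap_extend = -1)
  for (i in 1:25) {
    ref <- random_dna(sample(4:7, 1))
    clone <- random_dna(sample(3:7, 1))
    aln <- align_clone(ref, clone, scoring = scoring)
    expect_equal(aln$score,
                 oracle_global_score(clone, ref, 1, -1, -4, -1),
                 info = paste(ref, clone))
  }
})

test_that("substitution calls equal position-wise comparison on gap-free pairs", {
  withr::local_seed(99)
  for (i in 1:200) {
    ref <- random_dna(50)
    clone <- mutate_seq(ref, sample(0:5, 1))
    subs <- call_substitutions(align_clone(ref, clone))
    expected <- oracle_substitutions(ref, clone)
    expect_equal(subs$ref_position, expected$ref_position)
    expect_equal(subs$ref_base, expected$ref_base)
    expect_equal(subs$alt_base, expected$alt_base)
  }
})

test_that("summarize_condition computes mutations per bp and the coverage rule", {
  ref <- generate_reference(565, seed = 5)
  clones <- vapply(1:30, function(i) ref$seq, character(1))
  # plant exactly 12 substitutions across the clone set
  withr::local_seed(8)
  for (i in 1:12) clones[i] <- mutate_seq(clones[i], 1)
  names(clones) <- sprintf("c%02d", 1:30)
  alns <- align_clone(ref, clones)
  s <- summarize_condition(alns, ref, condition = "x")
  expect_equal(s$total_aligned_bp, 30 * 565)
  expect_equal(s$n_substitutions, 12)
  expect_equal(s$mut_per_bp, 12 / 16950)
  expect_true(s$qc_pass)
  expect_equal(sum(s$spectrum), 12)
  expect_true(all(diag(s$spectrum) == 0))

  # below the 10,000 bp rule the summary is flagged, not dropped
  short <- summarize_condition(alns[1:3], ref, condition = "tiny")
  expect_false(short$qc_pass)
  expect_equal(short$n_clones, 3)

  # no substitutions: rate 0, hotspot fraction undefined
  clean <- summarize_condition(align_clone(ref, setNames(rep(ref$seq, 2),
                                                         c("a", "b"))), ref)
  expect_equal(clean$mut_per_bp, 0)
  expect_true(is.na(clean$hotspot_fraction))

  # mixed references are rejected
  other <- generate_reference(565, seed = 6, id = "other")
  aln_other <- align_clone(other, other$seq)
  expect_error(summarize_condition(c(alns[1], list(aln_other)), ref), "mix")
})

test_that("monotonicity: an unmutated clone never increases mut_per_bp", {
  ref <- generate_reference(200, seed = 9)
  clones <- c(a = mutate_seq(ref$seq, 3), b = mutate_seq(ref$seq, 1))
  alns <- align_clone(ref, clones)
  before <- summarize_condition(alns, ref)$mut_per_bp
  alns$clean <- align_clone(ref, ref$seq, clone_id = "clean")
  after <- summarize_condition(alns, ref)$mut_per_bp
  expect_lte(after, before)
})

test_that("compare_conditions reproduces the exact conditional binomial test", {
  ref <- generate_reference(565, seed = 5)
  mk <- function(n_sub, bp) {
    structure(list(condition = "s", n_substitutions = n_sub,
                   total_aligned_bp = bp), class = "mutation_summary")
  }
  res <- compare_conditions(mk(2, 10000), mk(9, 10000))
  expect_equal(res$rate_ratio, 4.5)
  # two-sided exact p from Binomial(11, 1/2) tail enumeration
  expect_equal(res$p_value, 134 / 2048)
  expect_gte(res$rate_ratio, res$conf_int[1])
  expect_lte(res$rate_ratio, res$conf_int[2])

  same <- compare_conditions(mk(5, 10000), mk(5, 10000))
  expect_equal(same$rate_ratio, 1)
  expect_equal(same$p_value, 1)

  zero <- compare_conditions(mk(0, 10000), mk(0, 10000))
  expect_true(is.na(zero$rate_ratio))
  expect_equal(zero$p_value, 1)
})

test_that("substitution_spectrum tallies agree with a direct recount", {
  ref <- generate_reference(400, seed = 13)
  cs <- simulate_clones(ref, shm_params(mu_background = 5e-3,
                                        hotspot_multiplier = 2), 20, seed = 14)
  alns <- align_clone(ref, cs$clones)
  s <- summarize_condition(alns, ref)
  spec <- substitution_spectrum(s)
  # independent tally straight from the clone strings
  subs <- do.call(rbind, lapply(cs$clones, function(cl) {
    oracle_substitutions(ref$seq, cl)
  }))
  tally <- unclass(table(factor(subs$ref_base, c("A", "C", "G", "T")),
                         factor(subs$alt_base, c("A", "C", "G", "T"))))
  expect_equal(unclass(spec$spectrum), tally, ignore_attr = TRUE)
  expect_equal(spec$cg_fraction, mean(subs$ref_base %in% c("C", "G")))
  expect_equal(rowSums(spec$spectrum),
               setNames(as.numeric(table(factor(subs$ref_base,
                                                c("A", "C", "G", "T")))),
                        c("A", "C", "G", "T")))
  # degenerate case: no substitutions
  empty <- summarize_condition(align_clone(ref, setNames(ref$seq, "id")), ref)
  expect_true(all(substitution_spectrum(empty)$spectrum == 0))
})

test_that("filter_clones drops artifacts and flags duplicates", {
  ref <- generate_reference(300, seed = 15)
  good <- mutate_seq(ref$seq, 2)
  noisy <- mutate_seq(ref$seq, 45)                  # > 10% mismatches
  short <- substr(ref$seq, 1, 200)                  # < 80% of length
  clones <- c(a = good, b = noisy, c = short, d = good)
  alns <- align_clone(ref, clones)
  res <- filter_clones(alns)
  expect_setequal(res$qc$clone_id[res$qc$kept], c("a", "d"))
  expect_identical(res$qc$reason[res$qc$clone_id == "b"], "mismatch_frac")
  expect_identical(res$qc$reason[res$qc$clone_id == "c"], "short")
  expect_true(res$qc$duplicate[res$qc$clone_id == "d"])
  collapsed <- filter_clones(alns, collapse_duplicates = TRUE)
  expect_setequal(collapsed$qc$clone_id[collapsed$qc$kept], "a")
})
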