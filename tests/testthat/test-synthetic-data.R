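test_that("generate_reference honours length, seed determinism and GC target", {
  ref <- generate_reference(565, gc = 0.5, seed = 7)
  expect_s3_class(ref, "reference_sequence")
  expect_equal(nchar(ref$seq), 565)
  expect_identical(ref$seq, generate_reference(565, gc = 0.5, seed = 7)$seq)
  expect_false(identical(ref$seq, generate_reference(565, gc = 0.5,
                                                     seed = 8)$seq))
  # observed GC within the central 99% binomial interval at n = 10000, p = 0.6
  big <- generate_reference(10000, gc = 0.6, seed = 1)
  gc_count <- sum(strsplit(big$seq, "")[[1]] %in% c("G", "C"))
  expect_gte(gc_count, qbinom(0.005, 10000, 0.6))
  expect_lte(gc_count, qbinom(0.995, 10000, 0.6))
  expect_error(generate_reference(0, 0.5, seed = 1), "length")
  expect_error(generate_reference(100, 1.5, seed = 1), "gc")
})

test_that("simulate_clones: zero rate is the identity; counts are Poisson-like", {
  ref <- generate_reference(565, seed = 11)
  cs0 <- simulate_clones(ref, shm_params(mu_background = 0), 5, seed = 1)
  expect_true(all(cs0$clones == ref$seq))
  # with h = 1 every site mutates at mu; total substitutions across 30 clones
  # fall in the central 99% Poisson interval of mean mu * L * n
  cs <- simulate_clones(ref, shm_params(mu_background = 8e-4,
                                        hotspot_multiplier = 1), 30, seed = 2)
  total <- sum(vapply(cs$clones, function(cl) {
    nrow(oracle_substitutions(ref$seq, cl))
  }, numeric(1)))
  lambda <- 8e-4 * 565 * 30
  expect_gte(total, qpois(0.005, lambda))
  expect_lte(total, qpois(0.995, lambda))
  # determinism and length conservation when indels are off
  cs_again <- simulate_clones(ref, shm_params(mu_background = 8e-4,
                                              hotspot_multiplier = 1),
                              30, seed = 2)
  expect_identical(cs$clones, cs_again$clones)
  expect_true(all(nchar(cs$clones) == 565))
})

test_that("simulate_clones indels change clone length; spectrum weights steer changes", {
  ref <- generate_reference(400, seed = 3)
  cs <- simulate_clones(ref, shm_params(mu_background = 0, indel_rate = 0.01),
                        30, seed = 4)
  expect_true(any(nchar(cs$clones) != 400))
  # a spectrum forcing C->T and G->A only
  w <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  w["C", "T"] <- 1; w["G", "A"] <- 1
  w["A", "G"] <- 1e-9; w["T", "C"] <- 1e-9  # keep rows positive
  cs2 <- simulate_clones(ref, shm_params(mu_background = 0.02,
                                         hotspot_multiplier = 1,
                                         spectrum_weights = w), 20, seed = 5)
  subs <- do.call(rbind, lapply(cs2$clones, function(cl) {
    oracle_substitutions(ref$seq, cl)
  }))
  from_cg <- subs[subs$ref_base %in% c("C", "G"), ]
  expect_true(nrow(from_cg) > 10)
  expect_true(all(ifelse(from_cg$ref_base == "C", from_cg$alt_base == "T",
                         from_cg$alt_base == "A")))
})

test_that("hotspot mutation fraction converges to the closed form", {
  ref <- generate_reference(565, seed = 21)
  h <- 8
  p_expect <- expected_hotspot_fraction(ref, h)
  hot <- classify_hotspot(ref, seq_len(565)) != "none"
  fractions <- vapply(1:100, function(r) {
    cs <- simulate_clones(ref, shm_params(mu_background = 8e-4,
                                          hotspot_multiplier = h),
                          10, seed = 1000 + r)
    subs <- do.call(rbind, lapply(cs$clones, function(cl) {
      oracle_substitutions(ref$seq, cl)
    }))
    if (is.null(subs) || nrow(subs) == 0) return(NA_real_)
    mean(hot[subs$ref_position])
  }, numeric(1))
  fractions <- fractions[!is.na(fractions)]
  se <- sd(fractions) / sqrt(length(fractions))
  expect_lt(abs(mean(fractions) - p_expect), 3 * se)
})

test_that("aid_active = FALSE attenuates the rate by aid_null_multiplier", {
  ref <- generate_reference(565, seed = 31)
  count_subs <- function(aid_active, seeds) {
    vapply(seeds, function(s) {
      cs <- simulate_clones(ref, shm_params(mu_background = 4e-3,
                                            hotspot_multiplier = 1,
                                            aid_active = aid_active,
                                            aid_null_multiplier = 0.02),
                            10, seed = s)
      sum(vapply(cs$clones, function(cl) {
        nrow(oracle_substitutions(ref$seq, cl))
      }, numeric(1)))
    }, numeric(1))
  }
  active <- count_subs(TRUE, 1:200)
  null <- count_subs(FALSE, 201:400)
  ratio_per_rep <- mean(null) / mean(active)
  # delta-method SE of the ratio of means
  se <- ratio_per_rep * sqrt(var(null) / (200 * mean(null)^2) +
                             var(active) / (200 * mean(active)^2))
  expect_lt(abs(ratio_per_rep - 0.02), 3 * se)
})

test_that("simulate_binding_tracks: counts are sound and enrichment is recovered", {
  g <- genome_spec(c("chrA", "chrB"), c(120, 80), bin_size = 10000)
  dom <- data.frame(chrom = "chrA", start = 41, end = 60, enrichment = 4)
  plan <- planted_domain_spec(dom, background_mean = 20, dispersion = 10)
  sim <- simulate_binding_tracks(g, plan, seed = 5)
  all_counts <- c(unlist(sim$chip$counts), unlist(sim$input$counts))
  expect_true(all(all_counts >= 0))
  expect_true(all(all_counts == round(all_counts)))
  expect_identical(sim$truth,
                   data.frame(chrom = "chrA", start = 41L, end = 60L,
                              enrichment = 4))
  # same seed reproduces; different seed does not
  sim2 <- simulate_binding_tracks(g, plan, seed = 5)
  expect_identical(sim$chip$counts, sim2$chip$counts)
  sim3 <- simulate_binding_tracks(g, plan, seed = 6)
  expect_false(identical(sim$chip$counts, sim3$chip$counts))

  # in-domain / background chip ratio approaches the planted enrichment
  ratios <- vapply(1:100, function(s) {
    x <- simulate_binding_tracks(g, plan, seed = s)
    inside <- mean(x$chip$counts$chrA[41:60])
    outside <- mean(c(x$chip$counts$chrA[-(41:60)], x$chip$counts$chrB))
    inside / outside
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 4), 3 * se)
})

test_that("null tracks (enrichment 1) show no chip/input mean difference", {
  g <- genome_spec("chr1", 200, bin_size = 10000)
  plan <- planted_domain_spec(
    data.frame(chrom = "chr1", start = 1, end = 200, enrichment = 1),
    background_mean = 20, dispersion = 10)
  diffs <- vapply(1:50, function(s) {
    x <- simulate_binding_tracks(g, plan, seed = s)
    mean(x$chip$counts$chr1) - mean(x$input$counts$chr1)
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("overlapping planted domains are rejected", {
  g <- genome_spec("chr1", 100, bin_size = 10000)
  dom <- data.frame(chrom = "chr1", start = c(10, 25), end = c(30, 40),
                    enrichment = c(2, 3))
  expect_error(simulate_binding_tracks(g, planted_domain_spec(dom), seed = 1),
               "overlap")
})

test_that("write_fixture_set emits a parseable, seed-deterministic file set", {
  config <- small_config(seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  m1 <- write_fixture_set(config, d1)
  expect_gte(nrow(m1), 6)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  # all fixtures parse with the package's own readers
  genome <- genome_spec(config$genome$chromosomes,
                        unlist(config$genome$n_bins),
                        config$genome$bin_size)
  expect_named(read_fasta(file.path(d1, "reference.fasta")))
  expect_length(read_fasta(file.path(d1, "clones_stimulated.fasta")),
                config$shm$n_clones)
  chip <- read_bedgraph(file.path(d1, "chip_control.bedGraph"), genome)
  expect_s3_class(chip, "binned_track")
  expect_gt(track_total <- sum(unlist(chip$counts)), 0)
  ig <- read_bed(file.path(d1, "ig_clusters.bed"))
  expect_true(all(c("chrom", "start", "end", "name") %in% names(ig)))
  # byte-identical on re-run with the same config; different under a new seed
  m2 <- write_fixture_set(config, d2)
  expect_identical(m1$md5, m2$md5)
  m3 <- write_fixture_set(small_config(seed = 4), d3)
  expect_true(any(m3$md5 != m1$md5))
})
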