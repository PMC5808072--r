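#' Default pipeline configuration
#'
#' A single nested list holding every tunable of the pipeline exactly once:
#' fixture parameters (reference, SHM conditions, binding-track plan), LAD
#' calling parameters and differential-analysis parameters. The defaults
#' describe the emulated experiment: a 565 bp V-region amplicon; an
#' unstimulated condition, a stimulated condition with a 4.5-fold higher
#' substitution rate, and a stimulated AID-null condition; and a four
#' chromosome, 10 kb-binned genome in which three immunoglobulin variable
#' cluster loci lose two thirds of their Lamin B1 enrichment upon SHM
#' induction while other domains persist or grow.
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    reference = list(length = 565, gc = 0.5, id = "Vamp_synthetic"),
    shm = list(
      n_clones = 50,
      hotspot_multiplier = 8,
      aid_null_multiplier = 0.02,
      indel_rate = 0,
      spectrum = "uniform",
      min_assessed_bp = 10000,
      max_mismatch_frac = 0.1,
      min_length_frac = 0.8,
      collapse_duplicates = FALSE,
      conditions = list(
        unstimulated = list(mu = 8e-4, aid_active = TRUE),
        stimulated = list(mu = 3.6e-3, aid_active = TRUE),
        stimulated_aid_null = list(mu = 3.6e-3, aid_active = FALSE)
      )
    ),
    genome = list(chromosomes = c("chr1", "chr2", "chr3", "chr4"),
                  n_bins = c(500, 500, 500, 500), bin_size = 10000),
    tracks = list(
      background_mean = 20,
      dispersion = 10,
      conditions = c("control", "shm_induced"),
      domains = list(
        list(chrom = "chr1", start = 51, end = 80,
             enrichment = list(control = 4, shm_induced = 4)),
        list(chrom = "chr1", start = 201, end = 230,
             enrichment = list(control = 6, shm_induced = 2)),
        list(chrom = "chr1", start = 351, end = 400,
             enrichment = list(control = 4, shm_induced = 4)),
        list(chrom = "chr2", start = 101, end = 140,
             enrichment = list(control = 4, shm_induced = 4)),
        list(chrom = "chr2", start = 251, end = 280,
             enrichment = list(control = 6, shm_induced = 2)),
        list(chrom = "chr2", start = 421, end = 460,
             enrichment = list(control = 4, shm_induced = 4)),
        list(chrom = "chr3", start = 61, end = 100,
             enrichment = list(control = 6, shm_induced = 2)),
        list(chrom = "chr3", start = 301, end = 360,
             enrichment = list(control = 4, shm_induced = 4)),
        list(chrom = "chr4", start = 151, end = 200,
             enrichment = list(control = 4, shm_induced = 6)),
        list(chrom = "chr4", start = 301, end = 340,
             enrichment = list(control = 1, shm_induced = 4)),
        list(chrom = "chr4", start = 401, end = 430,
             enrichment = list(control = 4, shm_induced = 4))
      ),
      ig_clusters = list(
        list(name = "IGH_synthetic", chrom = "chr1", start = 201, end = 230),
        list(name = "IGK_synthetic", chrom = "chr2", start = 251, end = 280),
        list(name = "IGL_synthetic", chrom = "chr3", start = 61, end = 100)
      )
    ),
    lads = list(pseudocount = 1, percentile = 66.7, gap_penalty = 3,
                n_perm = 2000, q_threshold = 0.05),
    diff = list(delta_threshold = 0.5, min_width = 3, n_perm = 500)
  )
}

config_genome <- function(config) {
  genome_spec(unlist(config$genome$chromosomes),
              unlist(config$genome$n_bins),
              config$genome$bin_size)
}

#' Read a pipeline configuration from JSON
#'
#' Reads a configuration written by [write_fixture_set()] (or authored by
#' hand) and normalises it to the in-memory layout of [default_config()],
#' so that a serialised configuration round-trips to an identical
#' configuration hash.
#'
#' @param path JSON file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  config <- jsonlite::read_json(path, simplifyVector = FALSE)
  config$seed <- as.integer(config$seed)
  config$genome$chromosomes <- unlist(config$genome$chromosomes)
  config$genome$n_bins <- unlist(config$genome$n_bins)
  config$tracks$conditions <- unlist(config$tracks$conditions)
  config
}

config_domains_df <- function(config, condition) {
  do.call(rbind, lapply(config$tracks$domains, function(d) {
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               enrichment = d$enrichment[[condition]],
               stringsAsFactors = FALSE)
  }))
}

config_ig_df <- function(config, genome) {
  do.call(rbind, lapply(config$tracks$ig_clusters, function(d) {
    data.frame(chrom = d$chrom,
               start = (d$start - 1) * genome$bin_size,
               end = d$end * genome$bin_size,
               name = d$name, stringsAsFactors = FALSE)
  }))
}

config_shm_params <- function(config, cond) {
  sw <- switch(config$shm$spectrum,
               uniform = NULL,
               aid = aid_spectrum_weights(),
               stop("unknown spectrum preset: ", config$shm$spectrum))
  shm_params(mu_background = cond$mu,
             hotspot_multiplier = config$shm$hotspot_multiplier,
             aid_active = cond$aid_active,
             aid_null_multiplier = config$shm$aid_null_multiplier,
             indel_rate = config$shm$indel_rate,
             spectrum_weights = sw)
}

#' Write the complete synthetic fixture set
#'
#' Generates the reference amplicon, one clone FASTA per SHM condition, one
#' ChIP and one input bedGraph per binding condition plus a truth BED of the
#' planted domains, the Ig-cluster annotation BED, a copy of the resolved
#' configuration and a TSV manifest with per-file MD5 checksums and seeds.
#' Output is byte-identical for identical configurations.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir output directory (created if missing).
#' @return data.frame manifest (`file`, `md5`, `seed`), invisibly written as
#'   `manifest.tsv`.
#' @export
write_fixture_set <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir) && file.access(out_dir, 2) == 0,
              sprintf("cannot write to directory '%s'", out_dir))
  seed <- config$seed
  hdr <- output_header(config, seed)
  genome <- config_genome(config)
  files <- character(0)
  seeds <- integer(0)
  add <- function(path, s) {
    files <<- c(files, path)
    seeds <<- c(seeds, as.integer(s))
  }

  ref <- generate_reference(config$reference$length, config$reference$gc,
                            seed = seed, id = config$reference$id)
  p <- file.path(out_dir, "reference.fasta")
  write_fasta(ref, p)
  add(p, seed)

  cond_names <- names(config$shm$conditions)
  for (i in seq_along(cond_names)) {
    cname <- cond_names[i]
    cs <- simulate_clones(ref, config_shm_params(config,
                                                 config$shm$conditions[[i]]),
                          n_clones = config$shm$n_clones,
                          seed = seed + 100L + i, condition = cname)
    p <- file.path(out_dir, sprintf("clones_%s.fasta", cname))
    write_fasta(cs, p)
    add(p, seed + 100L + i)
  }

  track_conds <- unlist(config$tracks$conditions)
  for (j in seq_along(track_conds)) {
    tname <- track_conds[j]
    plan <- planted_domain_spec(config_domains_df(config, tname),
                                background_mean = config$tracks$background_mean,
                                dispersion = config$tracks$dispersion)
    sim <- simulate_binding_tracks(genome, plan, seed = seed + 200L + j)
    p_chip <- file.path(out_dir, sprintf("chip_%s.bedGraph", tname))
    p_input <- file.path(out_dir, sprintf("input_%s.bedGraph", tname))
    write_bedgraph(sim$chip, p_chip, header = hdr)
    write_bedgraph(sim$input, p_input, header = hdr)
    add(p_chip, seed + 200L + j)
    add(p_input, seed + 200L + j)
    pt <- file.path(out_dir, sprintf("truth_%s.bed", tname))
    truth_bp <- bins_to_bp(sim$truth, genome)
    truth_bp$name <- sprintf("planted_x%g", sim$truth$enrichment)
    write_bed(truth_bp, pt, header = hdr)
    add(pt, seed + 200L + j)
  }

  p <- file.path(out_dir, "ig_clusters.bed")
  write_bed(config_ig_df(config, genome), p, header = hdr)
  add(p, seed)

  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(p, seed)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = seeds, stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.tsv")
  writeLines(c(hdr, paste(names(manifest), collapse = "\t"),
               sprintf("%s\t%s\t%d", manifest$file, manifest$md5,
                       manifest$seed)), mpath)
  invisible(manifest)
}

write_tsv_with_header <- function(df, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # fix numeric formatting so outputs are byte-stable across platforms
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- trimws(formatC(df[[nm]], format = "g", digits = 8))
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pipeline stages --------------------------------------------------------

pipeline_shm <- function(config, out_dir) {
  ref_path <- file.path(out_dir, "reference.fasta")
  assert_that(file.exists(ref_path),
              sprintf("missing fixture '%s'; run the simulate stage first",
                      ref_path))
  refseq <- read_fasta(ref_path)
  ref <- structure(list(id = names(refseq)[1], seq = unname(refseq[1])),
                   class = "reference_sequence")
  cond_names <- names(config$shm$conditions)
  summaries <- list()
  for (cname in cond_names) {
    cpath <- file.path(out_dir, sprintf("clones_%s.fasta", cname))
    assert_that(file.exists(cpath), sprintf("missing fixture '%s'", cpath))
    clones <- read_fasta(cpath)
    alns <- align_clone(ref, clones)
    kept <- filter_clones(alns,
                          max_mismatch_frac = config$shm$max_mismatch_frac,
                          min_length_frac = config$shm$min_length_frac,
                          collapse_duplicates = isTRUE(config$shm$collapse_duplicates))
    summaries[[cname]] <- summarize_condition(
      kept$alignments, ref, condition = cname,
      min_assessed_bp = config$shm$min_assessed_bp)
  }
  baseline <- summaries[[1]]
  fold <- lapply(cond_names[-1], function(cname) {
    compare_conditions(baseline, summaries[[cname]])
  })
  names(fold) <- cond_names[-1]
  list(summaries = summaries, fold_changes = fold)
}

summary_to_row <- function(s) {
  data.frame(condition = s$condition, n_clones = s$n_clones,
             total_aligned_bp = s$total_aligned_bp,
             n_substitutions = s$n_substitutions, mut_per_bp = s$mut_per_bp,
             n_hotspot = s$n_hotspot, hotspot_fraction = s$hotspot_fraction,
             cg_fraction = s$cg_fraction,
             transition_fraction = s$transition_fraction,
             n_indel_events = s$n_indel_events, qc_pass = s$qc_pass,
             stringsAsFactors = FALSE)
}

fold_to_row <- function(f) {
  data.frame(condition_a = f$condition_a, condition_b = f$condition_b,
             rate_ratio = f$rate_ratio, ci_low = f$conf_int[1],
             ci_high = f$conf_int[2], p_value = f$p_value,
             n_a = f$n_a, n_b = f$n_b, bp_a = f$bp_a, bp_b = f$bp_b,
             stringsAsFactors = FALSE)
}

pipeline_lads <- function(config, out_dir) {
  genome <- config_genome(config)
  track_conds <- unlist(config$tracks$conditions)
  res <- list()
  for (j in seq_along(track_conds)) {
    tname <- track_conds[j]
    chip <- read_bedgraph(file.path(out_dir, sprintf("chip_%s.bedGraph",
                                                     tname)), genome)
    input <- read_bedgraph(file.path(out_dir, sprintf("input_%s.bedGraph",
                                                      tname)), genome)
    res[[tname]] <- call_lads(
      chip, input,
      pseudocount = config$lads$pseudocount,
      percentile = config$lads$percentile,
      gap_penalty = config$lads$gap_penalty,
      n_perm = config$lads$n_perm,
      q_threshold = config$lads$q_threshold,
      seed = config$seed + 300L + 10L * j)
  }
  res
}

pipeline_diff <- function(config, out_dir, lads = NULL) {
  genome <- config_genome(config)
  if (is.null(lads)) lads <- pipeline_lads(config, out_dir)
  track_conds <- unlist(config$tracks$conditions)
  assert_that(length(track_conds) >= 2,
              "differential analysis needs two binding conditions")
  a <- lads[[track_conds[1]]]
  b <- lads[[track_conds[2]]]
  regions <- detect_canyons_mesas(a$ratio, b$ratio,
                                  delta_threshold = config$diff$delta_threshold,
                                  min_width = config$diff$min_width)
  dom_a <- a$domains[a$domains$significant, , drop = FALSE]
  dom_b <- b$domains[b$domains$significant, , drop = FALSE]
  profile <- chromosome_binding_profile(dom_a, genome, dom_b)
  ig <- read_bed(file.path(out_dir, "ig_clusters.bed"))
  canyons <- regions[regions$type == "canyon", , drop = FALSE]
  overlap <- overlap_annotation(canyons, ig, genome,
                                n_perm = config$diff$n_perm,
                                seed = config$seed + 400L)
  loci <- lapply(seq_len(nrow(ig)), function(i) {
    locus_fold_change(a$ratio, b$ratio, ig[i, ])
  })
  names(loci) <- ig$name
  list(regions = regions, profile = profile, overlap = overlap,
       locus_folds = loci, ig = ig)
}

#' Run pipeline stages and write their outputs
#'
#' Orchestrates the analysis stages over a fixture/working directory:
#' \describe{
#'   \item{`simulate`}{writes the synthetic fixture set
#'     ([write_fixture_set()]).}
#'   \item{`shm`}{per-condition mutation summaries (`shm_summary.tsv`) and
#'     rate-ratio contrasts against the first condition
#'     (`shm_fold_change.tsv`).}
#'   \item{`lads`}{per-condition LAD calls (`lads_<condition>.bed`) and
#'     statistics (`lad_stats.tsv`).}
#'   \item{`diff`}{canyon/mesa BED (`canyons_mesas.bed`), per-chromosome
#'     coverage profile (`chromosome_profile.tsv`) and Ig-cluster overlap
#'     plus locus fold changes (`overlap_report.json`).}
#'   \item{`report`}{all of the above plus a combined `report.json`.}
#' }
#' Every text output starts with `#` header lines (JSON: a `_meta` field)
#' recording the tool version, configuration hash and seed; identical
#' (config, seed) runs produce byte-identical files.
#'
#' @param subcommand one of `"simulate"`, `"shm"`, `"lads"`, `"diff"`,
#'   `"report"`.
#' @param config configuration list, see [default_config()].
#' @param out_dir working directory holding fixtures and outputs.
#' @param seed optional override of `config$seed`.
#' @return Invisible list of stage results (stage-dependent).
#' @export
run_pipeline <- function(subcommand = c("simulate", "shm", "lads", "diff",
                                        "report"),
                         config = default_config(), out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(config, config$seed)
  meta <- list(tool = "lamingate",
               version = as.character(utils::packageVersion("lamingate")),
               config_hash = config_hash(config), seed = config$seed)
  genome <- config_genome(config)

  if (subcommand == "simulate") {
    manifest <- write_fixture_set(config, out_dir)
    return(invisible(list(manifest = manifest)))
  }

  if (subcommand == "shm") {
    shm <- pipeline_shm(config, out_dir)
    for (s in shm$summaries) {
      if (!s$qc_pass) {
        warning(sprintf(
          "condition '%s': only %d aligned bp assessed (minimum %d); qc_pass=FALSE",
          s$condition, s$total_aligned_bp, config$shm$min_assessed_bp),
          call. = FALSE)
      }
    }
    write_tsv_with_header(do.call(rbind, lapply(shm$summaries,
                                                summary_to_row)),
                          file.path(out_dir, "shm_summary.tsv"), hdr)
    write_tsv_with_header(do.call(rbind, lapply(shm$fold_changes,
                                                fold_to_row)),
                          file.path(out_dir, "shm_fold_change.tsv"), hdr)
    return(invisible(shm))
  }

  if (subcommand == "lads") {
    lads <- pipeline_lads(config, out_dir)
    stats <- list()
    for (tname in names(lads)) {
      dom <- lads[[tname]]$domains
      sig <- dom[dom$significant, , drop = FALSE]
      bed <- bins_to_bp(sig, genome)
      bed$name <- sprintf("LAD_%s_%03d", tname, seq_len(nrow(sig)))
      bed$score <- sig$score
      write_bed(bed, file.path(out_dir, sprintf("lads_%s.bed", tname)),
                header = hdr)
      stats[[tname]] <- data.frame(
        condition = tname, n_domains = nrow(sig),
        covered_bins = if (nrow(sig)) sum(sig$end - sig$start + 1L) else 0L,
        threshold = lads[[tname]]$scores$threshold,
        min_q = if (nrow(dom)) min(dom$q) else NA_real_,
        stringsAsFactors = FALSE)
    }
    write_tsv_with_header(do.call(rbind, stats),
                          file.path(out_dir, "lad_stats.tsv"), hdr)
    return(invisible(lads))
  }

  if (subcommand == "diff") {
    diff <- pipeline_diff(config, out_dir)
    bed <- bins_to_bp(diff$regions, genome)
    bed$name <- sprintf("%s_%03d", diff$regions$type,
                        seq_len(nrow(diff$regions)))
    bed$score <- diff$regions$mean_delta
    write_bed(bed, file.path(out_dir, "canyons_mesas.bed"), header = hdr)
    write_tsv_with_header(diff$profile,
                          file.path(out_dir, "chromosome_profile.tsv"), hdr)
    report <- list(
      `_meta` = meta,
      canyon_ig_overlap = list(
        overlap_bp = diff$overlap$overlap_bp,
        jaccard = diff$overlap$jaccard,
        enrichment = diff$overlap$enrichment,
        expected_bp = diff$overlap$expected_bp,
        p = diff$overlap$p,
        per_annotation = diff$overlap$per_annotation),
      locus_fold_changes = lapply(diff$locus_folds, function(f) {
        list(fold = f$fold, direction = f$direction, n_bins = f$n_bins)
      }))
    jsonlite::write_json(report, file.path(out_dir, "overlap_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(diff))
  }

  # report: run every stage and combine
  run_pipeline("simulate", config, out_dir)
  shm <- run_pipeline("shm", config, out_dir)
  lads <- run_pipeline("lads", config, out_dir)
  diff <- run_pipeline("diff", config, out_dir)
  combined <- list(
    `_meta` = meta,
    shm = list(
      summaries = lapply(shm$summaries, function(s) {
        r <- summary_to_row(s)
        as.list(r)
      }),
      fold_changes = lapply(shm$fold_changes, function(f) as.list(fold_to_row(f)))),
    lads = lapply(lads, function(l) {
      sig <- l$domains[l$domains$significant, , drop = FALSE]
      list(n_domains = nrow(sig), threshold = l$scores$threshold)
    }),
    diff = list(
      n_canyons = sum(diff$regions$type == "canyon"),
      n_mesas = sum(diff$regions$type == "mesa"),
      chromosome_profile = diff$profile,
      canyon_ig_jaccard = diff$overlap$jaccard,
      canyon_ig_enrichment = diff$overlap$enrichment,
      canyon_ig_p = diff$overlap$p,
      locus_fold_changes = lapply(diff$locus_folds, function(f) {
        list(fold = f$fold, direction = f$direction)
      })))
  jsonlite::write_json(combined, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(shm = shm, lads = lads, diff = diff, report = combined))
}
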