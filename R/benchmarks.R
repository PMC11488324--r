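#' Planted-variant recovery study
#'
#' The standard in-silico validation of the genotyping pipeline: a toy
#' mitochondrial genome carries six low-frequency heteroplasmies
#' (zero-inflated Beta per cell, bulk VAF around 5%) and two
#' near-homoplasmic ones; reads are simulated at ~100x per-cell mito
#' coverage and the full pipeline (pileup, candidate identification,
#' filtering cascade) is run. Recovery is assessed over the planted variants
#' that meet the qualifying conditions (true bulk VAF >= 0.5% and >= 50
#' carrier cells), together with the RMSE of the per-cell VAF estimates over
#' non-missing entries.
#'
#' @param genome A `genome_spec`.
#' @param seed Seed for variant placement.
#' @return `recovery_variant_table()`: the planted variant truth tibble.
#' @export
recovery_variant_table <- function(genome, seed = 42L) {
  withr::with_seed(seed, {
    pos <- sort(sample(100:(genome$mito_length - 100L), 8))
    ref <- ref_base(genome, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    tibble(
      variant_id = sprintf("m.%d%s>%s", pos, ref, alt),
      pos = pos, ref = ref, alt = alt,
      freq_class = c(rep("low", 6), "high", "high"),
      pi0 = c(rep(0.5, 6), 0.05, 0.05),
      beta_a = c(rep(2, 6), 50, 50),
      beta_b = c(rep(18, 6), 1, 1),
      designated = c(TRUE, TRUE, rep(FALSE, 4), TRUE, FALSE)
    )
  })
}

#' @rdname recovery_variant_table
#' @param n_cells Number of cells per run.
#' @param mito_length Toy mitochondrial genome length (bp).
#' @return `simulate_recovery_run()`: list with `genome`, `truth`, `sim`.
#' @export
simulate_recovery_run <- function(seed, n_cells = 120L, mito_length = 1500L) {
  genome <- genome_spec("mm10", c(chr1 = 2e5L, chr2 = 2e5L),
                        mito_length = mito_length, seed = 3L)
  vt <- recovery_variant_table(genome)
  cfg <- sim_config(n_cells = n_cells, frag_meanlog = log(300),
                    frag_sdlog = 0.3, mito_depth_scale = 4.7,
                    n_peaks = 50L, variants = vt)
  truth <- simulate_cells(cfg, genome, seed = seed)
  sim <- simulate_fragments(truth, genome, seed = seed + 1000L)
  list(genome = genome, truth = truth, sim = sim)
}

#' @rdname recovery_variant_table
#' @param seeds Integer vector of simulation seeds.
#' @return `recovery_benchmark()`: list with per-seed tibble `runs` and a
#'   one-row `summary` (`recall`, `vaf_rmse`, counts).
#' @export
recovery_benchmark <- function(seeds = 1:10) {
  runs <- purrr::map_dfr(seeds, function(s) {
    d <- simulate_recovery_run(s)
    res <- call_mito_variants(d$sim$mito_reads, d$genome)
    truth_bulk <- d$truth$cell_vaf %>%
      group_by(.data$variant_id) %>%
      summarise(bulk = mean(.data$true_vaf),
                carriers = sum(.data$true_vaf > 0), .groups = "drop")
    qualifying <- truth_bulk %>%
      filter(.data$bulk >= 0.005, .data$carriers >= 50L)
    recovered_ids <- res$variants$variant_id[res$variants$pass_all]
    sq_err <- res$vaf %>%
      filter(.data$variant_id %in% intersect(qualifying$variant_id,
                                             recovered_ids),
             !is.na(.data$vaf)) %>%
      inner_join(d$truth$cell_vaf, by = c("barcode", "variant_id")) %>%
      summarise(sse = sum((.data$vaf - .data$true_vaf)^2), n = dplyr::n())
    tibble(seed = s,
           n_qualifying = nrow(qualifying),
           n_recovered = sum(qualifying$variant_id %in% recovered_ids),
           sse = sq_err$sse, n_vaf = sq_err$n)
  })
  summary <- tibble(
    n_seeds = length(seeds),
    recall = sum(runs$n_recovered) / sum(runs$n_qualifying),
    vaf_rmse = sqrt(sum(runs$sse) / sum(runs$n_vaf))
  )
  list(runs = runs, summary = summary)
}

#' Permutation-null calibration study
#'
#' Simulates a peak-count matrix with no carrier effect (a ~50/50
#' carrier/WT split driven by one designated variant) and runs the
#' random-split permutation control; with no planted signal the median
#' significant-peak count should be zero.
#'
#' @param seed Integer seed.
#' @param n_cells,n_peaks Dataset geometry.
#' @param n_reps Number of random splits.
#' @return List with `real` (glance of the true-label contrast) and `perm`
#'   (glance of the permutation control).
#' @export
permutation_null_benchmark <- function(seed = 1L, n_cells = 300L,
                                       n_peaks = 150L, n_reps = 100L) {
  genome <- genome_spec("mm10", c(chr1 = 2e5L, chr2 = 2e5L),
                        mito_length = 1500L, seed = 3L)
  vt <- recovery_variant_table(genome)
  vt$designated <- c(TRUE, rep(FALSE, 7))
  cfg <- sim_config(n_cells = n_cells, frag_meanlog = log(100),
                    frag_sdlog = 0.3, n_peaks = n_peaks, variants = vt)
  truth <- simulate_cells(cfg, genome, seed = seed)
  peaks <- withr::with_seed(seed, simulate_peaks(genome, n_peaks, 300L))
  emb <- embed_carrier_effects(truth, peaks, list(), effect = 1,
                               n_affected = 0L, seed = seed + 1L)
  assignment <- tibble(barcode = truth$cells$barcode,
                       status = if_else(truth$cells$carrier, "carrier", "WT"))
  real <- glance(differential_peaks(emb$counts, assignment))
  perm <- glance(permutation_control(emb$counts, assignment, n_reps = n_reps,
                                     seed = seed + 2L))
  list(real = real, perm = perm)
}

#' Barnyard recovery study
#'
#' Simulates a two-species mixing experiment with planted collision and
#' contamination rates and classifies it, reporting planted and recovered
#' rates side by side.
#'
#' @param seed Integer seed.
#' @param n_cells Number of barcodes.
#' @param collision_rate,contamination_rate Planted rates.
#' @return One-row tibble with planted and recovered counts and rates.
#' @export
barnyard_benchmark <- function(seed = 1L, n_cells = 5000L,
                               collision_rate = 0.02,
                               contamination_rate = 0.005) {
  gh <- genome_spec("hg19", c(chr1 = 1e5L), mito_chrom = "hg19_chrM",
                    mito_length = 300L)
  gm <- genome_spec("mm10", c(chr1 = 1e5L), mito_chrom = "mm10_chrM",
                    mito_length = 300L)
  cfg <- sim_config(n_cells = n_cells, doublet_rate = collision_rate,
                    contamination_rate = contamination_rate)
  by <- simulate_barnyard(cfg, list(gh, gm), seed = seed)
  rep <- glance(classify_barnyard(by$cells))
  tibble(
    n_cells = rep$n_cells,
    planted_collisions = sum(by$truth$doublet),
    recovered_collisions = rep$n_mixed,
    collision_rate = rep$collision_rate,
    planted_contaminated = sum(by$truth$contaminated),
    recovered_contaminated = rep$n_contaminated,
    contamination_rate = rep$contamination_rate,
    n_singlet = rep$n_singlet
  )
}

#' Wilcoxon type-I error calibration
#'
#' Repeatedly draws two same-distribution samples and records how often the
#' test rejects at `alpha`.
#'
#' @param n_sims Number of null simulations.
#' @param n_per_group Sample size per group.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return Observed rejection rate.
#' @export
wilcoxon_type1_rate <- function(n_sims = 1000L, n_per_group = 50L,
                                alpha = 0.01, seed = 1L) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_sims), function(i) {
      wilcoxon_rank_sum(rnorm(n_per_group), rnorm(n_per_group),
                        exact_max = 0L)$p_value
    }, numeric(1)) < alpha)
  })
}
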