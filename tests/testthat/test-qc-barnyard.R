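test_that("TSS enrichment behaves at its defining extremes", {
  tss <- tibble(chrom = "chr1", pos = 50000L)

  # uniform fragments give a score near 1
  withr::with_seed(51, {
    start <- sample.int(99000L, 20000L)
    uni <- tibble(chrom = "chr1", start = start, end = start + 150L,
                  barcode = "BC1", support = 1L)
  })
  s_uni <- compute_tss_enrichment(uni, tss)
  expect_gt(s_uni$tss_enrichment, 0.7)
  expect_lt(s_uni$tss_enrichment, 1.3)

  # all insertions exactly at the TSS, none in flanks: the pseudocount rule
  # gives the window-normalised maximum, well above 1
  pin <- tibble(chrom = "chr1", start = rep(50000L, 10L), end = 50001L,
                barcode = "BC2", support = 1L)
  s_pin <- compute_tss_enrichment(pin, tss)
  expect_gt(s_pin$tss_enrichment, 1)

  # a requested barcode without fragments scores 0 with a warning
  expect_warning(
    s0 <- compute_tss_enrichment(uni, tss, barcodes = c("BC1", "none")),
    "no fragments")
  expect_equal(s0$tss_enrichment[s0$barcode == "none"], 0)

  expect_error(compute_tss_enrichment(uni, tss[0, ]), "TSS")
})

test_that("simulated TSS enrichment is recovered near its target", {
  g <- toy_genome()
  cfg <- sim_config(n_cells = 30L, frag_meanlog = log(2000), frag_sdlog = 0.1,
                    p_peak = 0, tss_enrichment = 5,
                    n_variants_low = 1L, n_variants_high = 0L,
                    mito_depth_scale = 0.01)
  truth <- simulate_cells(cfg, g, seed = 61)
  sim <- simulate_fragments(truth, g, seed = 62)
  sc <- compute_tss_enrichment(sim$fragments, sim$tss)
  expect_gt(mean(sc$tss_enrichment), 4)
  expect_lt(mean(sc$tss_enrichment), 6)
})

test_that("FRiP covers its boundary cases and matches brute force", {
  peaks <- tibble(chrom = "chr1", start = c(100L, 1000L),
                  end = c(300L, 1200L), id = c("p1", "p2"))
  inside <- tibble(chrom = "chr1", start = c(150L, 1050L),
                   end = c(250L, 1150L), barcode = "BC1", support = 1L)
  expect_equal(compute_frip(inside, peaks)$frip, 1)
  expect_equal(compute_frip(inside, peaks[0, ])$frip, 0)

  # random fragments vs per-base membership oracle on a toy chromosome
  withr::with_seed(52, {
    start <- sample.int(9000L, 2000L)
    frags <- tibble(chrom = "chr1", start = start, end = start + 50L,
                    barcode = sprintf("BC%d", sample.int(5L, 2000L, TRUE)),
                    support = 1L)
    tpk <- tibble(chrom = "chr1", start = c(0L, 4000L), end = c(1500L, 5500L),
                  id = c("a", "b"))
  })
  frip <- compute_frip(frags, tpk)
  base_member <- logical(10000L)
  for (i in seq_len(nrow(tpk))) {
    base_member[(tpk$start[i] + 1L):tpk$end[i]] <- TRUE
  }
  oracle <- frags %>%
    mutate(hit = vapply(seq_len(nrow(frags)), function(i)
      any(base_member[(start[i] + 1L):end[i]]), logical(1))) %>%
    group_by(barcode) %>%
    summarise(frip = mean(hit))
  expect_equal(frip$frip[match(oracle$barcode, frip$barcode)], oracle$frip)
})

test_that("mito content and coverage arithmetic is exact", {
  frags <- tibble(chrom = "chr1", start = seq_len(40L), end = seq_len(40L) + 10L,
                  barcode = "BC1", support = 1L)
  mito <- make_read(rep("BC1", 60L), 1L, strrep("A", 10L))
  mc <- compute_mito_content(frags, mito)
  expect_equal(mc$mito_content_pct, 60)
  expect_equal(compute_mito_content(frags, mito[0, ])$mito_content_pct, 0)

  one <- make_read("BC1", 1L, strrep("A", 100L))
  cov <- compute_mito_mean_coverage(one, 16569L)
  expect_equal(cov$mean_coverage, 100 / 16569)
  cov0 <- compute_mito_mean_coverage(one[0, ], 16569L)
  expect_equal(attr(cov0, "summary")$mean, 0)

  expect_equal(coverage_fold_change(282.87, 4.61), 61.36)
  expect_error(coverage_fold_change(1, 0), "positive")
})

test_that("cell filters apply the printed boundary semantics and are monotone", {
  m <- tibble(barcode = c("a", "b", "c"),
              tss_enrichment = c(1.2, 1.19, 5.0),
              n_fragments = c(2000L, 4000L, 50001L),
              frip = c(0.21, 0.3, 0.9))
  out <- apply_cell_filters(m)
  expect_equal(out$pass_qc, c(TRUE, FALSE, FALSE))

  # monotonicity: raising any threshold never adds a passing cell
  withr::with_seed(53, {
    mm <- tibble(barcode = sprintf("BC%d", 1:200),
                 tss_enrichment = runif(200, 0, 4),
                 n_fragments = as.integer(runif(200, 0, 60000)),
                 frip = runif(200))
  })
  base <- apply_cell_filters(mm)$pass_qc
  for (alt in list(apply_cell_filters(mm, tss_min = 2)$pass_qc,
                   apply_cell_filters(mm, frag_range = c(5000L, 50000L))$pass_qc,
                   apply_cell_filters(mm, frip_min = 0.5)$pass_qc)) {
    expect_true(all(!alt | base))
  }
})

test_that("top-cell selection ranks by complexity with stable ties", {
  m <- tibble(barcode = c("b", "a", "c"), n_fragments = c(20L, 30L, 10L))
  expect_equal(select_top_cells(m, 1), "a")
  expect_setequal(select_top_cells(m, 10), m$barcode)
  # stable under permutation of the input rows
  withr::with_seed(54, {
    mm <- tibble(barcode = sprintf("BC%03d", 1:100),
                 n_fragments = sample.int(50L, 100L, replace = TRUE))
  })
  sel1 <- select_top_cells(mm, 10)
  sel2 <- select_top_cells(mm[sample.int(100L), ], 10)
  expect_identical(sel1, sel2)
})

test_that("barnyard classification handles pure, mixed and relabelled cells", {
  pure <- tibble(barcode = c("x", "y"),
                 n_frag_hg19 = c(100L, 0L), n_frag_mm10 = c(0L, 80L),
                 n_mito_hg19 = c(50L, 0L), n_mito_mm10 = c(0L, 40L))
  r <- classify_barnyard(pure)
  expect_equal(glance(r)$collision_rate, 0)
  expect_equal(glance(r)$contamination_rate, 0)

  half <- tibble(barcode = "z", n_frag_hg19 = 50L, n_frag_mm10 = 50L,
                 n_mito_hg19 = 10L, n_mito_mm10 = 10L)
  expect_equal(glance(classify_barnyard(half, purity_threshold = 0.51))$n_mixed, 1L)

  # rates are invariant to barcode relabelling
  withr::with_seed(55, {
    cfg <- sim_config(n_cells = 800L, doublet_rate = 0.05,
                      contamination_rate = 0.02)
    gh <- genome_spec("hg19", c(chr1 = 1e5L), mito_chrom = "hg19_chrM",
                      mito_length = 300L)
    gm <- genome_spec("mm10", c(chr1 = 1e5L), mito_chrom = "mm10_chrM",
                      mito_length = 300L)
    by <- simulate_barnyard(cfg, list(gh, gm), seed = 8)
  })
  r1 <- glance(classify_barnyard(by$cells))
  shuffled <- by$cells
  shuffled$barcode <- rev(shuffled$barcode)
  r2 <- glance(classify_barnyard(shuffled))
  expect_equal(r1$collision_rate, r2$collision_rate)
  expect_equal(r1$contamination_rate, r2$contamination_rate)

  # zero-assignable cells are excluded and counted
  none <- tibble(barcode = "n", n_frag_hg19 = 0L, n_frag_mm10 = 0L,
                 n_mito_hg19 = 0L, n_mito_mm10 = 0L)
  expect_equal(glance(classify_barnyard(none))$n_excluded, 1L)
})
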