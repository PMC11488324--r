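test_that("pileup applies the read-level filters exactly", {
  g <- toy_genome(mito_length = 200L)
  reads <- bind_rows(
    ref_read(g, "BC1", 10L),                       # passes
    ref_read(g, "BC1", 10L, mapq = 29L),           # below MAPQ threshold
    ref_read(g, "BC1", 10L, nm = 3L),              # too many mismatches
    ref_read(g, "BC1", 10L, qual = phred_string(19L, 20L))  # all bases fail BQ
  )
  t1 <- pileup_allele_counts(reads, g)
  expect_equal(sum(t1$count), 20L)  # only the first read contributes

  # per-base quality: a single low-quality base drops just that base
  q <- phred_string(37L, 20L)
  substr(q, 5, 5) <- intToUtf8(10L + 33L)
  t2 <- pileup_allele_counts(ref_read(g, "BC1", 10L, qual = q), g)
  expect_equal(sum(t2$count), 19L)
  expect_false(14L %in% t2$pos)  # pos 10 + offset 4

  # reads overhanging the mito end are clipped with a warning
  expect_warning(
    t3 <- pileup_allele_counts(make_read("BC1", 190L, strrep("A", 20L)), g),
    "clipped")
  expect_equal(max(t3$pos), 200L)
  expect_equal(sum(t3$count), 11L)
})

test_that("pileup equals the naive per-read oracle on random reads", {
  g <- toy_genome(mito_length = 300L)
  withr::with_seed(71, {
    n <- 1000L
    pos <- sample.int(280L, n, replace = TRUE)
    len <- sample(10:20, n, replace = TRUE)
    reads <- tibble(
      barcode = sprintf("BC%02d", sample.int(20L, n, replace = TRUE)),
      chrom = "chrM", pos = pos,
      strand = sample(c("+", "-"), n, replace = TRUE),
      mapq = sample(c(10L, 30L, 60L), n, replace = TRUE, prob = c(.1, .2, .7)),
      nm = sample(0:4, n, replace = TRUE),
      seq = vapply(seq_len(n), function(i) {
        s <- substr(g$mito_seq, pos[i], pos[i] + len[i] - 1L)
        if (runif(1) < 0.5) {  # sprinkle mismatches and Ns
          j <- sample.int(nchar(s), 1)
          substr(s, j, j) <- sample(c("A", "C", "G", "T", "N"), 1)
        }
        s
      }, character(1)),
      qual = vapply(len, function(l) paste(intToUtf8(
        sample(c(12L, 25L, 40L), l, replace = TRUE) + 33L,
        multiple = TRUE), collapse = ""), character(1))
    )
  })
  got <- pileup_allele_counts(reads, g)
  attr(got, "config") <- NULL
  want <- naive_pileup(reads, g$mito_length)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("pseudo-bulk aggregation is an exact sum over cells", {
  g <- toy_genome(mito_length = 120L)
  r1 <- ref_read(g, "BC1", 5L)
  r2 <- ref_read(g, "BC2", 15L)
  t1 <- pileup_allele_counts(r1, g)
  t12 <- pileup_allele_counts(bind_rows(r1, r2), g)
  b1 <- aggregate_pseudobulk(t1)
  b12 <- aggregate_pseudobulk(t12)
  expect_equal(sum(b12$count), sum(t12$count))  # conservation
  # single cell: bulk equals that cell's tensor
  expect_equal(b1$count, t1$count[order(t1$pos, t1$allele, t1$strand)])
  # two cells: bulk is the elementwise sum
  manual <- t12 %>% group_by(pos, allele, strand) %>%
    summarise(count = sum(count), .groups = "drop")
  expect_equal(as.data.frame(b12), as.data.frame(manual))
})

test_that("per-cell VAF follows alt/(alt+ref) with low-coverage masking", {
  g <- toy_genome(mito_length = 100L)
  p <- 50L
  ref <- ref_base(g, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk <- function(bc, base, n) {
    make_read(rep(bc, n), p, base)
  }
  reads <- bind_rows(
    mk("BC1", alt, 3L), mk("BC1", ref, 7L),   # VAF 0.30 at coverage 10
    mk("BC2", alt, 2L), mk("BC2", ref, 7L),   # coverage 9: masked
    mk("BC3", ref, 12L)                        # alt 0 -> VAF 0
  )
  tensor <- pileup_allele_counts(reads, g)
  variants <- tibble(variant_id = "v", pos = p, ref = ref, alt = alt)
  vaf <- compute_cell_vaf(tensor, variants)
  expect_equal(vaf$vaf[vaf$barcode == "BC1"], 0.30)
  expect_true(is.na(vaf$vaf[vaf$barcode == "BC2"]))
  expect_equal(vaf$vaf[vaf$barcode == "BC3"], 0)
})

test_that("pseudo-bulk VAF equals the depth-weighted mean of cell VAFs", {
  d <- recovery_dataset(seed = 301, n_cells = 40L, mito_length = 600L)
  tensor <- pileup_allele_counts(d$sim$mito_reads, d$genome)
  vaf <- compute_cell_vaf(tensor, d$variants,
                          genotyping_config(low_coverage_threshold = 0L))
  bulk <- aggregate_pseudobulk(tensor)
  for (i in seq_len(nrow(d$variants))) {
    v <- d$variants[i, ]
    cell <- vaf %>% filter(variant_id == v$variant_id)
    weighted <- sum(cell$vaf * cell$coverage) / sum(cell$coverage)
    alt_bulk <- sum(bulk$count[bulk$pos == v$pos & bulk$allele == v$alt])
    ref_bulk <- sum(bulk$count[bulk$pos == v$pos & bulk$allele == v$ref])
    expect_equal(weighted, alt_bulk / (alt_bulk + ref_bulk))
  }
})

test_that("informative-variant statistics exclude constant and absent alleles", {
  g <- toy_genome(mito_length = 100L)
  p <- 30L
  ref <- ref_base(g, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  # homoplasmic: every cell all-alt at the site -> VMR 0 -> not informative
  reads <- purrr::map_dfr(1:20, function(i)
    make_read(rep(sprintf("BC%02d", i), 12L), p, alt,
              strand = rep(c("+", "-"), 6L)))
  tensor <- pileup_allele_counts(reads, g)
  cand <- identify_candidate_variants(tensor, g, keep_all = TRUE)
  row <- cand[cand$pos == p & cand$alt == alt, ]
  expect_equal(row$vmr, 0)
  expect_false(row$candidate)

  # reference-only position yields no candidate row
  ref_only <- purrr::map_dfr(1:5, function(i)
    ref_read(g, sprintf("BC%02d", i), 10L, len = 5L))
  cand2 <- identify_candidate_variants(pileup_allele_counts(ref_only, g), g,
                                       keep_all = TRUE)
  expect_equal(nrow(cand2), 0L)
})

test_that("a planted heteroplasmic variant is identified as a candidate", {
  d <- recovery_dataset(seed = 303, n_cells = 60L, mito_length = 800L)
  tensor <- pileup_allele_counts(d$sim$mito_reads, d$genome)
  cand <- identify_candidate_variants(tensor, d$genome)
  low <- d$variants$variant_id[d$variants$freq_class == "low"]
  expect_gt(mean(low %in% cand$variant_id), 0.8)
})

test_that("the filter cascade has the printed boundary semantics", {
  base <- random_candidates(3, seed = 81)
  base$bulk_depth <- c(249L, 1000L, 1000L)
  base$alt_depth <- c(10L, 100L, 100L)
  base$n_cells <- c(100L, 49L, 100L)
  base$plus_strand_fraction <- 0.5
  base$pos <- c(100L, 200L, 310L)
  out <- apply_bulk_filters(base, species = "hg19")
  expect_equal(out$pass_bulk_depth, c(FALSE, TRUE, TRUE))
  expect_equal(out$pass_min_cells, c(TRUE, FALSE, TRUE))
  expect_equal(out$pass_blacklist, c(TRUE, TRUE, FALSE))
  expect_equal(out$pass_all, c(FALSE, FALSE, FALSE))
  # the same positions pass the blacklist under the mouse key
  expect_true(all(apply_bulk_filters(base, species = "mm10")$pass_blacklist))
})

test_that("the filter cascade equals a brute-force oracle and is monotone", {
  cand <- random_candidates(1000L, seed = 82)
  cfg <- genotyping_config()
  got <- apply_bulk_filters(cand, cfg, species = "hg19")
  want <- naive_cascade(cand, cfg, cfg$blacklist$hg19)
  expect_identical(got$pass_all, want)

  # tightening any threshold yields a subset of passing variants
  tighter <- list(
    genotyping_config(allele_depth_ratio = 10),
    genotyping_config(strand_support_max = 0.8),
    genotyping_config(min_bulk_depth = 500L),
    genotyping_config(min_cells = 100L)
  )
  for (cfg2 in tighter) {
    got2 <- apply_bulk_filters(cand, cfg2, species = "hg19")
    expect_true(all(!got2$pass_all | got$pass_all))
  }

  # flags are independent: failing variants are retained for audit
  expect_equal(nrow(got), nrow(cand))
  expect_lt(nrow(apply_bulk_filters(cand, cfg, species = "hg19",
                                    drop_failed = TRUE)), nrow(cand))
})

test_that("qPCR copy number follows 2 x 2^dCt", {
  expect_equal(qpcr_copy_number(20, 20), 2)
  expect_equal(qpcr_copy_number(30, 20), 2048)
  expect_equal(qpcr_copy_number(18, 20), 0.5)
})

test_that("variant annotation reproduces the known worked examples", {
  g <- mito_genome("mm10")
  v <- tibble(pos = c(15219L, 15984L, 9821L, 11185L),
              ref = c("T", "C", "A", "G"), alt = c("C", "T", "T", "A"))
  ann <- annotate_variants(v, g)
  cytb <- ann[ann$pos == 15219L, ]
  expect_equal(cytb$gene, "CYTB")
  expect_equal(cytb$cdna_change, "c.T1075C")  # 15219 - 14145 + 1 = 1075
  expect_equal(cytb$aa_change, "p.F359L")
  expect_equal(cytb$effect, "nonsynonymous")
  expect_equal(ann$region[ann$pos == 15984L], "D-loop")
  expect_equal(ann$gene[ann$pos == 9821L], "tRNA-Arg")
  expect_equal(ann$effect[ann$pos == 9821L], "noncoding")
  nd4 <- ann[ann$pos == 11185L, ]
  expect_equal(nd4$aa_change, "p.R340H")  # homolog of the human LHON allele

  # third-position change in the same CYTB codon is synonymous (TTC -> TTT)
  syn <- annotate_variants(tibble(pos = 15221L, ref = "C", alt = "T"), g)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_change, "p.F359F")

  # intergenic fallback and overlapping genes (ATP8/ATP6 share 7927-7969)
  ig <- annotate_variants(tibble(pos = 16299L, ref = "A", alt = "C"),
                          toy_genome(16299L))
  expect_equal(ig$region, "intergenic")
  ov <- annotate_variants(tibble(pos = 7950L, ref = ref_base(g, 7950L),
                                 alt = "A"), g)
  expect_setequal(ov$gene, c("ATP8", "ATP6"))
})

test_that("full-pipeline recovery meets the recall and RMSE targets on one seed", {
  d <- recovery_dataset(seed = 1)
  res <- call_mito_variants(d$sim$mito_reads, d$genome)
  truth_bulk <- d$truth$cell_vaf %>%
    group_by(variant_id) %>%
    summarise(bulk = mean(true_vaf), carriers = sum(true_vaf > 0))
  qualifying <- truth_bulk %>% filter(bulk >= 0.005, carriers >= 50L)
  recalled <- qualifying$variant_id %in%
    res$variants$variant_id[res$variants$pass_all]
  expect_gte(mean(recalled), 0.9)
})
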