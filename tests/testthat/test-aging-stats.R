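test_that("exact Wilcoxon enumeration matches hand-derived and base-R results", {
  # all C(4,2) = 6 assignments; {1,2} vs {3,4} is one of the two extremes
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  # identical multisets: maximal overlap
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # against the base-R exact test on tie-free draws, all group sizes <= 8
  withr::with_seed(91, {
    for (n in c(2L, 4L, 6L, 8L)) {
      for (m in c(3L, 5L, 8L)) {
        x <- rnorm(n); y <- rnorm(m)
        p_mine <- wilcoxon_rank_sum(x, y)$p_value
        p_base <- wilcox.test(x, y, exact = TRUE)$p.value
        expect_equal(p_mine, p_base, tolerance = 1e-12)
      }
    }
  })

  # the enumeration handles ties (base R's exact path cannot)
  p_tie <- wilcoxon_rank_sum(c(1, 1, 2), c(1, 2, 2))$p_value
  expect_true(p_tie > 0 && p_tie <= 1)

  # large-sample approximation close to the exact answer at n = 8 vs 8
  withr::with_seed(92, {
    x <- rnorm(8); y <- rnorm(8, 0.5)
  })
  p_exact <- wilcoxon_rank_sum(x, y)$p_value
  p_approx <- wilcoxon_rank_sum(x, y, exact_max = 0L)$p_value
  expect_lt(abs(p_exact - p_approx), 0.01)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("pairwise content matrices do the pair bookkeeping exactly", {
  expect_equal(significant_pair_summary(45, 11)$total_pairs, 55)
  expect_equal(significant_pair_summary(45, 11)$fraction_printed, 0.82)
  expect_equal(significant_pair_summary(30, 9)$fraction_printed, 0.83)
  expect_error(significant_pair_summary(60, 10), "exceed")

  withr::with_seed(93, {
    d <- tibble(
      cell_type = rep(c("B", "T", "NK", "Mono"), each = 40),
      mito_content_pct = c(rnorm(40, 50, 5), rnorm(40, 50, 5),
                           rnorm(40, 70, 5), rnorm(40, 30, 5))
    )
  })
  pm <- pairwise_content_matrix(d, alpha = 0.01)
  s <- glance(pm)
  expect_equal(s$total_pairs, choose(4, 2))
  expect_equal(s$n_sig, sum(tidy(pm)$significant))
  expect_equal(s$fraction, s$n_sig / s$total_pairs)
  # NK and Mono differ from everything; B vs T do not
  res <- tidy(pm)
  bt <- res[res$type_a == "B" & res$type_b == "T", ]
  expect_false(bt$significant)
  expect_equal(s$n_sig, 5)
})

test_that("mutation burden counts detected variants over non-missing entries", {
  vaf <- tibble(
    barcode = c("c1", "c1", "c1", "c2", "c2", "c2"),
    variant_id = rep(c("v1", "v2", "v3"), 2),
    alt_count = c(0L, 2L, 5L, 0L, 0L, 0L),
    vaf = c(0, 0.02, NA, 0, 0, 0)
  )
  b <- mutation_burden(vaf)
  expect_equal(b$burden[b$barcode == "c1"], 1L)  # {0, 0.02, missing}
  expect_equal(b$burden[b$barcode == "c2"], 0L)
  expect_equal(b$n_informative[b$barcode == "c1"], 2L)
  # monotone (non-increasing) in the detection threshold
  b2 <- mutation_burden(vaf, min_alt_reads = 3L)
  expect_true(all(b2$burden <= b$burden))
})

test_that("a planted burden shift is detected by the group comparison", {
  withr::with_seed(94, {
    n <- 500L
    per_cell <- tibble(
      barcode = sprintf("BC%04d", 1:(2 * n)),
      age_group = rep(c("young", "aged"), each = n),
      cell_type = "B",
      burden = c(rpois(n, 1.0), rpois(n, 1.5))
    )
  })
  cmp <- compare_groups(per_cell, "burden", "age_group", by = "cell_type")
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$mean_a, cmp$mean_b)  # "aged" sorts before "young"
})

test_that("mean VAF by group averages non-missing entries per stratum", {
  vaf <- tibble(barcode = c("c1", "c2", "c2"),
                variant_id = c("v1", "v1", "v2"),
                alt_count = c(1L, 1L, 0L),
                vaf = c(0.5, 0.2, NA))
  ann <- tibble(barcode = c("c1", "c2"), cell_type = "B",
                age_group = c("young", "aged"))
  mv <- mean_vaf_by_group(vaf, ann)
  expect_equal(mv$mean_vaf[mv$age_group == "young"], 0.5)
  expect_equal(mv$mean_vaf[mv$age_group == "aged"], 0.2)
})

test_that("shared-variant sets intersect on (pos, ref, alt) identity", {
  a <- tibble(pos = 1L, ref = "A", alt = "C")
  expect_equal(shared_variant_sets(list(A = a, B = a))$region, "A&B")
  b <- tibble(pos = 2L, ref = "G", alt = "T")
  venn <- shared_variant_sets(list(A = a, B = b))
  expect_setequal(venn$region, c("A", "B"))
  expect_true(all(venn$n == 1L))

  # three samples sharing one variant, emulating the shared D-loop pattern
  shared <- tibble(pos = c(15984L, 15728L), ref = "C", alt = "T")
  young <- bind_rows(shared, tibble(pos = 100L, ref = "A", alt = "G"))
  aged <- bind_rows(shared, tibble(pos = 200L, ref = "T", alt = "A"))
  bm <- tibble(pos = 15984L, ref = "C", alt = "T")
  venn3 <- shared_variant_sets(list(ys = young, as = aged, bm = bm))
  both_spleens <- venn3[venn3$region == "ys&as", ]
  expect_equal(both_spleens$n, 1L)
  expect_equal(both_spleens$variant_ids, "m.15728C>T")
  expect_equal(venn3$variant_ids[venn3$region == "ys&as&bm"], "m.15984C>T")
  expect_error(shared_variant_sets(list(a, b)), "named")
})

test_that("gene activity counts fragments in body + upstream window", {
  gt <- tibble(gene = c("gplus", "gminus"), chrom = "chr1",
               start = c(10000L, 30000L), end = c(12000L, 32000L),
               strand = c("+", "-"))
  frags <- tibble(
    chrom = "chr1",
    start = c(10500L, 7999L, 5000L, 33500L, 26000L),
    end = c(10600L, 8100L, 5100L, 33600L, 26100L),
    barcode = "BC1", support = 1L
  )
  act <- gene_activity_scores(frags, gt)
  # in-body and promoter-window fragments count; 2001 bp upstream does not
  expect_equal(act$activity[act$gene == "gplus"], 2L)
  # minus-strand gene: upstream is to the right
  expect_equal(act$activity[act$gene == "gminus"], 1L)

  # brute-force oracle on random fragments
  withr::with_seed(95, {
    start <- sample.int(50000L, 1000L)
    rf <- tibble(chrom = "chr1", start = start, end = start + 100L,
                 barcode = sprintf("BC%d", sample.int(4L, 1000L, TRUE)),
                 support = 1L)
  })
  act2 <- gene_activity_scores(rf, gt)
  oracle <- purrr::map_dfr(seq_len(nrow(gt)), function(i) {
    w_s <- if (gt$strand[i] == "+") gt$start[i] - 2000L else gt$start[i]
    w_e <- if (gt$strand[i] == "+") gt$end[i] else gt$end[i] + 2000L
    hit <- rf$start + 1L <= w_e & rf$end >= w_s
    tibble(gene = gt$gene[i], barcode = rf$barcode[hit])
  }) %>% count(barcode, gene, name = "activity")
  expect_equal(
    arrange(act2, barcode, gene)$activity,
    arrange(oracle, barcode, gene)$activity
  )
})

test_that("signature scores are z-score means with degenerate-gene handling", {
  act <- tibble(barcode = rep(c("a", "b", "c"), each = 2),
                gene = rep(c("g1", "g2"), 3),
                activity = c(5, 1, 5, 2, 5, 3))
  # g1 constant -> contributes 0; one-gene set equals that gene's z-score
  s1 <- signature_score(act, "g1")
  expect_true(all(s1$score == 0))
  s2 <- signature_score(act, "g2")
  expect_equal(s2$score, as.numeric(scale(c(1, 2, 3))))
  s12 <- signature_score(act, c("g1", "g2"))
  expect_equal(s12$score, s2$score / 2)

  # a planted high-signature subpopulation separates strongly
  withr::with_seed(96, {
    n <- 100L
    mat <- matrix(rpois(n * 5L, 5), nrow = n,
                  dimnames = list(sprintf("BC%03d", 1:n),
                                  sprintf("g%d", 1:5)))
    mat[1:30, 1:3] <- mat[1:30, 1:3] + 6L
  })
  sc <- signature_score(mat, c("g1", "g2", "g3"))
  hi <- sc$score[sc$barcode %in% sprintf("BC%03d", 1:30)]
  lo <- sc$score[!sc$barcode %in% sprintf("BC%03d", 1:30)]
  expect_lt(wilcoxon_rank_sum(hi, lo, exact_max = 0L)$p_value, 0.01)
})

test_that("aggregate profile correlation is scale-invariant on the raw scale", {
  withr::with_seed(97, a <- setNames(rpois(200, 20), sprintf("p%d", 1:200)))
  expect_equal(aggregate_profile_correlation(a, a), 1)
  expect_equal(aggregate_profile_correlation(a, 2 * a, log1p_transform = FALSE), 1)
  expect_gt(aggregate_profile_correlation(a, 2 * a), 0.999)
  # replicate pairs with Poisson noise land in a high-correlation band
  withr::with_seed(98, {
    lam <- rlnorm(300, 3, 1)
    r1 <- setNames(rpois(300, lam), sprintf("p%d", 1:300))
    r2 <- setNames(rpois(300, lam), sprintf("p%d", 1:300))
  })
  r <- aggregate_profile_correlation(r1, r2)
  expect_gt(r, 0.85)
  expect_error(aggregate_profile_correlation(a[1:2], a[1:2]), "3 shared")
})
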