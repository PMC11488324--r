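suppressPackageStartupMessages(library(dplyr))

# small genome with a toy mito chromosome; gene table left empty unless asked
toy_genome <- function(mito_length = 400L, seed = 3L,
                       nuclear = c(chr1 = 2e5L, chr2 = 2e5L)) {
  genome_spec("mm10", nuclear, mito_length = mito_length, seed = seed)
}

phred_string <- function(q, len) strrep(intToUtf8(q + 33L), len)

# one mito read; qual defaults to a constant-quality string
make_read <- function(barcode, pos, seq, strand = "+", mapq = 60L, nm = 0L,
                      qual = phred_string(37L, nchar(seq)), chrom = "chrM") {
  tibble(barcode = barcode, chrom = chrom, pos = as.integer(pos),
         strand = strand, mapq = as.integer(mapq), nm = as.integer(nm),
         seq = seq, qual = qual)
}

# reference-matching read of given length starting at pos
ref_read <- function(genome, barcode, pos, len = 20L, ...) {
  make_read(barcode, pos, substr(genome$mito_seq, pos, pos + len - 1L), ...)
}

# independent per-read / per-base pileup oracle (plain double loop)
naive_pileup <- function(reads, mito_length, min_bq = 20L, min_mapq = 30L,
                         max_nm = 2L) {
  acc <- list()
  for (i in seq_len(nrow(reads))) {
    if (reads$mapq[i] < min_mapq || reads$nm[i] > max_nm) next
    s <- strsplit(reads$seq[i], "")[[1]]
    q <- utf8ToInt(reads$qual[i]) - 33L
    for (j in seq_along(s)) {
      p <- reads$pos[i] + j - 1L
      if (p > mito_length) next
      if (q[j] < min_bq) next
      if (!s[j] %in% c("A", "C", "G", "T")) next
      key <- paste(reads$barcode[i], p, s[j], reads$strand[i], sep = "|")
      acc[[key]] <- (acc[[key]] %||% 0L) + 1L
    }
  }
  if (!length(acc)) {
    return(tibble(barcode = character(), pos = integer(), allele = character(),
                  strand = character(), count = integer()))
  }
  parts <- strsplit(names(acc), "|", fixed = TRUE)
  tibble(
    barcode = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    allele = vapply(parts, `[`, "", 3),
    strand = vapply(parts, `[`, "", 4),
    count = unlist(acc, use.names = FALSE)
  ) %>% arrange(barcode, pos, allele, strand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planted variant table used by the recovery tests (package study design)
recovery_variants <- function(genome, seed = 42L) {
  recovery_variant_table(genome, seed = seed)
}

# simulate one genotyping dataset at ~100x per-cell mito coverage
recovery_dataset <- function(seed, n_cells = 120L, mito_length = 1500L) {
  d <- simulate_recovery_run(seed, n_cells = n_cells,
                             mito_length = mito_length)
  d$variants <- d$truth$variants
  d
}

# random pseudo-bulk candidate table exercising every branch of the cascade
random_candidates <- function(n, seed) {
  withr::with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    bulk_depth <- sample.int(2000L, n)
    alt_depth <- pmin(as.integer(round(runif(n) * bulk_depth)), bulk_depth)
    tibble(
      pos = sample.int(16299L, n), ref = ref,
      alt = vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                   character(1), USE.NAMES = FALSE),
      variant_id = sprintf("v%d", seq_len(n)),
      n_cells = sample.int(200L, n, replace = TRUE),
      alt_depth = alt_depth, bulk_depth = bulk_depth,
      bulk_vaf = alt_depth / bulk_depth,
      plus_strand_fraction = runif(n),
      mean_coverage = runif(n, 1, 300),
      strand_concordance = runif(n, -1, 1), vmr = runif(n, 0, 1)
    )
  })
}

# plain-loop reference implementation of the filtering cascade
naive_cascade <- function(cand, cfg, blacklist) {
  out <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    refd <- cand$bulk_depth[i] - cand$alt_depth[i]
    altd <- cand$alt_depth[i]
    f1 <- if (min(refd, altd) == 0) TRUE else
      max(refd, altd) / min(refd, altd) >= cfg$allele_depth_ratio
    psf <- cand$plus_strand_fraction[i]
    f2 <- max(psf, 1 - psf) <= cfg$strand_support_max
    f3 <- cand$bulk_depth[i] >= cfg$min_bulk_depth
    f7 <- cand$n_cells[i] >= cfg$min_cells
    f8 <- !cand$pos[i] %in% blacklist
    out[i] <- f1 && f2 && f3 && f7 && f8
  }
  out
}

# null peak-count dataset (no carrier effect) for permutation calibration;
# a single designated variant keeps the carrier/WT split near 50/50
null_peak_dataset <- function(seed, n_cells = 300L, n_peaks = 150L) {
  g <- toy_genome()
  vt <- recovery_variants(g)
  vt$designated <- c(TRUE, rep(FALSE, 7))
  cfg <- sim_config(n_cells = n_cells, frag_meanlog = log(100),
                    frag_sdlog = 0.3, n_peaks = n_peaks, variants = vt)
  truth <- simulate_cells(cfg, g, seed = seed)
  peaks <- withr::with_seed(seed, simulate_peaks(g, n_peaks, 300L))
  emb <- embed_carrier_effects(truth, peaks, list(), effect = 1,
                               n_affected = 0L, seed = seed + 1L)
  assignment <- tibble(barcode = truth$cells$barcode,
                       status = if_else(truth$cells$carrier, "carrier", "WT"))
  list(counts = emb$counts, assignment = assignment, truth = truth,
       peaks = peaks)
}
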