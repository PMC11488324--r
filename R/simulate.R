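#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic mtscATAC-seq
#' generator. Defaults emulate the study conditions the pipeline targets:
#' ~6,400 unique nuclear fragments per cell (log-normal), mitochondrial
#' content around 50% (Beta-distributed per cell type and age group, higher
#' and tighter in young cells), a ~2% droplet collision rate and a 0.5%
#' mito contamination rate, and per-cell heteroplasmy drawn from a
#' zero-inflated Beta: with probability `pi0` a cell carries none of a
#' variant, otherwise its VAF is Beta(a, b) (defaults 0.5, 50, i.e. mostly
#' sub-1% VAFs), plus a few near-homoplasmic sites.
#'
#' @param n_cells Number of barcodes to simulate.
#' @param species Assembly label (`"mm10"` or `"hg19"`).
#' @param doublet_rate Probability a barcode is a droplet collision.
#' @param contamination_rate Probability a singlet receives foreign mito
#'   reads.
#' @param contamination_frac Fraction of a contaminated cell's mito reads
#'   that originate from the foreign cell.
#' @param frag_meanlog,frag_sdlog Log-normal parameters of the per-cell
#'   unique nuclear fragment count.
#' @param mito_depth_scale Multiplier on the number of mito reads implied by
#'   the cell's mito-content fraction (use < 1 to scale coverage down).
#' @param read_length Mito read length (bp).
#' @param frag_length Nuclear fragment length (bp).
#' @param strand_prob Probability a mito read is on the plus strand.
#' @param phred_hi,phred_lo Phred qualities of ordinary and low-quality
#'   bases; `q_low_rate` is the per-base probability of a low-quality base.
#'   Sequencing errors are injected at the Phred-implied rate of each base.
#' @param mapq_hi,mapq_lo,mapq_fail_rate MAPQ of ordinary reads, MAPQ of the
#'   `mapq_fail_rate` fraction of reads simulated as poorly mapped.
#' @param nm_fail_rate Fraction of reads whose mismatch-count field is set
#'   above the mismatch filter (simulating misaligned reads).
#' @param p_peak Probability a nuclear fragment falls inside a peak.
#' @param n_peaks,peak_width Toy peak set geometry.
#' @param tss_enrichment Target ratio of Tn5 insertion density at TSSs
#'   (+/-100 bp) over distal flanks.
#' @param n_variants_low,n_variants_high Number of low-frequency and
#'   near-homoplasmic variants planted when no variant table is supplied.
#' @param pi0,beta_a,beta_b Zero-inflated Beta parameters of per-cell VAF for
#'   low-frequency variants.
#' @param cell_types Optional tibble (`cell_type`, `age_group`, `prop`,
#'   `content_mean`, `content_conc`) describing the population; a default
#'   young/aged two-group, five-type population is used when `NULL`.
#' @param variants Optional variant truth tibble (`variant_id`, `pos`, `ref`,
#'   `alt`, `pi0`, `beta_a`, `beta_b`, `freq_class`, `designated`).
#' @param seed Seed recorded in the output manifest.
#'
#' @return A validated list of class `mtsc_sim_config`.
#' @export
sim_config <- function(n_cells = 500L,
                       species = "mm10",
                       doublet_rate = 0.02,
                       contamination_rate = 0.005,
                       contamination_frac = 0.2,
                       frag_meanlog = log(6400),
                       frag_sdlog = 0.6,
                       mito_depth_scale = 1,
                       read_length = 80L,
                       frag_length = 150L,
                       strand_prob = 0.5,
                       phred_hi = 37L, phred_lo = 15L, q_low_rate = 0.05,
                       mapq_hi = 60L, mapq_lo = 10L, mapq_fail_rate = 0.05,
                       nm_fail_rate = 0.02,
                       p_peak = 0.35,
                       n_peaks = 200L, peak_width = 500L,
                       tss_enrichment = 5,
                       n_variants_low = 8L, n_variants_high = 2L,
                       pi0 = 0.8, beta_a = 0.5, beta_b = 50,
                       cell_types = NULL,
                       variants = NULL,
                       seed = NULL) {
  cfg <- as.list(environment())
  rates <- c("doublet_rate", "contamination_rate", "contamination_frac",
             "strand_prob", "q_low_rate", "mapq_fail_rate", "nm_fail_rate",
             "p_peak", "pi0")
  for (f in rates) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("configuration error: field '%s' must be a rate in [0, 1]", f))
    }
  }
  for (f in c("n_cells", "frag_sdlog", "read_length", "frag_length",
              "beta_a", "beta_b", "mito_depth_scale", "tss_enrichment")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || is.na(v) || v <= 0) {
      abort(sprintf("configuration error: field '%s' must be positive", f))
    }
  }
  if (!is.null(cell_types)) {
    need <- c("cell_type", "age_group", "prop", "content_mean", "content_conc")
    if (!all(need %in% names(cell_types))) {
      abort(paste0("configuration error: field 'cell_types' needs columns ",
                   paste(need, collapse = ", ")))
    }
  }
  structure(cfg, class = "mtsc_sim_config")
}

sim_config_keys <- function() {
  setdiff(names(formals(sim_config)), c("cell_types", "variants"))
}

default_cell_types <- function() {
  types <- c("B", "CD4T", "CD8T", "Plasma", "Neutrophil")
  tidyr::expand_grid(cell_type = types, age_group = c("young", "aged")) %>%
    mutate(
      prop = 1 / dplyr::n(),
      content_mean = if_else(.data$age_group == "young", 0.55, 0.45),
      content_conc = if_else(.data$age_group == "young", 20, 8)
    )
}

default_variants <- function(config, genome) {
  n <- config$n_variants_low + config$n_variants_high
  pos <- sort(sample(seq(100L, genome$mito_length - 100L), n))
  ref <- ref_base(genome, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  cls <- c(rep("low", config$n_variants_low), rep("high", config$n_variants_high))
  tibble(
    variant_id = sprintf("m.%d%s>%s", pos, ref, alt),
    pos = pos, ref = ref, alt = alt, freq_class = cls,
    pi0 = if_else(cls == "low", config$pi0, 0.3),
    beta_a = if_else(cls == "low", config$beta_a, 50),
    beta_b = if_else(cls == "low", config$beta_b, 1),
    designated = FALSE
  ) %>%
    mutate(designated = dplyr::row_number() %in%
             c(which(cls == "high"), which(cls == "low")[1]))
}

#' Simulate a cell population with ground truth
#'
#' Draws the per-barcode truth table the downstream stages are tested
#' against: species, cell type and age group, doublet and contamination
#' status, mito-content fraction (Beta per type x age), per-variant true VAF
#' (zero-inflated Beta), and carrier status for the designated variant set.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_spec()].
#' @param seed Integer seed; the run is deterministic given the seed.
#'
#' @return A list of class `mtsc_truth` with tibbles `cells` (one row per
#'   barcode), `variants` (one row per planted variant) and `cell_vaf` (long,
#'   barcode x variant true VAF).
#' @export
simulate_cells <- function(config, genome, seed = config$seed %||% 1L) {
  stopifnot(inherits(config, "mtsc_sim_config"), inherits(genome, "genome_spec"))
  withr::with_seed(seed, {
    ct <- config$cell_types %||% default_cell_types()
    if (nrow(ct) < 2L) abort("configuration error: field 'cell_types' needs >= 2 rows")
    n <- as.integer(config$n_cells)
    idx <- sample(nrow(ct), n, replace = TRUE, prob = ct$prop)
    cells <- tibble(
      barcode = sprintf("BC%05d", seq_len(n)),
      species = config$species,
      cell_type = ct$cell_type[idx],
      age_group = ct$age_group[idx],
      doublet = as.logical(rbinom(n, 1, config$doublet_rate)),
      mito_content = rbeta(n, ct$content_mean[idx] * ct$content_conc[idx],
                           (1 - ct$content_mean[idx]) * ct$content_conc[idx]),
      n_nuclear_frags = pmax(10L, as.integer(round(rlnorm(n, config$frag_meanlog,
                                                          config$frag_sdlog))))
    )
    # a collision merges two cells: record the partner's type label
    cells$doublet_type <- NA_character_
    dbl <- which(cells$doublet)
    if (length(dbl)) {
      j <- sample(nrow(ct), length(dbl), replace = TRUE, prob = ct$prop)
      cells$doublet_type[dbl] <- ct$cell_type[j]
    }
    cells$contaminated <- !cells$doublet &
      as.logical(rbinom(n, 1, config$contamination_rate))
    cells$contamination_frac <- if_else(cells$contaminated,
                                        config$contamination_frac, 0)
    cells$n_mito_reads <- as.integer(round(
      cells$n_nuclear_frags * cells$mito_content / (1 - cells$mito_content) *
        config$mito_depth_scale))

    variants <- config$variants %||% default_variants(config, genome)
    cell_vaf <- tidyr::expand_grid(barcode = cells$barcode,
                                   variant_id = variants$variant_id) %>%
      left_join(variants, by = "variant_id") %>%
      mutate(
        true_vaf = if_else(
          as.logical(rbinom(dplyr::n(), 1, .data$pi0)), 0,
          rbeta(dplyr::n(), .data$beta_a, .data$beta_b)
        )
      ) %>%
      select("barcode", "variant_id", "true_vaf")
    carriers <- cell_vaf %>%
      inner_join(variants[variants$designated, "variant_id"], by = "variant_id") %>%
      group_by(.data$barcode) %>%
      summarise(carrier = any(.data$true_vaf > 0), .groups = "drop")
    cells <- left_join(cells, carriers, by = "barcode")
    if (is.null(cells$carrier)) cells$carrier <- FALSE
    cells$carrier[is.na(cells$carrier)] <- FALSE
    structure(list(cells = cells, variants = variants, cell_vaf = cell_vaf,
                   config = config, seed = seed),
              class = "mtsc_truth")
  })
}

#' @export
print.mtsc_truth <- function(x, ...) {
  cat("<mtsc_truth> ", nrow(x$cells), " cells, ", nrow(x$variants),
      " planted variants (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate nuclear fragments and mitochondrial reads
#'
#' Generates the two read-level files implied by a truth table: nuclear Tn5
#' fragments concentrated in a toy peak set (with TSS-proximal insertion
#' enrichment), and mitochondrial reads carrying alt alleles per the true
#' per-cell VAFs via binomial sampling, with Phred-modelled base errors and
#' MAPQ / mismatch-count fields populated so a configurable fraction of reads
#' fails each read-level filter. Contamination is realised as reads whose
#' genotype is drawn from a donor cell.
#'
#' @param truth An `mtsc_truth` from [simulate_cells()].
#' @param genome The same `genome_spec` used for the truth table.
#' @param seed Integer seed.
#'
#' @return A list with tibbles `fragments`, `mito_reads`, `peaks` and integer
#'   vector `tss` (TSS positions on the toy nuclear genome).
#' @export
simulate_fragments <- function(truth, genome, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "mtsc_truth"))
  config <- truth$config
  if (!identical(config$species, genome$species)) {
    abort("truth/config species does not match the supplied genome")
  }
  withr::with_seed(seed, {
    peaks <- simulate_peaks(genome, config$n_peaks, config$peak_width)
    tss <- as.integer(round((peaks$start + peaks$end) / 2))[
      seq(1, nrow(peaks), by = 5)]
    tss_chrom <- peaks$chrom[seq(1, nrow(peaks), by = 5)]
    frags <- sim_nuclear_fragments(truth$cells, genome, peaks, tss, tss_chrom, config)
    reads <- sim_mito_reads(truth, genome, config)
    list(fragments = frags, mito_reads = reads, peaks = peaks,
         tss = tibble(chrom = tss_chrom, pos = tss))
  })
}

#' Simulate a toy peak set
#'
#' Uniformly placed fixed-width peaks on the nuclear chromosomes,
#' position-sorted with sequential ids.
#'
#' @param genome A `genome_spec`.
#' @param n_peaks Number of peaks.
#' @param width Peak width (bp).
#' @return Peak tibble (`chrom`, `start`, `end`, `id`).
#' @export
simulate_peaks <- function(genome, n_peaks, width) {
  lens <- genome$nuclear_chroms
  chrom <- sample(names(lens), n_peaks, replace = TRUE,
                  prob = as.numeric(lens) / sum(as.numeric(lens)))
  start <- vapply(chrom, function(ch) sample.int(lens[[ch]] - width, 1),
                  integer(1), USE.NAMES = FALSE)
  tibble(chrom = chrom, start = start, end = start + width,
         id = sprintf("peak_%05d", seq_len(n_peaks))) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(id = sprintf("peak_%05d", dplyr::row_number()))
}

sim_nuclear_fragments <- function(cells, genome, peaks, tss, tss_chrom, config) {
  n_tot <- sum(cells$n_nuclear_frags)
  barcode <- rep(cells$barcode, cells$n_nuclear_frags)
  lens <- genome$nuclear_chroms
  g_len <- sum(as.numeric(lens))
  flen <- config$frag_length
  # insertion-density mixture calibrated so TSS windows reach the target
  # enrichment over distal flanks: a TSS-assigned fragment puts its start
  # inside the window and, when the fragment is short enough, part of the
  # time its other end too (factor 1 + q); the background density is
  # N * (2 - w) / G since one of a TSS fragment's two insertions is diverted
  q_mate <- max(0, 202 - flen) / 201
  A <- (config$tss_enrichment - 1) * 201 * length(tss) / g_len
  w_tss <- min(0.9, 2 * A / (1 + q_mate + A))
  kind <- sample(c("peak", "tss", "bg"), n_tot, replace = TRUE,
                 prob = c(config$p_peak, w_tss, max(0, 1 - config$p_peak - w_tss)))
  chrom <- character(n_tot); start <- integer(n_tot)
  i_bg <- which(kind == "bg")
  if (length(i_bg)) {
    chrom[i_bg] <- sample(names(lens), length(i_bg), replace = TRUE,
                          prob = as.numeric(lens) / g_len)
    start[i_bg] <- floor(runif(length(i_bg)) * (lens[chrom[i_bg]] - flen))
  }
  i_pk <- which(kind == "peak")
  if (length(i_pk)) {
    p <- sample.int(nrow(peaks), length(i_pk), replace = TRUE)
    chrom[i_pk] <- peaks$chrom[p]
    span <- pmax(1L, peaks$end[p] - peaks$start[p] - flen)
    start[i_pk] <- peaks$start[p] + floor(runif(length(i_pk)) * span)
  }
  i_ts <- which(kind == "tss")
  if (length(i_ts)) {
    t <- sample.int(length(tss), length(i_ts), replace = TRUE)
    chrom[i_ts] <- tss_chrom[t]
    start[i_ts] <- pmax(0L, tss[t] - 100L + floor(runif(length(i_ts)) * 201))
  }
  tibble(chrom = chrom, start = start, end = start + flen,
         barcode = barcode, support = 1L) %>%
    arrange(.data$chrom, .data$start)
}

phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

sim_mito_reads <- function(truth, genome, config) {
  cells <- truth$cells
  n_reads <- cells$n_mito_reads
  n_tot <- sum(n_reads)
  if (n_tot == 0L) {
    return(tibble(barcode = character(), chrom = character(), pos = integer(),
                  strand = character(), mapq = integer(), nm = integer(),
                  seq = character(), qual = character()))
  }
  rl <- as.integer(config$read_length)
  L <- genome$mito_length
  barcode <- rep(cells$barcode, n_reads)
  # genotype source: contaminated cells draw a fraction of reads from a donor
  origin <- barcode
  cont <- cells$barcode[cells$contaminated]
  if (length(cont) && nrow(cells) > 1L) {
    is_cont_read <- barcode %in% cont &
      runif(n_tot) < config$contamination_frac
    k <- sum(is_cont_read)
    if (k) {
      donors <- sample(cells$barcode, k, replace = TRUE)
      origin[is_cont_read] <- donors
    }
  }
  pos <- sample.int(L - rl + 1L, n_tot, replace = TRUE)
  strand <- if_else(runif(n_tot) < config$strand_prob, "+", "-")
  seq <- substring(genome$mito_seq, pos, pos + rl - 1L)
  n_mm <- integer(n_tot)

  # plant alt alleles per the origin cell's true VAF
  vaf_wide <- truth$cell_vaf %>%
    tidyr::pivot_wider(names_from = "variant_id", values_from = "true_vaf")
  vmap <- as.data.frame(vaf_wide[-1])
  rownames(vmap) <- vaf_wide$barcode
  for (i in seq_len(nrow(truth$variants))) {
    v <- truth$variants[i, ]
    cov <- which(pos <= v$pos & pos + rl > v$pos)
    if (!length(cov)) next
    p_alt <- vmap[origin[cov], v$variant_id]
    take <- cov[runif(length(cov)) < p_alt]
    if (length(take)) {
      off <- v$pos - pos[take] + 1L
      substr(seq[take], off, off) <- v$alt
      n_mm[take] <- n_mm[take] + 1L
    }
  }

  # per-base qualities: mostly phred_hi with a q_low_rate fraction at
  # phred_lo; errors injected at the Phred-implied rate of each base
  qual <- rep(strrep(phred_char(config$phred_hi), rl), n_tot)
  k_lo <- rbinom(n_tot, rl, config$q_low_rate)
  qual <- scatter_edit(qual, k_lo, rl, phred_char(config$phred_lo))
  err_hi <- rbinom(n_tot, rl - k_lo, 10^(-config$phred_hi / 10))
  err_lo <- rbinom(n_tot, k_lo, 10^(-config$phred_lo / 10))
  k_err <- err_hi + err_lo
  seq <- scatter_edit(seq, k_err, rl, NULL)
  n_mm <- n_mm + k_err

  mapq <- if_else(runif(n_tot) < config$mapq_fail_rate,
                  as.integer(config$mapq_lo), as.integer(config$mapq_hi))
  nm_fail <- runif(n_tot) < config$nm_fail_rate
  nm <- if_else(nm_fail, 3L + as.integer(rbinom(n_tot, 3, 0.5)), n_mm)
  tibble(barcode = barcode, chrom = genome$mito_chrom, pos = pos,
         strand = strand, mapq = mapq, nm = nm, seq = seq, qual = qual)
}

# replace `k[i]` random positions of string i; `value` NULL means a random
# different base (sequencing error), otherwise the given character
scatter_edit <- function(x, k, width, value) {
  rounds <- max(k, 0L)
  if (!is.finite(rounds) || rounds == 0L) return(x)
  for (r in seq_len(rounds)) {
    i <- which(k >= r)
    if (!length(i)) break
    p <- sample.int(width, length(i), replace = TRUE)
    if (is.null(value)) {
      cur <- substr(x[i], p, p)
      repl <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1), USE.NAMES = FALSE)
      substr(x[i], p, p) <- repl
    } else {
      substr(x[i], p, p) <- value
    }
  }
  x
}

#' Simulate a two-species (barnyard) mixing experiment
#'
#' Cells are assigned to one of two species; a planted fraction of barcodes
#' are collisions (capturing one cell of each species, nuclear fragments
#' split Beta(5,5)), and a planted fraction of singlets are contaminated
#' (a fraction of their mito reads relabelled from a cell of the other
#' species). Returns per-barcode per-species fragment and mito read counts
#' ready for [classify_barnyard()], plus the truth table.
#'
#' @param config A [sim_config()]; `doublet_rate` and `contamination_rate`
#'   are the planted collision and contamination rates.
#' @param genomes List of two `genome_spec`s (the two species).
#' @param seed Integer seed.
#' @param mean_frags,mean_mito Mean per-cell nuclear fragment and mito read
#'   counts (Poisson).
#'
#' @return A list with `cells` (per-barcode counts:
#'   `n_frag_<sp1>`, `n_frag_<sp2>`, `n_mito_<sp1>`, `n_mito_<sp2>`) and
#'   `truth` (per-barcode species, doublet and contamination flags).
#' @export
simulate_barnyard <- function(config, genomes, seed = 1L,
                              mean_frags = 300, mean_mito = 60) {
  stopifnot(length(genomes) == 2L)
  sp <- vapply(genomes, function(g) g$species, character(1))
  if (sp[1] == sp[2]) abort("barnyard simulation needs two distinct species")
  withr::with_seed(seed, {
    n <- as.integer(config$n_cells)
    species <- sample(sp, n, replace = TRUE)
    doublet <- as.logical(rbinom(n, 1, config$doublet_rate))
    n_frag <- stats::rpois(n, mean_frags)
    n_mito <- stats::rpois(n, mean_mito)
    # collisions carry both species; Beta(5,5) split keeps them away from
    # purity thresholds near 1
    mix <- if_else(doublet, rbeta(n, 5, 5), 1)
    f1 <- as.integer(round(n_frag * if_else(species == sp[1], mix, 1 - mix)))
    f2 <- n_frag - f1
    m1 <- as.integer(round(n_mito * if_else(species == sp[1], mix, 1 - mix)))
    m2 <- n_mito - m1
    contaminated <- !doublet & as.logical(rbinom(n, 1, config$contamination_rate))
    k <- which(contaminated)
    if (length(k)) {
      # relabel a fraction of mito reads to the other species' genome
      swap <- as.integer(round(n_mito[k] * config$contamination_frac))
      own1 <- species[k] == sp[1]
      m1[k] <- if_else(own1, m1[k] - swap, m1[k] + swap)
      m2[k] <- if_else(own1, m2[k] + swap, m2[k] - swap)
    }
    cells <- tibble(barcode = sprintf("BY%05d", seq_len(n)))
    cells[[paste0("n_frag_", sp[1])]] <- f1
    cells[[paste0("n_frag_", sp[2])]] <- f2
    cells[[paste0("n_mito_", sp[1])]] <- pmax(m1, 0L)
    cells[[paste0("n_mito_", sp[2])]] <- pmax(m2, 0L)
    truth <- tibble(barcode = cells$barcode, species = species,
                    doublet = doublet, contaminated = contaminated)
    list(cells = cells, truth = truth, species = sp, seed = seed)
  })
}

#' Plant carrier-linked accessibility effects in a peak-count matrix
#'
#' Builds a peaks x cells detection matrix where a chosen set of peaks has
#' its accessibility rate multiplied by `effect` in carrier cells, and writes
#' a planted motif instance into the sequence of every affected peak.
#'
#' @param truth An `mtsc_truth` (uses the `carrier` flag).
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `id`).
#' @param pwms Named list of PWMs (see [random_pwm()]); the first is planted.
#' @param effect Multiplicative accessibility effect in carrier cells
#'   (1 = no effect).
#' @param n_affected Number of affected peaks.
#' @param seed Integer seed.
#'
#' @return List with `counts` (peaks x cells 0/1 matrix), `peak_seqs` (named
#'   character), `affected` (affected peak ids), `planted_motif`.
#' @export
embed_carrier_effects <- function(truth, peaks, pwms, effect = 2,
                                  n_affected = 50L, seed = 1L) {
  stopifnot(inherits(truth, "mtsc_truth"))
  withr::with_seed(seed, {
    cells <- truth$cells
    n_affected <- min(n_affected, nrow(peaks))
    affected <- if (n_affected > 0) sample(peaks$id, n_affected) else character()
    base_rate <- rbeta(nrow(peaks), 2, 6)
    depth <- rlnorm(nrow(cells), 0, 0.3)
    rate <- outer(base_rate, rep(1, nrow(cells)))
    if (length(affected) && effect != 1) {
      rate[peaks$id %in% affected, cells$carrier] <-
        rate[peaks$id %in% affected, cells$carrier] * effect
    }
    p <- 1 - (1 - pmin(rate, 0.95))^rep(depth, each = nrow(peaks))
    counts <- matrix(rbinom(length(p), 1L, p), nrow = nrow(peaks),
                     dimnames = list(peaks$id, cells$barcode))
    width <- peaks$end - peaks$start
    seqs <- vapply(width, random_dna, character(1))
    names(seqs) <- peaks$id
    if (length(affected) && length(pwms)) {
      # the consensus sequence is planted so every affected peak carries a
      # scannable instance
      inst <- consensus_pwm(pwms[[1]])
      off <- vapply(width[match(affected, peaks$id)] - nchar(inst) + 1L,
                    function(m) sample.int(m, 1), integer(1))
      substr(seqs[affected], off, off + nchar(inst) - 1L) <- inst
    }
    list(counts = counts, peak_seqs = seqs, affected = affected,
         planted_motif = if (length(pwms)) names(pwms)[1] else NA_character_)
  })
}

#' Write a simulated dataset to disk
#'
#' Convenience wrapper: simulates cells and reads, then writes the 10x-style
#' fragments TSV, the MRF v1 mito reads TSV, the peak BED, the truth tables
#' and a flat key:value manifest recording the seed.
#'
#' @param config A [sim_config()].
#' @param genome A [genome_spec()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The output directory, invisibly.
#' @export
simulate_dataset <- function(config, genome, outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_cells(config, genome, seed = seed)
  sim <- simulate_fragments(truth, genome, seed = seed + 1L)
  write_fragments(sim$fragments, file.path(outdir, "fragments.tsv"))
  write_mito_reads(sim$mito_reads, file.path(outdir, "mito_reads.tsv"))
  write_peaks(sim$peaks, file.path(outdir, "peaks.bed"))
  readr::write_tsv(truth$cells, file.path(outdir, "truth_cells.tsv"), progress = FALSE)
  readr::write_tsv(truth$variants, file.path(outdir, "truth_variants.tsv"), progress = FALSE)
  readr::write_tsv(truth$cell_vaf, file.path(outdir, "truth_cell_vaf.tsv"), progress = FALSE)
  manifest <- list(package = "mtscatac", seed = seed, n_cells = config$n_cells,
                   species = config$species)
  write_config(manifest, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
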