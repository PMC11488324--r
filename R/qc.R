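insertions_of <- function(fragments) {
  tibble(
    barcode = rep(fragments$barcode, 2L),
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start, fragments$end - 1L)
  )
}

#' Per-cell TSS enrichment score
#'
#' The score for a cell is the mean Tn5 insertion density (both fragment
#' ends) per bp within +/-`window_bp` of any TSS, divided by the mean density
#' in distal flanks (`flank_bp` away on either side, 100 bp wide). A
#' pseudocount of one insertion is added to the flank count so cells with
#' empty flanks get a finite, window-normalised score.
#'
#' @param fragments Fragment tibble (see [read_fragments()]).
#' @param tss Tibble of TSS positions with columns `chrom`, `pos`.
#' @param window_bp Half-width of the TSS window (default 100).
#' @param flank_bp Distance to the distal flank (default 2000; the flank is
#'   the 100 bp ending at that distance, i.e. 1901-2000 bp from the TSS).
#' @param barcodes Optional barcodes to score; barcodes without fragments get
#'   score 0 with a warning.
#'
#' @return Tibble `barcode`, `tss_enrichment`.
#' @export
compute_tss_enrichment <- function(fragments, tss, window_bp = 100L,
                                   flank_bp = 2000L, barcodes = NULL) {
  if (!nrow(tss)) abort("at least one TSS is required")
  ins <- insertions_of(fragments)
  win_w <- 2L * window_bp + 1L
  flank_w <- 100L
  win <- tibble(chrom = tss$chrom, start = tss$pos - window_bp,
                end = tss$pos + window_bp)
  flank <- tibble(
    chrom = rep(tss$chrom, 2L),
    start = c(tss$pos - flank_bp, tss$pos + flank_bp - flank_w + 1L),
    end = c(tss$pos - flank_bp + flank_w - 1L, tss$pos + flank_bp)
  )
  count_in <- function(regions) {
    hits <- overlap_pairs(ins$chrom, ins$pos, ins$pos + 1L,
                          regions$chrom, regions$start, regions$end + 1L)
    table(ins$barcode[unique(hits$query)])
  }
  n_win <- count_in(win)
  n_flank <- count_in(flank)
  bcs <- barcodes %||% sort(unique(fragments$barcode))
  missing_bc <- setdiff(bcs, unique(fragments$barcode))
  if (length(missing_bc)) {
    warn(sprintf("%d barcode(s) have no fragments; TSS score set to 0",
                 length(missing_bc)))
  }
  win_bp_tot <- nrow(tss) * win_w
  flank_bp_tot <- nrow(tss) * 2L * flank_w
  w <- as.numeric(n_win[bcs]); w[is.na(w)] <- 0
  f <- as.numeric(n_flank[bcs]); f[is.na(f)] <- 0
  score <- (w / win_bp_tot) / ((f + 1) / flank_bp_tot)
  score[bcs %in% missing_bc] <- 0
  tibble(barcode = bcs, tss_enrichment = score)
}

# interval overlap (>= 1 bp) between two sets of half-open intervals,
# chromosome-aware; returns query/subject index pairs
overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out_q <- integer(0); out_s <- integer(0)
  for (ch in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == ch); si <- which(s_chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi] + 1L, q_end[qi]),
      IRanges::IRanges(s_start[si] + 1L, s_end[si])
    )
    out_q <- c(out_q, qi[S4Vectors::queryHits(hits)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(hits)])
  }
  list(query = out_q, subject = out_s)
}

#' Per-cell fraction of fragments in peaks (FRiP)
#'
#' A fragment is "in a peak" iff it overlaps any peak by at least 1 bp.
#'
#' @param fragments Fragment tibble.
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @return Tibble `barcode`, `n_fragments`, `frip`.
#' @export
compute_frip <- function(fragments, peaks) {
  tot <- count(fragments, .data$barcode, name = "n_fragments")
  if (!nrow(peaks)) return(mutate(tot, frip = 0))
  hits <- overlap_pairs(fragments$chrom, fragments$start, fragments$end,
                        peaks$chrom, peaks$start, peaks$end)
  in_peak <- tibble(barcode = fragments$barcode[unique(hits$query)]) %>%
    count(.data$barcode, name = "n_in_peak")
  tot %>%
    left_join(in_peak, by = "barcode") %>%
    mutate(frip = dplyr::coalesce(.data$n_in_peak, 0L) / .data$n_fragments) %>%
    select("barcode", "n_fragments", "frip")
}

#' Per-cell mitochondrial content percentage
#'
#' 100 x mito / (mito + nuclear) sequencing fragments per barcode, the proxy
#' used for mitochondrial copy number (mtDNA-CN).
#'
#' @param fragments Nuclear fragment tibble.
#' @param mito_reads Mito read tibble (one row per mito fragment/read).
#' @return Tibble `barcode`, `n_nuclear`, `n_mito`, `mito_content_pct`.
#' @export
compute_mito_content <- function(fragments, mito_reads) {
  nuc <- count(fragments, .data$barcode, name = "n_nuclear")
  mito <- count(mito_reads, .data$barcode, name = "n_mito")
  dplyr::full_join(nuc, mito, by = "barcode") %>%
    mutate(
      n_nuclear = dplyr::coalesce(.data$n_nuclear, 0L),
      n_mito = dplyr::coalesce(.data$n_mito, 0L),
      mito_content_pct = 100 * .data$n_mito /
        pmax(.data$n_mito + .data$n_nuclear, 1L)
    ) %>%
    arrange(.data$barcode)
}

#' Per-cell mitochondrial mean coverage
#'
#' Per-cell coverage (x) is the total number of aligned mito bases divided by
#' the mitochondrial genome length. The cohort mean and its normal-theory 95%
#' confidence interval are attached as attribute `"summary"`.
#'
#' @param mito_reads Mito read tibble.
#' @param mito_length Mitochondrial genome length (bp).
#' @return Tibble `barcode`, `mean_coverage`, with attribute `summary`
#'   (`mean`, `ci_lo`, `ci_hi`, `n_cells`).
#' @export
compute_mito_mean_coverage <- function(mito_reads, mito_length) {
  per_cell <- mito_reads %>%
    group_by(.data$barcode) %>%
    summarise(mean_coverage = sum(nchar(.data$seq)) / mito_length,
              .groups = "drop")
  m <- if (nrow(per_cell)) mean(per_cell$mean_coverage) else 0
  se <- if (nrow(per_cell) > 1L) stats::sd(per_cell$mean_coverage) / sqrt(nrow(per_cell)) else 0
  attr(per_cell, "summary") <- tibble(
    mean = m, ci_lo = m - qnorm(0.975) * se, ci_hi = m + qnorm(0.975) * se,
    n_cells = nrow(per_cell)
  )
  per_cell
}

#' Fold change between two cohort mean coverages
#'
#' Reports the ratio of two mean coverage depths (e.g. mito-optimised vs
#' standard scATAC libraries), rounded to two decimals as conventionally
#' printed.
#'
#' @param mean_num,mean_den Cohort mean coverages (x).
#' @return The fold change, rounded to 2 decimals.
#' @export
coverage_fold_change <- function(mean_num, mean_den) {
  if (any(mean_den <= 0)) abort("denominator coverage must be positive")
  round(mean_num / mean_den, 2)
}

#' Apply per-cell QC filters
#'
#' A cell passes iff TSS enrichment >= `tss_min`, unique nuclear fragment
#' count between `frag_range[1]` and `frag_range[2]` (inclusive), and
#' FRiP strictly greater than `frip_min`.
#'
#' @param metrics Tibble with `tss_enrichment`, `n_fragments`, `frip`.
#' @param tss_min,frag_range,frip_min Thresholds (defaults 1.2,
#'   c(2000, 50000), 0.2).
#' @return `metrics` with a logical `pass_qc` column.
#' @export
apply_cell_filters <- function(metrics, tss_min = 1.2,
                               frag_range = c(2000L, 50000L),
                               frip_min = 0.2) {
  mutate(metrics, pass_qc =
           .data$tss_enrichment >= tss_min &
           .data$n_fragments >= frag_range[1] &
           .data$n_fragments <= frag_range[2] &
           .data$frip > frip_min)
}

#' Select the top cells by chromatin complexity
#'
#' Ranks cells by unique nuclear fragment count (descending; ties broken
#' lexicographically by barcode) and returns the top `n` barcodes.
#'
#' @param metrics Tibble with `barcode`, `n_fragments`.
#' @param n Number of cells to keep.
#' @return Character vector of barcodes.
#' @export
select_top_cells <- function(metrics, n) {
  metrics %>%
    arrange(desc(.data$n_fragments), .data$barcode) %>%
    slice_head(n = n) %>%
    pull("barcode")
}

#' Classify a barnyard (two-species mixing) experiment
#'
#' A barcode is a singlet iff its major-species nuclear fragment fraction is
#' at least `purity_threshold`, otherwise mixed (a droplet collision). Among
#' singlets, a cell is contaminated iff its minor-species fraction of mito
#' reads is at least `mito_minor_threshold` - foreign-species mtDNA inside a
#' nuclear singlet. Barcodes with zero species-assignable nuclear fragments
#' are excluded and counted.
#'
#' @param cells Tibble with `barcode` and per-species counts
#'   `n_frag_<species>` (two columns) and `n_mito_<species>` (two columns),
#'   e.g. from [simulate_barnyard()].
#' @param purity_threshold Nuclear purity needed to call a singlet.
#' @param mito_minor_threshold Minor-species mito fraction that flags
#'   contamination.
#'
#' @return An object of class `mtsc_barnyard`: list with `cells` (per-cell
#'   calls) and `report` (one-row tibble of counts and rates).
#' @export
classify_barnyard <- function(cells, purity_threshold = 0.95,
                              mito_minor_threshold = 0.05) {
  frag_cols <- grep("^n_frag_", names(cells), value = TRUE)
  mito_cols <- grep("^n_mito_", names(cells), value = TRUE)
  if (length(frag_cols) != 2L || length(mito_cols) != 2L) {
    abort("cells must carry exactly two n_frag_<species> and two n_mito_<species> columns")
  }
  sp <- sub("^n_frag_", "", frag_cols)
  f1 <- cells[[frag_cols[1]]]; f2 <- cells[[frag_cols[2]]]
  m1 <- cells[[mito_cols[1]]]; m2 <- cells[[mito_cols[2]]]
  tot <- f1 + f2
  assignable <- tot > 0L
  major_frac <- pmax(f1, f2) / pmax(tot, 1L)
  species_call <- if_else(f1 >= f2, sp[1], sp[2])
  singlet <- assignable & major_frac >= purity_threshold
  mito_tot <- m1 + m2
  minor_mito_frac <- if_else(mito_tot > 0L,
                             pmin(m1, m2) / pmax(mito_tot, 1L), 0)
  contaminated <- singlet & minor_mito_frac >= mito_minor_threshold
  calls <- tibble(
    barcode = cells$barcode, species_call = species_call,
    assignable = assignable, major_fraction = major_frac,
    singlet = singlet, minor_mito_fraction = minor_mito_frac,
    contaminated = contaminated
  )
  n_cells <- sum(assignable)
  n_singlet <- sum(singlet)
  n_mixed <- n_cells - n_singlet
  report <- tibble(
    n_cells = n_cells, n_singlet = n_singlet, n_mixed = n_mixed,
    collision_rate = if (n_cells) n_mixed / n_cells else NA_real_,
    n_contaminated = sum(contaminated),
    contamination_rate = if (n_singlet) sum(contaminated) / n_singlet else NA_real_,
    n_excluded = sum(!assignable),
    purity_threshold = purity_threshold,
    mito_minor_threshold = mito_minor_threshold
  )
  structure(list(cells = calls, report = report), class = "mtsc_barnyard")
}

#' @export
print.mtsc_barnyard <- function(x, ...) {
  r <- x$report
  cat("<mtsc_barnyard> ", r$n_cells, " cells: ", r$n_mixed, " mixed (collision rate ",
      signif(100 * r$collision_rate, 3), "%), ", r$n_contaminated,
      " contaminated singlets (", signif(100 * r$contamination_rate, 3),
      "%)\n", sep = "")
  invisible(x)
}

#' @export
tidy.mtsc_barnyard <- function(x, ...) x$cells

#' @export
glance.mtsc_barnyard <- function(x, ...) x$report

#' Assemble the per-cell QC metrics table
#'
#' Convenience wrapper computing fragment counts, FRiP, TSS enrichment and
#' mito content for every barcode, ready for [apply_cell_filters()].
#'
#' @param fragments Nuclear fragment tibble.
#' @param mito_reads Mito read tibble.
#' @param peaks Peak tibble.
#' @param tss TSS tibble (`chrom`, `pos`).
#' @return Per-cell metrics tibble.
#' @export
qc_metrics <- function(fragments, mito_reads, peaks, tss) {
  compute_frip(fragments, peaks) %>%
    left_join(compute_tss_enrichment(fragments, tss), by = "barcode") %>%
    left_join(compute_mito_content(fragments, mito_reads), by = "barcode")
}
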