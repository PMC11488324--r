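#' Genotyping configuration
#'
#' Thresholds for the read-level filters, the informative-variant criteria
#' and the pseudo-bulk filtering cascade. Defaults: minimum base quality 20,
#' minimum MAPQ 30, at most two mismatches per read, per-cell site coverage
#' below 10 treated as missing, a five-fold allele depth ratio, at most 90%
#' of alt reads on one strand, bulk site depth of at least 250, at least 50
#' cells exhibiting the SNP, strand concordance of at least 0.65, VAF
#' variance-to-mean ratio of at least 0.01, and a species-keyed position
#' blacklist (human m.310, a poly-C artifact).
#'
#' @param min_base_quality,min_mapq,max_mismatches Read/base-level filters.
#' @param low_coverage_threshold Per-cell site coverage below which a cell's
#'   VAF is missing (not zero).
#' @param allele_depth_ratio Required max/min bulk allele depth ratio
#'   (filter 1); set `NA` to disable.
#' @param strand_support_max Maximum fraction of alt reads on one strand
#'   (filter 2); must be in (0.5, 1].
#' @param min_bulk_depth Minimum pseudo-bulk site depth (filter 3).
#' @param min_cells Minimum number of cells exhibiting the SNP (filter 7).
#' @param strand_concordance_min,vmr_min Informative-variant criteria.
#' @param blacklist Named list of blacklisted positions per species.
#' @return A validated list of class `mtsc_genotyping_config`.
#' @export
genotyping_config <- function(min_base_quality = 20L, min_mapq = 30L,
                              max_mismatches = 2L,
                              low_coverage_threshold = 10L,
                              allele_depth_ratio = 5,
                              strand_support_max = 0.90,
                              min_bulk_depth = 250L, min_cells = 50L,
                              strand_concordance_min = 0.65,
                              vmr_min = 0.01,
                              blacklist = list(hg19 = 310L, mm10 = integer())) {
  cfg <- as.list(environment())
  for (f in c("min_base_quality", "min_mapq", "low_coverage_threshold",
              "min_bulk_depth", "min_cells")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      abort(sprintf("genotyping config: '%s' must be a non-negative number", f))
    }
  }
  if (!is.na(strand_support_max) &&
      (strand_support_max <= 0.5 || strand_support_max > 1)) {
    abort("strand_support_max must lie in (0.5, 1]")
  }
  structure(cfg, class = "mtsc_genotyping_config")
}

#' Strand-resolved per-cell allele counts (pileup)
#'
#' Counts, for every cell x mito position x allele x strand, the bases of
#' reads passing the read-level filters: MAPQ >= `min_mapq`, at most
#' `max_mismatches` mismatches, and per-base quality >= `min_base_quality`
#' (applied to every base of a passing read). Reads overhanging the mito end
#' are clipped with a warning (no origin wrap-around).
#'
#' @param mito_reads Mito read tibble (see [read_mito_reads()]).
#' @param genome A `genome_spec` (for the mito length).
#' @param config A [genotyping_config()].
#' @return A long tibble `barcode`, `pos`, `allele`, `strand`, `count` with
#'   the filter settings attached as attribute `"config"`.
#' @export
pileup_allele_counts <- function(mito_reads, genome,
                                 config = genotyping_config()) {
  bcs <- sort(unique(mito_reads$barcode))
  res <- .pileup_counts(
    cell = match(mito_reads$barcode, bcs) - 1L,
    pos = as.integer(mito_reads$pos),
    is_plus = mito_reads$strand == "+",
    mapq = as.integer(mito_reads$mapq),
    nm = as.integer(mito_reads$nm),
    seq = mito_reads$seq, qual = mito_reads$qual,
    mito_length = genome$mito_length,
    min_base_quality = as.integer(config$min_base_quality),
    min_mapq = as.integer(config$min_mapq),
    max_mismatches = as.integer(config$max_mismatches)
  )
  if (res$n_clipped > 0) {
    warn(sprintf("%d read(s) overhang the mito end and were clipped",
                 res$n_clipped))
  }
  out <- tibble(
    barcode = bcs[res$cell + 1L],
    pos = res$pos,
    allele = c("A", "C", "G", "T")[res$allele + 1L],
    strand = c("+", "-")[res$strand + 1L],
    count = res$count
  ) %>% arrange(.data$barcode, .data$pos, .data$allele, .data$strand)
  attr(out, "config") <- config
  out
}

#' Aggregate a per-cell allele-count tensor into pseudo-bulk
#'
#' Exact sum over cells; the bulk total equals the tensor total.
#'
#' @param tensor Long allele-count tibble from [pileup_allele_counts()].
#' @return Tibble `pos`, `allele`, `strand`, `count`.
#' @export
aggregate_pseudobulk <- function(tensor) {
  tensor %>%
    group_by(.data$pos, .data$allele, .data$strand) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Per-cell variant allele frequencies
#'
#' For each cell and variant, VAF = alt / (alt + ref) summed over strands.
#' Cells whose site coverage (alt + ref) is below `low_coverage_threshold`
#' are flagged missing (`vaf = NA`), not zero.
#'
#' @param tensor Long allele-count tibble.
#' @param variants Tibble with `variant_id`, `pos`, `ref`, `alt`.
#' @param config A [genotyping_config()].
#' @return Long tibble `barcode`, `variant_id`, `pos`, `alt_count`,
#'   `ref_count`, `coverage`, `vaf`.
#' @export
compute_cell_vaf <- function(tensor, variants,
                             config = genotyping_config()) {
  cells <- sort(unique(tensor$barcode))
  site <- tensor %>%
    inner_join(select(variants, "variant_id", "pos", "ref", "alt"),
               by = "pos", relationship = "many-to-many") %>%
    mutate(kind = dplyr::case_when(
      .data$allele == .data$alt ~ "alt_count",
      .data$allele == .data$ref ~ "ref_count",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$kind)) %>%
    group_by(.data$barcode, .data$variant_id, .data$pos, .data$kind) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "kind", values_from = "count",
                       values_fill = 0L)
  grid <- tidyr::expand_grid(barcode = cells,
                             variants[, c("variant_id", "pos")])
  grid %>%
    left_join(site, by = c("barcode", "variant_id", "pos")) %>%
    mutate(
      alt_count = dplyr::coalesce(.data$alt_count, 0L),
      ref_count = dplyr::coalesce(.data$ref_count, 0L),
      coverage = .data$alt_count + .data$ref_count,
      vaf = if_else(.data$coverage >= config$low_coverage_threshold,
                    .data$alt_count / pmax(.data$coverage, 1L), NA_real_)
    )
}

#' Identify candidate informative variants
#'
#' Scans every non-reference allele at every covered position and computes
#' the informative-variant statistics: number of cells with alt evidence,
#' pseudo-bulk VAF, mean per-cell site coverage, strand concordance (Pearson
#' correlation of plus- and minus-strand alt counts across cells with site
#' coverage at or above the low-coverage threshold; 0 when degenerate), and
#' the variance-to-mean ratio (VMR) of the per-cell VAF. A candidate must
#' reach `strand_concordance_min` and `vmr_min`.
#'
#' @param tensor Long allele-count tibble.
#' @param genome A `genome_spec` (reference allele lookup).
#' @param config A [genotyping_config()].
#' @param keep_all Return non-candidates too (flagged)?
#' @return Variant tibble with statistics and a `candidate` flag.
#' @export
identify_candidate_variants <- function(tensor, genome,
                                        config = genotyping_config(),
                                        keep_all = FALSE) {
  n_cells_total <- dplyr::n_distinct(tensor$barcode)
  site_cov <- tensor %>%
    group_by(.data$barcode, .data$pos) %>%
    summarise(coverage = sum(.data$count), .groups = "drop")
  bulk_depth <- site_cov %>%
    group_by(.data$pos) %>%
    summarise(bulk_depth = sum(.data$coverage),
              mean_coverage = sum(.data$coverage) / n_cells_total,
              .groups = "drop")
  alt_tab <- tensor %>%
    mutate(ref = ref_base(genome, .data$pos)) %>%
    filter(.data$allele != .data$ref)
  if (!nrow(alt_tab)) {
    return(tibble(variant_id = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  per_cell <- alt_tab %>%
    tidyr::pivot_wider(names_from = "strand", values_from = "count",
                       values_fill = 0L)
  if (!"+" %in% names(per_cell)) per_cell[["+"]] <- 0L
  if (!"-" %in% names(per_cell)) per_cell[["-"]] <- 0L
  per_cell <- per_cell %>%
    rename(plus = "+", minus = "-") %>%
    mutate(alt_count = .data$plus + .data$minus) %>%
    left_join(site_cov, by = c("barcode", "pos"))
  thr <- config$low_coverage_threshold
  # cells with adequate site coverage but zero alt reads have no row in
  # per_cell; they enter the concordance / VMR sums as exact zeros, so the
  # statistics are accumulated as sufficient sums over the covered cells
  site_n <- site_cov %>%
    filter(.data$coverage >= thr) %>%
    count(.data$pos, name = "n_cov_cells")
  stats <- per_cell %>%
    rename(alt = "allele") %>%
    mutate(cov_ok = .data$coverage >= thr,
           cell_vaf = if_else(.data$cov_ok,
                              .data$alt_count / pmax(.data$coverage, 1L), 0)) %>%
    group_by(.data$pos, .data$ref, .data$alt) %>%
    summarise(
      n_cells = sum(.data$alt_count > 0L),
      alt_depth = sum(.data$alt_count),
      plus_depth = sum(.data$plus),
      s_p = sum(.data$plus[.data$cov_ok]),
      s_m = sum(.data$minus[.data$cov_ok]),
      s_pp = sum(as.numeric(.data$plus[.data$cov_ok])^2),
      s_mm = sum(as.numeric(.data$minus[.data$cov_ok])^2),
      s_pm = sum(as.numeric(.data$plus[.data$cov_ok]) *
                   .data$minus[.data$cov_ok]),
      s_v = sum(.data$cell_vaf),
      s_vv = sum(.data$cell_vaf^2),
      .groups = "drop"
    ) %>%
    left_join(site_n, by = "pos") %>%
    mutate(
      n_cov_cells = dplyr::coalesce(.data$n_cov_cells, 0L),
      strand_concordance = cor_from_sums(.data$s_p, .data$s_m, .data$s_pp,
                                         .data$s_mm, .data$s_pm,
                                         .data$n_cov_cells),
      vmr = vmr_from_sums(.data$s_v, .data$s_vv, .data$n_cov_cells)
    ) %>%
    select(-dplyr::starts_with("s_")) %>%
    left_join(bulk_depth, by = "pos") %>%
    mutate(
      bulk_vaf = .data$alt_depth / pmax(.data$bulk_depth, 1L),
      plus_strand_fraction = .data$plus_depth / pmax(.data$alt_depth, 1L),
      variant_id = sprintf("m.%d%s>%s", .data$pos, .data$ref, .data$alt),
      candidate = .data$strand_concordance >= config$strand_concordance_min &
        .data$vmr >= config$vmr_min
    ) %>%
    select("variant_id", "pos", "ref", "alt", "n_cells", "alt_depth",
           "bulk_depth", "bulk_vaf", "plus_strand_fraction", "mean_coverage",
           "strand_concordance", "vmr", "candidate") %>%
    arrange(.data$pos, .data$alt)
  if (keep_all) stats else filter(stats, .data$candidate)
}

# Pearson correlation from sufficient sums over n cells (zeros included);
# degenerate (zero variance on a strand, or < 2 cells) is defined as 0
cor_from_sums <- function(s_p, s_m, s_pp, s_mm, s_pm, n) {
  num <- s_pm - s_p * s_m / pmax(n, 1L)
  den <- sqrt(pmax(s_pp - s_p^2 / pmax(n, 1L), 0) *
                pmax(s_mm - s_m^2 / pmax(n, 1L), 0))
  if_else(n < 2L | den <= 0, 0, num / den)
}

# variance-to-mean ratio of per-cell VAF from sufficient sums over n cells
vmr_from_sums <- function(s_v, s_vv, n) {
  m <- s_v / pmax(n, 1L)
  v <- pmax(s_vv - s_v^2 / pmax(n, 1L), 0) / pmax(n - 1L, 1L)
  if_else(n < 2L | m == 0, 0, v / m)
}

#' Apply the pseudo-bulk filtering cascade
#'
#' Flags every candidate against the cascade: (1) at least a five-fold
#' difference in bulk depth between the two alleles, (2) not more than 90%
#' of alt reads on one strand, (3) bulk site depth of at least 250, (4)-(6)
#' base quality / MAPQ / mismatch limits (guaranteed upstream by the
#' read-level filters and recorded as passes), (7) at least 50 cells
#' exhibiting the SNP, and (8) not on the species blacklist. All flags are
#' retained for audit; failing variants are kept unless `drop_failed`.
#'
#' @param candidates Candidate tibble from [identify_candidate_variants()].
#' @param config A [genotyping_config()].
#' @param species Species key into the blacklist.
#' @param drop_failed Drop variants failing any filter?
#' @return The candidates with `pass_*` flag columns and `pass_all`.
#' @export
apply_bulk_filters <- function(candidates, config = genotyping_config(),
                               species = "mm10", drop_failed = FALSE) {
  bl <- config$blacklist[[species]] %||% integer()
  out <- candidates %>%
    mutate(
      ref_depth = .data$bulk_depth - .data$alt_depth,
      pass_allele_ratio = if (is.na(config$allele_depth_ratio)) TRUE else
        pmax(.data$ref_depth, .data$alt_depth) /
        pmax(pmin(.data$ref_depth, .data$alt_depth), 0L) >=
        config$allele_depth_ratio | pmin(.data$ref_depth, .data$alt_depth) == 0L,
      pass_strand_support = pmax(.data$plus_strand_fraction,
                                 1 - .data$plus_strand_fraction) <=
        config$strand_support_max,
      pass_bulk_depth = .data$bulk_depth >= config$min_bulk_depth,
      pass_base_quality = TRUE,
      pass_mapq = TRUE,
      pass_mismatch = TRUE,
      pass_min_cells = .data$n_cells >= config$min_cells,
      pass_blacklist = !.data$pos %in% bl,
      pass_all = .data$pass_allele_ratio & .data$pass_strand_support &
        .data$pass_bulk_depth & .data$pass_min_cells & .data$pass_blacklist
    )
  if (drop_failed) filter(out, .data$pass_all) else out
}

#' Mitochondrial copy number from qPCR Ct values
#'
#' Copies of mtDNA = 2 x 2^dCt with dCt = Ct(nuclear gene) - Ct(mito gene).
#'
#' @param ct_nuclear,ct_mito Ct values (cycles); vectorised.
#' @return Copy number estimate(s).
#' @export
qpcr_copy_number <- function(ct_nuclear, ct_mito) {
  2 * 2^(ct_nuclear - ct_mito)
}

#' Full mitochondrial genotyping pipeline
#'
#' Pileup, candidate identification, the filtering cascade and annotation in
#' one call.
#'
#' @param mito_reads Mito read tibble.
#' @param genome A `genome_spec`.
#' @param config A [genotyping_config()].
#' @param drop_failed Keep only variants passing every filter?
#' @return A list with `variants` (annotated, flagged variant table),
#'   `vaf` (per-cell VAF long tibble for the passing variants) and `tensor`.
#' @export
call_mito_variants <- function(mito_reads, genome,
                               config = genotyping_config(),
                               drop_failed = TRUE) {
  tensor <- pileup_allele_counts(mito_reads, genome, config)
  cand <- identify_candidate_variants(tensor, genome, config)
  filt <- apply_bulk_filters(cand, config, species = genome$species,
                             drop_failed = drop_failed)
  ann <- annotate_variants(filt, genome)
  final <- filt %>% left_join(
    ann %>% group_by(.data$variant_id) %>%
      summarise(gene = paste(unique(.data$gene), collapse = ","),
                region = .data$region[1], effect = .data$effect[1],
                aa_change = .data$aa_change[1], .groups = "drop"),
    by = "variant_id")
  vaf <- compute_cell_vaf(tensor, final, config)
  list(variants = final, vaf = vaf, tensor = tensor)
}
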