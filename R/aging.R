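#' Two-sample Wilcoxon rank-sum test
#'
#' Unpaired two-sample rank-sum test. For small samples (both groups at most
#' `exact_max`) the p-value is computed by exhaustive enumeration of all
#' `choose(n + m, n)` group assignments of the pooled values (valid with
#' ties); otherwise the standard normal approximation with tie correction is
#' used via [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_max Largest group size for the exact-enumeration path.
#' @return A one-row tibble `statistic` (rank-sum W of `x`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater"),
                              exact_max = 10L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of x
  if (n <= exact_max && m <= exact_max) {
    combos <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
      two.sided = {
        mu <- n * m / 2
        mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
      },
      greater = mean(w_all >= w_obs - 1e-9),
      less = mean(w_all <= w_obs + 1e-9)
    )
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = FALSE,
                  correct = TRUE)$p.value)
    method <- "normal approximation (tie-corrected)"
  }
  tibble(statistic = w_obs, p_value = min(p, 1), method = method)
}

#' Pairwise mtDNA-content significance matrix
#'
#' Tests every unordered pair of cell types for a difference in per-cell
#' mtDNA content with the Wilcoxon rank-sum test and reports which pairs are
#' significant at `alpha` (raw p-values; no multiplicity correction, the
#' field convention for these matrices).
#'
#' @param data Tibble with one row per cell.
#' @param value Column holding the per-cell quantity (default
#'   `mito_content_pct`).
#' @param group Column holding the cell-type label (default `cell_type`).
#' @param alpha Significance level (default 0.01).
#' @return An object of class `mtsc_pairwise`: `pairs` tibble plus summary.
#' @export
pairwise_content_matrix <- function(data, value = "mito_content_pct",
                                    group = "cell_type", alpha = 0.01) {
  types <- sort(unique(data[[group]]))
  k <- length(types)
  if (k < 2L) abort("need at least two groups")
  pairs <- utils::combn(types, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- wilcoxon_rank_sum(data[[value]][data[[group]] == a],
                           data[[value]][data[[group]] == b])$p_value
    tibble(type_a = a, type_b = b, p_value = p, significant = p < alpha)
  })
  summ <- significant_pair_summary(sum(res$significant), k)
  structure(list(pairs = res, summary = mutate(summ, alpha = alpha)),
            class = "mtsc_pairwise")
}

#' Bookkeeping for significant cell-type pairs
#'
#' For `k` cell types there are `choose(k, 2)` unordered pairs; the summary
#' reports the significant count and the fraction significant (also rounded
#' to two decimals, as conventionally printed).
#'
#' @param n_sig Number of significant pairs.
#' @param k Number of cell types.
#' @return One-row tibble `n_sig`, `total_pairs`, `fraction`,
#'   `fraction_printed`.
#' @export
significant_pair_summary <- function(n_sig, k) {
  total <- choose(k, 2)
  if (n_sig > total) abort("n_sig cannot exceed choose(k, 2)")
  tibble(n_sig = n_sig, total_pairs = total, fraction = n_sig / total,
         fraction_printed = round(n_sig / total, 2))
}

#' @export
print.mtsc_pairwise <- function(x, ...) {
  s <- x$summary
  cat("<mtsc_pairwise> ", s$n_sig, "/", s$total_pairs,
      " significant pairs (fraction ", s$fraction_printed, ") at alpha ",
      s$alpha, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mtsc_pairwise <- function(x, ...) x$pairs

#' @export
glance.mtsc_pairwise <- function(x, ...) x$summary

#' Per-cell mutation burden
#'
#' A variant counts toward a cell's burden iff the cell has at least
#' `min_alt_reads` passing alt reads for it; missing (low-coverage) entries
#' are excluded, not treated as zero.
#'
#' @param vaf Long per-cell VAF tibble (from [compute_cell_vaf()]), with
#'   `barcode`, `variant_id`, `alt_count`, `vaf`.
#' @param min_alt_reads Alt-read detection threshold (default 1).
#' @return Tibble `barcode`, `burden`, `n_informative` (non-missing
#'   variants), `mean_vaf` (over non-missing entries).
#' @export
mutation_burden <- function(vaf, min_alt_reads = 1L) {
  vaf %>%
    group_by(.data$barcode) %>%
    summarise(
      burden = sum(!is.na(.data$vaf) & .data$alt_count >= min_alt_reads),
      n_informative = sum(!is.na(.data$vaf)),
      mean_vaf = if (any(!is.na(.data$vaf))) mean(.data$vaf, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
}

#' Group comparison of burden or mean VAF
#'
#' Wilcoxon comparison of a per-cell statistic between two groups within
#' each cell type.
#'
#' @param burden Per-cell tibble (e.g. from [mutation_burden()]) joined with
#'   annotation columns.
#' @param value Column to compare.
#' @param group Two-level grouping column (e.g. `age_group`).
#' @param by Stratifying column (e.g. `cell_type`); `NULL` for a single
#'   overall comparison.
#' @return Tibble with one row per stratum: group means, p-value.
#' @export
compare_groups <- function(burden, value, group, by = NULL) {
  strata <- if (is.null(by)) list(all = burden) else split(burden, burden[[by]])
  purrr::imap_dfr(strata, function(d, nm) {
    lv <- sort(unique(d[[group]]))
    if (length(lv) != 2L) {
      return(tibble(stratum = nm, group_a = NA, group_b = NA,
                    mean_a = NA_real_, mean_b = NA_real_, p_value = NA_real_))
    }
    a <- d[[value]][d[[group]] == lv[1]]
    b <- d[[value]][d[[group]] == lv[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tibble(stratum = nm, group_a = lv[1], group_b = lv[2],
           mean_a = mean(a), mean_b = mean(b),
           p_value = wilcoxon_rank_sum(a, b)$p_value)
  })
}

#' Per-type per-group mean VAF
#'
#' Mean per-cell VAF (over non-missing entries) by cell type and group.
#'
#' @param vaf Long per-cell VAF tibble.
#' @param annotation Tibble `barcode`, `cell_type`, plus the grouping column.
#' @param group Grouping column name (default `age_group`).
#' @return Tibble `cell_type`, group, `mean_vaf`, `n_cells`.
#' @export
mean_vaf_by_group <- function(vaf, annotation, group = "age_group") {
  vaf %>%
    inner_join(annotation, by = "barcode") %>%
    filter(!is.na(.data$vaf)) %>%
    group_by(.data$cell_type, .data[[group]]) %>%
    summarise(mean_vaf = mean(.data$vaf),
              n_cells = dplyr::n_distinct(.data$barcode), .groups = "drop")
}

#' Shared-variant set intersections (Venn counts)
#'
#' Variant identity is `(pos, ref, alt)`. Returns the count of variants in
#' every membership region across the supplied sample variant lists.
#'
#' @param variant_sets Named list of variant tibbles (each with `pos`, `ref`,
#'   `alt`).
#' @return Tibble `region` (e.g. `"A&B"`), `n`, `variant_ids`.
#' @export
shared_variant_sets <- function(variant_sets) {
  if (is.null(names(variant_sets)) || any(!nzchar(names(variant_sets)))) {
    abort("variant_sets must be a named list")
  }
  ids <- lapply(variant_sets, function(v)
    unique(sprintf("m.%d%s>%s", v$pos, v$ref, v$alt)))
  all_ids <- unique(unlist(ids))
  member <- vapply(ids, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(all_ids, names(ids)))
  region <- unname(apply(member, 1, function(r)
    paste(names(ids)[r], collapse = "&")))
  tibble(variant = all_ids, region = region) %>%
    group_by(.data$region) %>%
    summarise(n = dplyr::n(),
              variant_ids = paste(.data$variant, collapse = ","),
              .groups = "drop") %>%
    arrange(desc(.data$n))
}

#' Gene activity scores from fragments
#'
#' Counts, per cell and gene, the fragments overlapping the gene body
#' extended `upstream_bp` on the gene's 5' side (strand-aware), the standard
#' accessibility proxy for expression.
#'
#' @param fragments Fragment tibble (0-based half-open intervals).
#' @param gene_table Tibble `gene`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @param upstream_bp Upstream extension (default 2000).
#' @return Tibble `barcode`, `gene`, `activity`.
#' @export
gene_activity_scores <- function(fragments, gene_table, upstream_bp = 2000L) {
  gt <- gene_table %>%
    mutate(
      w_start = if_else(.data$strand == "+",
                        pmax(1L, .data$start - as.integer(upstream_bp)), .data$start),
      w_end = if_else(.data$strand == "+",
                      .data$end, .data$end + as.integer(upstream_bp))
    )
  hits <- overlap_pairs(fragments$chrom, fragments$start, fragments$end,
                        gt$chrom, gt$w_start - 1L, gt$w_end)
  if (!length(hits$query)) {
    return(tibble(barcode = character(), gene = character(),
                  activity = integer()))
  }
  tibble(barcode = fragments$barcode[hits$query],
         gene = gt$gene[hits$subject]) %>%
    count(.data$barcode, .data$gene, name = "activity")
}

#' Gene-set signature score per cell
#'
#' Mean of per-gene z-scored (across cells) activities over a gene set;
#' zero-variance genes contribute 0.
#'
#' @param activity Tibble `barcode`, `gene`, `activity` (absent pairs are
#'   zero) or a cells x genes matrix.
#' @param gene_set Character vector of gene names.
#' @return Tibble `barcode`, `score`.
#' @export
signature_score <- function(activity, gene_set) {
  if (is.matrix(activity)) {
    activity <- as_tibble(activity, rownames = "barcode") %>%
      tidyr::pivot_longer(-"barcode", names_to = "gene", values_to = "activity")
  }
  wide <- activity %>%
    filter(.data$gene %in% gene_set) %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "activity",
                       values_fill = 0)
  bcs <- union(unique(activity$barcode), wide$barcode)
  miss <- setdiff(bcs, wide$barcode)
  if (length(miss)) {
    pad <- tibble(barcode = miss)
    for (g in setdiff(names(wide), "barcode")) pad[[g]] <- 0
    wide <- bind_rows(wide, pad)
  }
  mat <- as.matrix(wide[-1])
  z <- apply(mat, 2, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (is.null(dim(z))) z <- matrix(z, ncol = ncol(mat))
  tibble(barcode = wide$barcode,
         score = if (ncol(mat)) rowMeans(z) else 0) %>%
    arrange(.data$barcode)
}

#' Correlation of aggregate accessibility profiles
#'
#' Pearson correlation of per-peak aggregate counts between two profiles over
#' the shared peak set, log1p-transformed by default (raw scale available).
#'
#' @param a,b Named numeric vectors (or tibbles `id`, `count`) of per-peak
#'   aggregate counts.
#' @param log1p_transform Apply `log1p` before correlating (default TRUE).
#' @return Pearson correlation coefficient.
#' @export
aggregate_profile_correlation <- function(a, b, log1p_transform = TRUE) {
  to_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$count, x$id) else x
  }
  a <- to_vec(a); b <- to_vec(b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) abort("need at least 3 shared peaks")
  av <- a[shared]; bv <- b[shared]
  if (log1p_transform) { av <- log1p(av); bv <- log1p(bv) }
  cor(av, bv)
}
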