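#' Assign carrier / wild-type status from designated variants
#'
#' A cell is a `carrier` iff it has detected alt evidence (at least
#' `min_alt_reads` passing alt reads) for any designated variant, `WT` iff
#' it is covered at one or more designated sites and carries none, and
#' `unassigned` iff all designated sites are missing (low coverage).
#'
#' @param vaf Long per-cell VAF tibble (`barcode`, `variant_id`,
#'   `alt_count`, `vaf`; `vaf = NA` means missing).
#' @param designated Character vector of designated variant ids.
#' @param min_alt_reads Detection threshold (default 1).
#' @return Tibble `barcode`, `n_detected`, `status`, with attribute
#'   `"summary"` (carrier/WT/unassigned counts and the fraction of carriers
#'   with two or more designated variants).
#' @export
assign_carrier_status <- function(vaf, designated, min_alt_reads = 1L) {
  d <- vaf %>% filter(.data$variant_id %in% designated)
  if (!nrow(d)) abort("none of the designated variants is present in the VAF table")
  out <- d %>%
    group_by(.data$barcode) %>%
    summarise(
      n_covered = sum(!is.na(.data$vaf)),
      n_detected = sum(!is.na(.data$vaf) & .data$alt_count >= min_alt_reads),
      .groups = "drop"
    ) %>%
    mutate(status = dplyr::case_when(
      .data$n_detected >= 1L ~ "carrier",
      .data$n_covered >= 1L ~ "WT",
      TRUE ~ "unassigned"
    )) %>%
    select("barcode", "n_detected", "status")
  n_car <- sum(out$status == "carrier")
  attr(out, "summary") <- tibble(
    n_carrier = n_car,
    n_wt = sum(out$status == "WT"),
    n_unassigned = sum(out$status == "unassigned"),
    frac_carrier = n_car / nrow(out),
    frac_multi = if (n_car) sum(out$n_detected >= 2L) / n_car else NA_real_
  )
  out
}

#' Carrier-versus-wild-type differential accessibility
#'
#' Per peak, accessibility is binarized (detected iff >= 1 fragment) and
#' association with carrier status is tested. The default test is a
#' likelihood-ratio test of the logistic model
#' `detected ~ group + log(total fragments)` against the covariate-only
#' model; `method = "fisher"` uses Fisher's exact test on the 2 x 2
#' detection table (for tiny data). P-values are BH-adjusted across peaks.
#' Fold change is the ratio of detection rates normalized by group mean
#' depth, with pseudocount `1/n_cells`. A peak is significant iff
#' `q < alpha` and the fold change is at least `fc_threshold` in either
#' direction.
#'
#' @param counts Peaks x cells matrix (row/col names required) or a long
#'   tibble `peak`, `barcode`, `count`.
#' @param assignment Tibble `barcode`, `status` from
#'   [assign_carrier_status()]; only `carrier` and `WT` cells are used.
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param fc_threshold Fold-change cutoff (default 1.25).
#' @param method `"lr"` (default) or `"fisher"`.
#' @param depth Optional named per-cell sequencing depth used as the model
#'   covariate and for rate normalisation; defaults to the column sums of
#'   `counts` (adequate when the matrix spans many peaks).
#' @return An object of class `mtsc_diff`; `tidy()` gives the per-peak
#'   table, `glance()` the summary.
#' @export
differential_peaks <- function(counts, assignment, alpha = 0.01,
                               fc_threshold = 1.25,
                               method = c("lr", "fisher"), depth = NULL) {
  method <- match.arg(method)
  counts <- as_peak_matrix(counts)
  keep <- assignment$barcode[assignment$status %in% c("carrier", "WT")]
  keep <- intersect(colnames(counts), keep)
  counts <- counts[, keep, drop = FALSE]
  status <- assignment$status[match(keep, assignment$barcode)]
  g <- as.integer(status == "carrier")
  if (sum(g) < 2L || sum(1 - g) < 2L) abort("need >= 2 cells per group")
  depth <- if (is.null(depth)) colSums(counts) else depth[keep]
  lt <- log(depth + 1)
  y_all <- counts >= 1L
  det <- rowSums(y_all)
  skipped <- rownames(counts)[det == 0L]
  use <- which(det > 0L)
  n_cells <- length(keep)
  pc <- 1 / n_cells
  d_car <- mean(depth[g == 1L]); d_wt <- mean(depth[g == 0L])
  d_all <- mean(depth)
  res <- purrr::map_dfr(use, function(i) {
    y <- as.integer(y_all[i, ])
    p <- if (method == "lr") lr_test_logistic(y, g, lt) else {
      tab <- table(factor(y, levels = 0:1), factor(g, levels = 0:1))
      stats::fisher.test(tab)$p.value
    }
    r_car <- mean(y[g == 1L]) / (d_car / d_all)
    r_wt <- mean(y[g == 0L]) / (d_wt / d_all)
    fc <- (r_car + pc) / (r_wt + pc)
    tibble(peak = rownames(counts)[i],
           rate_carrier = mean(y[g == 1L]), rate_wt = mean(y[g == 0L]),
           fold_change = fc, log2_fc = log2(fc), p_value = p)
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < alpha &
    (res$fold_change >= fc_threshold | res$fold_change <= 1 / fc_threshold)
  res$direction <- if_else(res$log2_fc >= 0, "up_in_carrier", "down_in_carrier")
  structure(
    list(results = arrange(res, .data$q_value),
         skipped = skipped,
         summary = tibble(n_peaks_tested = nrow(res),
                          n_significant = sum(res$significant),
                          n_skipped = length(skipped),
                          n_carrier = sum(g), n_wt = sum(1 - g),
                          alpha = alpha, fc_threshold = fc_threshold,
                          method = method)),
    class = "mtsc_diff"
  )
}

as_peak_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts)) || is.null(colnames(counts))) {
      abort("peak matrix needs peak rownames and barcode colnames")
    }
    return(counts)
  }
  if (is.data.frame(counts)) {
    wide <- tidyr::pivot_wider(counts, names_from = "barcode",
                               values_from = "count", values_fill = 0L)
    m <- as.matrix(wide[-1])
    rownames(m) <- wide$peak
    return(m)
  }
  abort("counts must be a matrix or a long tibble (peak, barcode, count)")
}

lr_test_logistic <- function(y, g, lt) {
  w <- rep(1, length(y))
  fit1 <- suppressWarnings(glm.fit(cbind(1, g, lt), y, weights = w,
                                   family = binomial()))
  fit0 <- suppressWarnings(glm.fit(cbind(1, lt), y, weights = w,
                                   family = binomial()))
  stat <- max(fit0$deviance - fit1$deviance, 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @export
print.mtsc_diff <- function(x, ...) {
  s <- x$summary
  cat("<mtsc_diff> ", s$n_significant, " significant of ", s$n_peaks_tested,
      " peaks (q < ", s$alpha, ", FC ", s$fc_threshold, "; ", s$n_carrier,
      " carrier vs ", s$n_wt, " WT cells)\n", sep = "")
  invisible(x)
}

#' @export
tidy.mtsc_diff <- function(x, ...) x$results

#' @export
glance.mtsc_diff <- function(x, ...) x$summary

#' Random-split permutation control for differential accessibility
#'
#' Repeatedly permutes the carrier/WT labels (preserving the group sizes,
#' i.e. the mutation-to-WT ratio), recomputes the differential peaks, and
#' records the number of significant peaks per replicate. On data without a
#' real group effect the significant count should collapse to zero.
#'
#' @param counts Peaks x cells matrix (or long tibble).
#' @param assignment Carrier assignment tibble.
#' @param n_reps Number of random splits (default 100).
#' @param seed Integer seed.
#' @inheritParams differential_peaks
#' @return An object of class `mtsc_perm`; `tidy()` gives per-replicate
#'   counts, `glance()` the summary (median count, fraction of replicates
#'   with any significant peak).
#' @export
permutation_control <- function(counts, assignment, n_reps = 100L, seed = 1L,
                                alpha = 0.01, fc_threshold = 1.25,
                                method = c("lr", "fisher")) {
  method <- match.arg(method)
  withr::with_seed(seed, {
    reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      perm <- assignment
      lab <- perm$status[perm$status %in% c("carrier", "WT")]
      perm$status[perm$status %in% c("carrier", "WT")] <- sample(lab)
      d <- differential_peaks(counts, perm, alpha = alpha,
                              fc_threshold = fc_threshold, method = method)
      tibble(rep = r, n_significant = d$summary$n_significant)
    })
    structure(
      list(reps = reps,
           summary = tibble(
             n_reps = n_reps,
             median_significant = median(reps$n_significant),
             max_significant = max(reps$n_significant),
             frac_reps_with_any = mean(reps$n_significant > 0L))),
      class = "mtsc_perm"
    )
  })
}

#' @export
print.mtsc_perm <- function(x, ...) {
  s <- x$summary
  cat("<mtsc_perm> ", s$n_reps, " random splits: median ",
      s$median_significant, " significant peaks, ",
      round(100 * s$frac_reps_with_any, 1), "% of replicates with any\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.mtsc_perm <- function(x, ...) x$reps

#' @export
glance.mtsc_perm <- function(x, ...) x$summary

#' Link peaks to their nearest gene
#'
#' Assigns each peak to the gene whose body (or promoter window) is nearest;
#' ties report all genes, comma-separated.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `id`; 0-based).
#' @param gene_table Tibble `gene`, `chrom`, `start`, `end` (1-based).
#' @return Tibble `id`, `linked_gene`, `distance`.
#' @export
link_nearest_gene <- function(peaks, gene_table) {
  purrr::pmap_dfr(peaks[, c("chrom", "start", "end", "id")],
    function(chrom, start, end, id) {
      g <- gene_table[gene_table$chrom == chrom, ]
      if (!nrow(g)) {
        return(tibble(id = id, linked_gene = NA_character_,
                      distance = NA_real_))
      }
      # distance between [start+1, end] and [g$start, g$end], 0 if overlapping
      d <- pmax(g$start - end, (start + 1L) - g$end, 0L)
      dmin <- min(d)
      tibble(id = id,
             linked_gene = paste(g$gene[d == dmin], collapse = ","),
             distance = dmin)
    })
}
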