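BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat 4 x L numeric matrix of per-position base probabilities (rows
#'   A, C, G, T; columns sum to 1).
#' @param id Motif identifier.
#' @return A `mtsc_pwm` (the matrix with row names and an `id` attribute).
#' @export
pwm <- function(mat, id) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) abort("a PWM needs 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) abort("motif length must be >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6)) abort("PWM columns must sum to 1")
  rownames(mat) <- BASES
  structure(mat, id = id, class = c("mtsc_pwm", "matrix", "array"))
}

#' Generate a random sharp PWM
#'
#' Each column concentrates most probability on one random base - a simple
#' stand-in for a transcription-factor motif.
#'
#' @param id Motif identifier.
#' @param len Motif length (default 8).
#' @param sharpness Probability of the consensus base per column.
#' @return A `mtsc_pwm`.
#' @export
random_pwm <- function(id, len = 8L, sharpness = 0.9) {
  cons <- sample.int(4L, len, replace = TRUE)
  m <- matrix((1 - sharpness) / 3, nrow = 4L, ncol = len)
  m[cbind(cons, seq_len(len))] <- sharpness
  pwm(m, id)
}

#' Consensus sequence of a PWM
#'
#' @param p A `mtsc_pwm`.
#' @return The per-position argmax bases as a single string.
#' @export
consensus_pwm <- function(p) {
  paste(BASES[apply(unclass(p), 2, which.max)], collapse = "")
}

#' Sample a sequence from a PWM
#'
#' @param p A `mtsc_pwm`.
#' @return A character scalar of length `ncol(p)`.
#' @export
sample_pwm <- function(p) {
  paste(vapply(seq_len(ncol(p)), function(j) sample(BASES, 1, prob = p[, j]),
               character(1)), collapse = "")
}

#' Read / write PWMs in JASPAR-style plain text
#'
#' Format: a `>id` header line, then four lines `A [ 1 2 3 ]` etc. with
#' per-position counts or probabilities (normalised on read).
#'
#' @param path File path.
#' @return `read_pwms()` returns a named list of `mtsc_pwm`s.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no PWM headers ('>id') found")
  out <- lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads[i]])
    block <- lines[(heads[i] + 1L):(heads[i] + 4L)]
    rows <- lapply(block, function(l) {
      body <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    })
    m <- do.call(rbind, rows)
    m <- sweep(m, 2, colSums(m), "/")
    pwm(m, id)
  })
  setNames(out, vapply(out, attr, character(1), "id"))
}

#' @rdname read_pwms
#' @param pwms Named list of `mtsc_pwm`s.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", attr(p, "id")), con)
    for (b in BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(sprintf("%.10g", p[b, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

pwm_logodds <- function(p, background, pseudo = 0.01) {
  m <- sweep(unclass(p) + pseudo, 2, colSums(unclass(p) + pseudo), "/")
  log2(m / background)
}

score_best_window <- function(seq, W) {
  L <- ncol(W)
  n <- nchar(seq)
  if (n < L) return(-Inf)
  idx <- match(strsplit(seq, "")[[1]], BASES)
  n_win <- n - L + 1L
  score <- numeric(n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    b <- idx[j:(j + n_win - 1L)]
    bad <- is.na(b)
    ok <- ok & !bad
    b[bad] <- 1L
    score <- score + W[cbind(b, j)]
  }
  if (!any(ok)) return(-Inf)
  max(score[ok])
}

#' Scan peak sequences for motif hits
#'
#' Slides the log-odds score of each PWM over both strands of each sequence;
#' a sequence is a hit iff its best window score reaches the threshold.
#'
#' @param pwms Named list of `mtsc_pwm`s (or a single `mtsc_pwm`).
#' @param seqs Named character vector of peak sequences.
#' @param threshold Log-odds (bits) hit threshold; the default `NULL` uses
#'   75% of each motif's maximum achievable score.
#' @param background Background base frequencies (A, C, G, T).
#' @return Logical peaks x motifs matrix.
#' @export
scan_motifs <- function(pwms, seqs, threshold = NULL,
                        background = rep(0.25, 4)) {
  if (inherits(pwms, "mtsc_pwm")) pwms <- setNames(list(pwms), attr(pwms, "id"))
  rc <- revcomp(seqs)
  hits <- vapply(pwms, function(p) {
    W <- pwm_logodds(p, background)
    thr <- threshold %||% (0.75 * sum(apply(W, 2, max)))
    fwd <- vapply(seqs, score_best_window, numeric(1), W = W)
    rev <- vapply(rc, score_best_window, numeric(1), W = W)
    pmax(fwd, rev) >= thr
  }, logical(length(seqs)))
  hits <- matrix(hits, nrow = length(seqs),
                 dimnames = list(names(seqs), names(pwms)))
  hits
}

#' Motif over-representation in differential peaks
#'
#' Per motif, the upper-tail hypergeometric probability of observing at
#' least the seen number of motif-hit peaks among the differential set,
#' given the hit total in the background (all tested peaks); BH-adjusted and
#' ranked by ascending p.
#'
#' @param hits Logical peaks x motifs matrix from [scan_motifs()].
#' @param diff_peaks Character vector of differential peak ids.
#' @param background_peaks Character vector of background peak ids (default
#'   all rows of `hits`).
#' @return Tibble `motif`, `n_diff_hits`, `n_diff`, `n_bg_hits`, `n_bg`,
#'   `p_value`, `q_value`, ranked ascending by p.
#' @export
motif_enrichment <- function(hits, diff_peaks,
                             background_peaks = rownames(hits)) {
  diff_peaks <- intersect(diff_peaks, background_peaks)
  N <- length(background_peaks)
  n <- length(diff_peaks)
  res <- purrr::map_dfr(colnames(hits), function(m) {
    K <- sum(hits[background_peaks, m])
    k <- sum(hits[diff_peaks, m])
    tibble(motif = m, n_diff_hits = k, n_diff = n, n_bg_hits = K, n_bg = N,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value, desc(.data$n_diff_hits))
}
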