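#' Read a 10x-style fragments file
#'
#' Fragments are deduplicated Tn5 fragments in the 10x dialect: five
#' tab-separated columns `chrom`, `start` (0-based inclusive), `end`
#' (exclusive), `barcode`, `support` (read count), position-sorted. Plain or
#' gzip/bgzip-compressed files are accepted (compression is auto-detected).
#'
#' @param path Path to the fragments TSV.
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`,
#'   `support`.
#' @export
read_fragments <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "barcode", "support"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), barcode = readr::col_character(),
      support = readr::col_integer()
    ),
    progress = FALSE
  )
  pr <- readr::problems(x)
  if (nrow(pr)) {
    abort(sprintf("malformed fragments file '%s' at line %d: %s",
                  path, pr$row[1], pr$expected[1]))
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start >= x$end |
                 x$start < 0L | is.na(x$barcode) | x$barcode == "" |
                 is.na(x$support) | x$support < 1L)
  if (length(bad)) {
    abort(sprintf("invalid fragment record at line %d (need 0 <= start < end, non-empty barcode, support >= 1)",
                  bad[1]))
  }
  x
}

#' Write a fragments file
#'
#' @param fragments Tibble of fragment records (see [read_fragments()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param sort If `TRUE`, sort by `(chrom, start)` before writing; if `FALSE`
#'   (default) unsorted input is an error.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path, sort = FALSE) {
  need <- c("chrom", "start", "end", "barcode", "support")
  if (!all(need %in% names(fragments))) {
    abort(paste0("fragments must have columns: ", paste(need, collapse = ", ")))
  }
  fragments <- fragments[need]
  if (is.unsorted_frag(fragments)) {
    if (sort) {
      fragments <- arrange(fragments, .data$chrom, .data$start, .data$end)
    } else {
      abort("fragments are not position-sorted; pass sort = TRUE to sort on write")
    }
  }
  readr::write_tsv(fragments, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

is.unsorted_frag <- function(x) {
  o <- order(x$chrom, x$start, x$end)
  any(o != seq_len(nrow(x)))
}

#' Read mitochondrial reads (MRF v1)
#'
#' MRF v1 ("mito read format") is a plain TSV with one aligned mitochondrial
#' read per line: `barcode`, `chrom`, `pos` (1-based leftmost), `strand`
#' (`+`/`-`), `mapq`, `nm` (mismatch count), `seq`, `qual` (Phred+33 string,
#' same length as `seq`).
#'
#' @param path Path to an MRF v1 TSV.
#' @return A tibble with one row per read.
#' @export
read_mito_reads <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("barcode", "chrom", "pos", "strand", "mapq", "nm",
                  "seq", "qual"),
    col_types = readr::cols(
      barcode = readr::col_character(), chrom = readr::col_character(),
      pos = readr::col_integer(), strand = readr::col_character(),
      mapq = readr::col_integer(), nm = readr::col_integer(),
      seq = readr::col_character(), qual = readr::col_character()
    ),
    progress = FALSE
  )
  pr <- readr::problems(x)
  if (nrow(pr)) {
    abort(sprintf("malformed MRF file '%s' at line %d: %s",
                  path, pr$row[1], pr$expected[1]))
  }
  bad_strand <- which(!x$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    abort(sprintf("unknown strand symbol '%s' at line %d",
                  x$strand[bad_strand[1]], bad_strand[1]))
  }
  bad_len <- which(nchar(x$seq) != nchar(x$qual))
  if (length(bad_len)) {
    abort(sprintf("seq/qual length mismatch at line %d (%d vs %d)",
                  bad_len[1], nchar(x$seq[bad_len[1]]),
                  nchar(x$qual[bad_len[1]])))
  }
  qr <- range(utf8ToInt(paste(x$qual, collapse = "")))
  if (length(x$qual) && (qr[1] < 33L || qr[2] > 126L)) {
    abort("qual string decodes outside Phred range [0, 93]")
  }
  x
}

#' Write mitochondrial reads (MRF v1)
#'
#' @param reads Tibble of mito reads (see [read_mito_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mito_reads <- function(reads, path) {
  need <- c("barcode", "chrom", "pos", "strand", "mapq", "nm", "seq", "qual")
  if (!all(need %in% names(reads))) {
    abort(paste0("mito reads must have columns: ", paste(need, collapse = ", ")))
  }
  readr::write_tsv(reads[need], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read peaks from a BED3(+name) file
#'
#' @param path Path to a BED file with at least `chrom`, `start`, `end`;
#'   column 4, when present, is the peak id (otherwise ids are generated).
#' @return A tibble `chrom`, `start` (0-based), `end` (exclusive), `id`,
#'   sorted by position.
#' @export
read_peaks <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 3L) abort("BED file needs at least 3 columns")
  x <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    id = if (ncol(raw) >= 4L) raw[[4]] else NA_character_
  )
  if (any(is.na(x$start) | is.na(x$end) | x$start >= x$end)) {
    abort("invalid BED interval (need 0 <= start < end)")
  }
  if (anyNA(x$id)) x$id <- sprintf("peak_%05d", seq_len(nrow(x)))
  arrange(x, .data$chrom, .data$start)
}

#' Write peaks as BED3+name
#'
#' @param peaks Tibble with `chrom`, `start`, `end`, `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(peaks[c("chrom", "start", "end", "id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a mitochondrial gene model
#'
#' Accepts either the documented TSV dialect (header
#' `gene start end strand class`, 1-based inclusive coordinates) or BED6
#' (0-based half-open; the name field must be `gene:class`). The product
#' class vocabulary is `protein`, `tRNA`, `rRNA`, `D-loop`.
#'
#' @param path Path to the gene model file.
#' @return A tibble `gene`, `start`, `end`, `strand`, `class` (1-based
#'   inclusive).
#' @export
read_gene_model <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    warn(sprintf("empty gene model file '%s'", path))
    return(empty_gene_table())
  }
  if (grepl("^gene\t", first)) {
    x <- readr::read_tsv(path, col_types = readr::cols(
      gene = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), strand = readr::col_character(),
      class = readr::col_character()
    ), progress = FALSE)
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (ncol(raw) < 6L) abort("BED gene model needs 6 columns (name = gene:class)")
    nm <- stringr::str_split_fixed(raw[[4]], ":", 2)
    x <- tibble(gene = nm[, 1], start = as.integer(raw[[2]]) + 1L,
                end = as.integer(raw[[3]]), strand = raw[[6]], class = nm[, 2])
  }
  bad <- setdiff(unique(x$class), c("protein", "tRNA", "rRNA", "D-loop"))
  if (length(bad)) {
    abort(paste0("unknown gene class token(s): ", paste(bad, collapse = ", "),
                 " (valid: protein, tRNA, rRNA, D-loop)"))
  }
  if (any(!x$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  x
}

variant_table_cols <- c(
  "pos", "ref", "alt", "gene", "region", "effect", "aa_change",
  "bulk_depth", "bulk_vaf", "n_cells", "plus_strand_fraction",
  "mean_coverage", "strand_concordance", "vmr",
  "pass_allele_ratio", "pass_strand_support", "pass_bulk_depth",
  "pass_base_quality", "pass_mapq", "pass_mismatch", "pass_min_cells",
  "pass_blacklist", "pass_all"
)

#' Write / read the variant table
#'
#' The variant table is a TSV with a fixed, documented column order: position
#' (1-based, `m.<pos>` frame), ref/alt alleles, annotation (gene, region,
#' effect, amino-acid change), pseudo-bulk statistics (depth, VAF, number of
#' supporting cells, plus-strand fraction of alt reads, mean per-cell
#' coverage, strand concordance, VAF variance-to-mean ratio), and the
#' pass/fail audit flag of every filter in the cascade.
#'
#' @param variants Tibble of variant calls.
#' @param path Output path.
#' @return `write_variant_table()` returns `path` invisibly;
#'   `read_variant_table()` returns the tibble.
#' @export
write_variant_table <- function(variants, path) {
  missing_cols <- setdiff(variant_table_cols, names(variants))
  for (m in missing_cols) variants[[m]] <- NA
  readr::write_tsv(variants[variant_table_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), gene = readr::col_character(),
    region = readr::col_character(), effect = readr::col_character(),
    aa_change = readr::col_character(), bulk_depth = readr::col_integer(),
    bulk_vaf = readr::col_double(), n_cells = readr::col_integer(),
    plus_strand_fraction = readr::col_double(),
    mean_coverage = readr::col_double(),
    strand_concordance = readr::col_double(), vmr = readr::col_double(),
    .default = readr::col_logical()
  ), progress = FALSE)
}

#' Export variants as VCF-lite
#'
#' A minimal CHROM/POS/REF/ALT/INFO export for interoperability; per-cell
#' heteroplasmy stays in the variant table / VAF matrix.
#'
#' @param variants Variant tibble (needs `pos`, `ref`, `alt`; bulk stats used
#'   when present).
#' @param path Output path.
#' @param chrom Mito chromosome name written in column 1.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(variants, path, chrom = "chrM") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- if (all(c("bulk_depth", "bulk_vaf") %in% names(variants))) {
    sprintf("DP=%d;AF=%.6g", variants$bulk_depth, variants$bulk_vaf)
  } else rep(".", nrow(variants))
  filt <- if ("pass_all" %in% names(variants)) {
    if_else(variants$pass_all, "PASS", "FAIL")
  } else rep(".", nrow(variants))
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\t%s",
                     chrom, variants$pos,
                     sprintf("m.%d%s>%s", variants$pos, variants$ref, variants$alt),
                     variants$ref, variants$alt, filt, info), con)
  invisible(path)
}

#' Read / write a flat key:value configuration file
#'
#' One `key: value` pair per line; `#` starts a comment. Values are coerced
#' to numeric where possible. Unknown keys are an error listing the valid
#' keys.
#'
#' @param path Path to the config file.
#' @param valid_keys Character vector of accepted keys (defaults to the
#'   scalar fields of [sim_config()]).
#' @return A named list.
#' @export
read_config <- function(path, valid_keys = sim_config_keys()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  if (any(lengths(m) != 3L)) {
    abort(sprintf("malformed config line: '%s'", lines[which(lengths(m) != 3L)[1]]))
  }
  keys <- trimws(vapply(m, `[`, character(1), 2))
  vals <- trimws(vapply(m, `[`, character(1), 3))
  unknown <- setdiff(keys, valid_keys)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                 "\nvalid keys: ", paste(valid_keys, collapse = ", ")))
  }
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(out, keys)
}

#' @rdname read_config
#' @param config Named list of scalar settings.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), character(1))),
             path)
  invisible(path)
}
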