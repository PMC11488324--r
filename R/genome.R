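#' Genome specification for joint nuclear / mitochondrial analysis
#'
#' A `genome_spec` bundles everything the pipeline needs to know about a
#' genome: nuclear chromosome names and lengths (toy-scale for simulation),
#' the mitochondrial chromosome name and length, a mitochondrial gene table
#' (1-based inclusive coordinates, the `m.<pos>` convention used for mtDNA
#' variants), and a mitochondrial reference sequence.
#'
#' @param species Species/assembly label, e.g. `"mm10"`.
#' @param nuclear_chroms Named integer vector of nuclear chromosome lengths.
#' @param mito_chrom Mitochondrial chromosome name.
#' @param mito_length Mitochondrial genome length in bp.
#' @param mito_genes Tibble with columns `gene`, `start`, `end`, `strand`,
#'   `class` (one of `"protein"`, `"tRNA"`, `"rRNA"`, `"D-loop"`); 1-based
#'   inclusive coordinates on the mito chromosome.
#' @param mito_seq Mitochondrial reference sequence as a single string of
#'   length `mito_length`. If `NULL`, a seeded random sequence is generated.
#' @param seed Seed for random reference generation (ignored when `mito_seq`
#'   is supplied).
#'
#' @return An object of class `genome_spec` (a list).
#' @export
genome_spec <- function(species, nuclear_chroms, mito_chrom = "chrM",
                        mito_length, mito_genes = NULL, mito_seq = NULL,
                        seed = 1L) {
  if (is.null(mito_seq)) {
    mito_seq <- withr::with_seed(seed, random_dna(mito_length))
  }
  gs <- structure(
    list(
      species = species,
      nuclear_chroms = nuclear_chroms,
      mito_chrom = mito_chrom,
      mito_length = as.integer(mito_length),
      mito_genes = if (is.null(mito_genes)) empty_gene_table() else as_tibble(mito_genes),
      mito_seq = mito_seq
    ),
    class = "genome_spec"
  )
  validate_genome_spec(gs)
}

validate_genome_spec <- function(gs) {
  if (nchar(gs$mito_seq) != gs$mito_length) {
    abort(sprintf("mito reference length (%d) != declared mito_length (%d)",
                  nchar(gs$mito_seq), gs$mito_length))
  }
  g <- gs$mito_genes
  if (nrow(g)) {
    bad_class <- setdiff(unique(g$class), c("protein", "tRNA", "rRNA", "D-loop"))
    if (length(bad_class)) {
      abort(paste0("unknown gene class token(s): ", paste(bad_class, collapse = ", ")))
    }
    if (any(g$start < 1L | g$end > gs$mito_length | g$start > g$end)) {
      abort("gene intervals must lie within [1, mito_length]")
    }
    # protein genes with an incomplete terminal codon are trimmed to the last
    # complete codon when translating (mitochondrial mRNAs complete their stop
    # codons post-transcriptionally), so any length >= 3 is acceptable
    if (any(g$class == "protein" & (g$end - g$start + 1L) < 3L)) {
      abort("protein genes must span at least one codon")
    }
  }
  gs
}

empty_gene_table <- function() {
  tibble(gene = character(), start = integer(), end = integer(),
         strand = character(), class = character())
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", x$species, "\n", sep = "")
  cat("  nuclear: ", length(x$nuclear_chroms), " chrom(s), ",
      sum(as.numeric(x$nuclear_chroms)), " bp total\n", sep = "")
  cat("  mito:    ", x$mito_chrom, " (", x$mito_length, " bp), ",
      nrow(x$mito_genes), " annotated features\n", sep = "")
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Built-in mitochondrial genome specifications
#'
#' Builds a `genome_spec` for the mouse (mm10, 16,299 bp) or human (hg19,
#' 16,569 bp) mitochondrial genome using the bundled gene coordinate tables.
#' The reference sequence is synthetic (seeded random) but anchored at a small
#' set of loci carrying well-characterised variants, so that annotation of
#' those variants reproduces the expected gene, region and amino-acid calls:
#' for mm10, m.15219 sits at the first base of CYTB codon 359 (Phe, TTC),
#' m.9821 is `A` inside tRNA-Arg, m.15984 and m.15728 are `C` in the D-loop,
#' and m.11185 sits at the second base of ND4 codon 340 (Arg, CGC); for hg19,
#' m.310 is `T` inside a poly-C context. Coordinates, not sequence content,
#' drive the analysis.
#'
#' @param species `"mm10"` or `"hg19"`.
#' @param nuclear_chroms Named integer vector of (toy) nuclear chromosome
#'   lengths used by the simulator.
#' @param seed Seed for the random portion of the reference.
#'
#' @return A `genome_spec`.
#' @export
mito_genome <- function(species = c("mm10", "hg19"),
                        nuclear_chroms = c(chr1 = 1e6L, chr2 = 1e6L),
                        seed = 20L) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0(species, "_mito_genes.tsv"),
                      package = "mtscatac")
  genes <- read_gene_model(path)
  len <- if (species == "mm10") 16299L else 16569L
  seq <- withr::with_seed(seed, random_dna(len))
  anchors <- if (species == "mm10") {
    list(c(15219L, "TTC"), c(9821L, "A"), c(15984L, "C"), c(15728L, "C"),
         c(11184L, "CGC"))
  } else {
    list(c(303L, "CCCCCCCTCCCCC"))  # puts T at m.310 within a poly-C tract
  }
  for (a in anchors) {
    pos <- as.integer(a[[1]])
    substr(seq, pos, pos + nchar(a[[2]]) - 1L) <- a[[2]]
  }
  genome_spec(species = species, nuclear_chroms = nuclear_chroms,
              mito_chrom = "chrM", mito_length = len, mito_genes = genes,
              mito_seq = seq)
}

#' Reference base(s) at mitochondrial position(s)
#'
#' @param genome A `genome_spec`.
#' @param pos Integer vector of 1-based mitochondrial positions.
#' @return Character vector of reference bases.
#' @export
ref_base <- function(genome, pos) {
  stopifnot(inherits(genome, "genome_spec"))
  if (any(pos < 1L | pos > genome$mito_length)) {
    abort("position outside mitochondrial genome")
  }
  vapply(pos, function(p) substr(genome$mito_seq, p, p), character(1))
}
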