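#' Annotate mitochondrial variants
#'
#' Maps each variant position onto the mito gene table and, for protein
#' genes, computes the cDNA offset (`c.N = pos - gene_start + 1` on plus
#' strand genes), the affected codon on the coding strand and the amino-acid
#' change under the vertebrate mitochondrial genetic code. Positions inside
#' tRNA/rRNA genes or the D-loop are noncoding; positions outside every
#' feature are intergenic. Variants in overlapping genes get one row per
#' gene. Protein genes whose length is not a multiple of three are trimmed
#' to the last complete codon (mitochondrial stop codons are completed
#' post-transcriptionally); a variant in the trimmed tail is reported
#' without an amino-acid call.
#'
#' @param variants Tibble with `pos`, `ref`, `alt` (and optionally
#'   `variant_id`).
#' @param genome A `genome_spec` with a gene table and reference sequence.
#' @return Tibble with one row per variant x overlapping feature: `gene`,
#'   `region` (`protein`, `tRNA`, `rRNA`, `D-loop`, `intergenic`), `effect`
#'   (`synonymous`, `nonsynonymous`, `noncoding`), `cdna_change`,
#'   `aa_change`.
#' @export
annotate_variants <- function(variants, genome) {
  if (!nrow(variants)) {
    return(tibble(variant_id = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(), region = character(),
                  effect = character(), cdna_change = character(),
                  aa_change = character()))
  }
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- sprintf("m.%d%s>%s", variants$pos, variants$ref,
                                   variants$alt)
  }
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  genes <- genome$mito_genes
  purrr::pmap_dfr(
    variants[, c("variant_id", "pos", "ref", "alt")],
    function(variant_id, pos, ref, alt) {
      hit <- genes[genes$start <= pos & genes$end >= pos, ]
      if (!nrow(hit)) {
        return(tibble(variant_id = variant_id, pos = pos, ref = ref, alt = alt,
                      gene = NA_character_, region = "intergenic",
                      effect = "noncoding", cdna_change = NA_character_,
                      aa_change = NA_character_))
      }
      purrr::pmap_dfr(hit, function(gene, start, end, strand, class) {
        region <- class
        if (class != "protein") {
          return(tibble(variant_id = variant_id, pos = pos, ref = ref,
                        alt = alt, gene = gene, region = region,
                        effect = "noncoding", cdna_change = NA_character_,
                        aa_change = NA_character_))
        }
        plus <- strand == "+"
        c_off <- if (plus) pos - start + 1L else end - pos + 1L
        c_ref <- if (plus) ref else comp[[ref]]
        c_alt <- if (plus) alt else comp[[alt]]
        cdna <- sprintf("c.%s%d%s", c_ref, c_off, c_alt)
        len <- end - start + 1L
        n_codon <- len %/% 3L
        codon_idx <- (c_off - 1L) %/% 3L  # 0-based
        if (codon_idx >= n_codon) {
          return(tibble(variant_id = variant_id, pos = pos, ref = ref,
                        alt = alt, gene = gene, region = region,
                        effect = "noncoding", cdna_change = cdna,
                        aa_change = NA_character_))
        }
        within <- (c_off - 1L) %% 3L + 1L
        cds_codon_start <- codon_idx * 3L + 1L
        if (plus) {
          g0 <- start + cds_codon_start - 1L
          codon <- substr(genome$mito_seq, g0, g0 + 2L)
        } else {
          g0 <- end - cds_codon_start + 1L
          fwd <- substr(genome$mito_seq, g0 - 2L, g0)
          codon <- paste(rev(comp[strsplit(fwd, "")[[1]]]), collapse = "")
        }
        mut <- codon
        substr(mut, within, within) <- c_alt
        aa_ref <- unname(code[codon])
        aa_alt <- unname(code[mut])
        tibble(
          variant_id = variant_id, pos = pos, ref = ref, alt = alt,
          gene = gene, region = region,
          effect = if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous",
          cdna_change = cdna,
          aa_change = sprintf("p.%s%d%s", aa_ref, codon_idx + 1L, aa_alt)
        )
      })
    }
  )
}
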