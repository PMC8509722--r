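#' Build a variant table
#'
#' Canonical container for single-nucleotide variant calls: a data.frame with
#' columns `chrom`, `pos`, `ref`, `alt`, `genotype`, `gene`, `maf`,
#' `consequence`, `protein_change`. Missing MAF is `NA` (no population
#' frequency record). `consequence` and `protein_change` are filled by
#' [annotate_consequence()].
#'
#' @param chrom,pos,ref,alt call coordinates and alleles (SNVs only).
#' @param genotype one of `"het"`, `"hom_ref"`, `"hom_alt"`.
#' @param gene gene symbol (may be `NA` before annotation).
#' @param maf minor allele frequency in `[0,1]` or `NA`.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, genotype = "het",
                          gene = NA_character_, maf = NA_real_) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   genotype = as.character(genotype),
                   gene = as.character(gene), maf = as.numeric(maf),
                   consequence = NA_character_,
                   protein_change = NA_character_,
                   stringsAsFactors = FALSE)
  validate_variants(df)
  class(df) <- c("variant_table", "data.frame")
  df
}

validate_variants <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "genotype", "maf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_var("variant table lacks columns: ",
                             paste(miss, collapse = ", "))
  bad <- nchar(df$ref) != 1L | nchar(df$alt) != 1L
  if (any(bad))
    stop_var("only SNVs are supported; indel alleles at row(s) ",
             paste(which(bad), collapse = ", "))
  if (any(df$ref == df$alt))
    stop_var("ref equals alt at row(s) ",
             paste(which(df$ref == df$alt), collapse = ", "))
  if (!all(df$genotype %in% c("het", "hom_ref", "hom_alt")))
    stop_var("genotype must be het/hom_ref/hom_alt")
  if (any(!is.na(df$maf) & (df$maf < 0 | df$maf > 1)))
    stop_var("maf must be in [0,1] or NA")
  invisible(df)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate protein consequences of SNVs against a transcript
#'
#' For each variant on the transcript's chromosome the coding consequence is
#' derived by codon lookup in the spliced CDS: `synonymous`, `missense` or
#' `nonsense`, with an HGVS-style short protein label (`p.R1135C`,
#' `p.L10=` for synonymous, `p.R12*` for a gained stop). Positions outside
#' the CDS are labelled `splice_region` (within 2 nt of a CDS segment
#' boundary, intronic side), `noncoding` (deeper intronic) or `utr` (inside
#' the transcript span but outside the CDS extremes). On `"-"`-strand
#' transcripts alleles are complemented before codon lookup.
#'
#' @param variants a variant table (see [variant_table()]).
#' @param tx a [transcript()].
#' @return the variant table with `gene`, `consequence` and `protein_change`
#'   filled.
#' @section Errors:
#' A variant whose `ref` allele disagrees with the transcript sequence raises
#' a reference-mismatch error naming the position. Indels are rejected.
#' @export
annotate_consequence <- function(variants, tx) {
  validate_variants(variants)
  stopifnot(inherits(tx, "transcript"))
  if (!all(variants$chrom == tx$chrom))
    stop_var("variant chromosome does not match transcript ", tx$id)
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    idx <- genomic_to_cds(tx, pos)
    if (is.na(idx)) {
      variants$consequence[i] <- noncoding_class(tx, pos)
      variants$protein_change[i] <- NA_character_
      variants$gene[i] <- tx$gene
      next
    }
    ref_sense <- if (tx$strand == "+") variants$ref[i]
                 else COMPLEMENT[[variants$ref[i]]]
    alt_sense <- if (tx$strand == "+") variants$alt[i]
                 else COMPLEMENT[[variants$alt[i]]]
    if (substr(tx$cds_sequence, idx, idx) != ref_sense)
      stop_var("reference mismatch at position ", pos, ": transcript has ",
               substr(tx$cds_sequence, idx, idx), " (sense strand), variant ",
               "ref gives ", ref_sense)
    codon_i <- (idx - 1L) %/% 3L + 1L
    frame <- (idx - 1L) %% 3L + 1L
    codon <- substr(tx$cds_sequence, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    alt_codon <- codon
    substr(alt_codon, frame, frame) <- alt_sense
    aa_ref <- Biostrings::GENETIC_CODE[[codon]]
    aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
    variants$consequence[i] <-
      if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else "missense"
    variants$protein_change[i] <- hgvs_p(aa_ref, codon_i, aa_alt)
    variants$gene[i] <- tx$gene
  }
  variants
}

# HGVS protein notation, one-letter short form: p.R1036Q; synonymous p.L10=;
# nonsense p.R12*.
hgvs_p <- function(aa_ref, codon, aa_alt) {
  suffix <- if (aa_ref == aa_alt) "=" else aa_alt
  paste0("p.", aa_ref, codon, suffix)
}

#' Filter to rare heterozygous missense variants in panel genes
#'
#' Retains exactly the variants that are missense, heterozygous, in one of
#' the panel `genes`, and rare: MAF below `maf_max` or absent. A missing MAF
#' counts as rare because novel variants carry no frequency record. Input
#' order is preserved and the filter is idempotent.
#'
#' @param variants an annotated variant table.
#' @param maf_max MAF upper bound (exclusive); default `0.01` (1 percent).
#' @param genes character vector of panel gene symbols; `NULL` disables the
#'   gene restriction.
#' @return the retained rows, original order.
#' @export
filter_rare_missense <- function(variants, maf_max = 0.01, genes = NULL) {
  if (nrow(variants) == 0L) return(variants)
  if (any(is.na(variants$consequence)))
    stop_var("variants must be annotated before filtering")
  keep <- variants$consequence == "missense" &
    variants$genotype == "het" &
    (is.na(variants$maf) | variants$maf < maf_max)
  if (!is.null(genes)) keep <- keep & variants$gene %in% genes
  variants[keep, , drop = FALSE]
}
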