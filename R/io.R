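#' Read variant calls from a VCF
#'
#'
#' Reads sites and the per-sample GT field from a VCF (v4.2) file. MAF is
#' taken from the INFO key `AF` when present, optionally overridden by a
#' sidecar TSV of `variant_key` (`chrom:pos:ref:alt`) and `maf`.
#'
#' @param vcf path to a VCF file (single sample).
#' @param maf_tsv optional path to a two-column TSV `variant_key`, `maf`.
#' @return an unannotated variant table (see [variant_table()]).
#' @export
read_vcf_variants <- function(vcf, maf_tsv = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  gt_raw <- if (ncol(v@gt) >= 2L)
    vcfR::extract.gt(v, element = "GT") else matrix("0/1", nrow(fix))
  gt <- gsub("\\|", "/", gt_raw[, 1])
  genotype <- ifelse(gt %in% c("0/1", "1/0"), "het",
                     ifelse(gt == "1/1", "hom_alt", "hom_ref"))
  out <- variant_table(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT, genotype = genotype,
                       maf = af)
  if (!is.null(maf_tsv)) {
    side <- read.delim(maf_tsv, stringsAsFactors = FALSE)
    key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    i <- match(key, side$variant_key)
    out$maf[!is.na(i)] <- side$maf[i[!is.na(i)]]
  }
  out
}

#' Write variant calls as a minimal VCF v4.2
#'
#' Emits one single-sample VCF record per variant with the MAF in `INFO/AF`
#' and the genotype in the `GT` field.
#'
#' @param variants a variant table.
#' @param path output file.
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_name = "sample1") {
  validate_variants(variants)
  gt <- c(het = "0/1", hom_ref = "0/0", hom_alt = "1/1")[variants$genotype]
  info <- ifelse(is.na(variants$maf), ".",
                 sprintf("AF=%g", variants$maf))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a transcript model as GFF3
#'
#' One `gene`/`mRNA` pair plus one `CDS` feature per segment.
#'
#' @param tx a [transcript()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript_gff3 <- function(tx, path) {
  seg <- tx$cds_segments
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = c(tx$span[1], tx$span[1],
                                        pmin(seg$start, seg$end)),
                              end = c(tx$span[2], tx$span[2],
                                      pmax(seg$start, seg$end))),
    strand = tx$strand,
    type = c("gene", "mRNA", rep("CDS", nrow(seg))),
    ID = c(tx$gene, tx$id, paste0(tx$id, ".cds", seq_len(nrow(seg)))),
    Parent = c(NA, tx$gene, rep(tx$id, nrow(seg))),
    gene = tx$gene, phase = c(NA, NA, cds_phases(tx)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# GFF3 phase column for CDS segments, in transcription order.
cds_phases <- function(tx) {
  w <- tx$cds_segments$end - tx$cds_segments$start + 1L
  off <- c(0L, cumsum(w)[-length(w)])
  as.integer((3L - off %% 3L) %% 3L)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read predictor calls from TSV
#'
#' Expects columns `variant`, `polyphen`, `sift`, `pmut`, `ddg` (HGVS-p key,
#' categorical levels as in [predictor_damage_count()]).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_predictor_calls <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_predictors(p)
  p
}

#' Read evidence-context flags from TSV
#'
#' Expects a `variant` key column plus the eight 0/1 flag columns (see
#' [build_profile()]).
#'
#' @param path TSV file.
#' @return validated data.frame with logical flags.
#' @export
read_evidence_context <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_evidence(e)
  for (f in EVIDENCE_FLAGS) e[[f]] <- as.logical(e[[f]])
  e
}

#' Write a classification report as TSV
#'
#' Columns mirror the published report layout: Variant, Prediction Score,
#' Odd Score, Merged Score In Silico, Prior OR, Posterior OR, Posterior OR%,
#' Meaning, Class.
#'
#' @param result a `bayes_result` from [classify()]/[classify_batch()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(result, path) {
  out <- data.frame(Variant = result$variant,
                    `Prediction Score` = result$prediction_score,
                    `Odd Score` = result$odd_score,
                    `Merged Score In Silico` = result$merged_score,
                    `Prior OR` = result$prior_or,
                    `Posterior OR` = result$posterior_or,
                    `Posterior OR%` = result$posterior_or_pct,
                    Meaning = result$meaning,
                    Class = result$class_index,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotated variant table as TSV
#'
#' @param variants a variant table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read repeat-unit boundaries from TSV
#'
#' Expects columns `protein_id`, `start`, `end` (and optionally `label`).
#'
#' @param path TSV file.
#' @param protein_id optional filter.
#' @return data.frame with `start`, `end` sorted by `start`.
#' @export
read_unit_boundaries <- function(path, protein_id = NULL) {
  b <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(protein_id)) b <- b[b$protein_id == protein_id, , drop = FALSE]
  b <- b[order(b$start), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Write a unit alignment as aligned FASTA
#'
#' @param aln a `unit_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  write_fasta(aln$rows, path, type = "AA")
}

#' Write a conservation profile as TSV
#'
#' Columns: `column`, `score`, `consensus`.
#'
#' @param profile a `conservation_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- data.frame(column = seq_along(profile$scores),
                    score = profile$scores,
                    consensus = strsplit(profile$consensus, "")[[1]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
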