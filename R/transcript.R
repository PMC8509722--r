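#' Construct a transcript model
#'
#' A transcript bundles the genomic layout of a coding sequence (ordered CDS
#' segments, 1-based inclusive, in transcription order) with the spliced CDS
#' nucleotide sequence and the encoded protein. The CDS includes the terminal
#' stop codon; the protein does not.
#'
#' @param id transcript identifier (e.g. a RefSeq accession).
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments data.frame with integer columns `start`, `end`
#'   (genomic, 1-based inclusive), rows sorted in transcription order: by
#'   ascending `start` on `"+"`, descending on `"-"`.
#' @param cds_sequence spliced coding sequence (frame 0, includes stop codon),
#'   already strand-corrected (i.e. the sense-strand sequence).
#' @param protein_sequence optional; derived by translation when `NULL`.
#' @param gene gene symbol carried to annotated variants (defaults to `id`).
#' @param span optional genomic `c(start, end)` of the whole transcript;
#'   defaults to the CDS extremes. Positions inside the span but outside the
#'   CDS extremes are annotated `utr`.
#' @return an object of class `transcript`.
#' @export
transcript <- function(id, chrom, strand, cds_segments, cds_sequence,
                       protein_sequence = NULL, gene = id, span = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!strand %in% c("+", "-")) stop_var("strand must be '+' or '-'")
  seg <- as.data.frame(cds_segments)[, c("start", "end")]
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  if (nrow(seg) < 1L || any(seg$end < seg$start))
    stop_var("malformed CDS segments")
  gstart <- seg[order(seg$start), , drop = FALSE]
  if (any(gstart$start[-1] <= gstart$end[-nrow(gstart)]))
    stop_var("CDS segments overlap")
  expected_order <- if (strand == "+") order(seg$start) else order(-seg$start)
  if (!identical(expected_order, seq_len(nrow(seg))))
    stop_var("CDS segments not in transcription order for strand ", strand)

  cds_sequence <- toupper(cds_sequence)
  widths <- seg$end - seg$start + 1L
  if (sum(widths) != nchar(cds_sequence))
    stop_var("CDS segment widths (", sum(widths),
             ") do not match cds_sequence length (", nchar(cds_sequence), ")")
  if (nchar(cds_sequence) %% 3L != 0L)
    stop_var("CDS length not divisible by 3")

  translated <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_sequence)))
  if (substr(translated, nchar(translated), nchar(translated)) != "*")
    stop_var("CDS does not end in a stop codon")
  body <- substr(translated, 1L, nchar(translated) - 1L)
  if (grepl("\\*", body))
    stop_var("internal stop codon in CDS")
  if (is.null(protein_sequence)) {
    protein_sequence <- body
  } else if (!identical(toupper(protein_sequence), body)) {
    stop_var("translated CDS does not match supplied protein_sequence")
  }

  if (is.null(span)) span <- c(min(seg$start), max(seg$end))
  span <- as.integer(span)
  if (span[1] > min(seg$start) || span[2] < max(seg$end))
    stop_var("span must contain all CDS segments")

  structure(list(id = id, chrom = chrom, strand = strand,
                 cds_segments = seg, cds_sequence = cds_sequence,
                 protein_sequence = protein_sequence, gene = gene,
                 span = span),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %s:%d-%d (%s), %d CDS segment(s), %d aa\n",
              x$id, x$chrom, x$span[1], x$span[2], x$strand,
              nrow(x$cds_segments), nchar(x$protein_sequence)))
  invisible(x)
}

# Map a genomic position to its 1-based index in the spliced CDS, or NA when
# the position is not coding. Walks segments in transcription order.
genomic_to_cds <- function(tx, pos) {
  off <- 0L
  for (k in seq_len(nrow(tx$cds_segments))) {
    s <- tx$cds_segments$start[k]; e <- tx$cds_segments$end[k]
    if (pos >= s && pos <= e) {
      return(off + if (tx$strand == "+") pos - s + 1L else e - pos + 1L)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

# Classification of a non-coding genomic position relative to the transcript:
# 'splice_region' within 2 nt of a CDS segment boundary on the intronic side,
# 'noncoding' deeper inside an intron, 'utr' inside the transcript span but
# outside the CDS extremes.
noncoding_class <- function(tx, pos) {
  seg <- tx$cds_segments
  cds_lo <- min(seg$start); cds_hi <- max(seg$end)
  if (pos < tx$span[1] || pos > tx$span[2])
    stop_var("position ", pos, " outside transcript span of ", tx$id)
  if (pos < cds_lo || pos > cds_hi) return("utr")
  # intronic: distance to the nearest segment edge
  d <- min(abs(pos - c(seg$start - 1L, seg$end + 1L))) + 1L
  if (d <= 2L) "splice_region" else "noncoding"
}

#' Read a transcript model from GFF3 + FASTA
#'
#' Builds a [transcript()] from the CDS features of a GFF3 file and a genome
#' FASTA. CDS segments are spliced in transcription order and
#' reverse-complemented on the minus strand.
#'
#' @param gff path to a GFF3 file containing `CDS` features for one
#'   transcript (optionally filtered by `id` against the feature `ID`/
#'   `Parent` attribute).
#' @param fasta path to the genome FASTA.
#' @param id optional transcript identifier to select among CDS features.
#' @param gene optional gene symbol (defaults to `id` or the GFF `gene`
#'   attribute when present).
#' @return a `transcript` object.
#' @export
read_transcript <- function(gff, fasta, id = NULL, gene = NULL) {
  all_gr <- rtracklayer::import(gff, format = "gff3")
  mr <- all_gr[tolower(as.character(all_gr$type)) %in% c("mrna", "gene")]
  span <- if (length(mr))
    c(min(GenomicRanges::start(mr)), max(GenomicRanges::end(mr))) else NULL
  gr <- all_gr[tolower(as.character(all_gr$type)) == "cds"]
  if (!is.null(id) && !is.null(gr$Parent)) {
    par <- vapply(gr$Parent, function(p) paste(p, collapse = ","), "")
    keep <- grepl(id, par, fixed = TRUE) |
      (!is.null(gr$ID) & grepl(id, as.character(gr$ID %||% ""), fixed = TRUE))
    if (any(keep)) gr <- gr[keep]
  }
  if (length(gr) == 0L) stop_var("no CDS features found in ", gff)
  strand <- as.character(GenomicRanges::strand(gr))[1]
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  seg <- data.frame(start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr))
  seg <- seg[order(if (strand == "+") seg$start else -seg$start), ,
             drop = FALSE]
  rownames(seg) <- NULL
  genome <- Biostrings::readDNAStringSet(fasta)
  gseq <- genome[[match(chrom, sub("\\s.*", "", names(genome)))]]
  pieces <- vapply(seq_len(nrow(seg)), function(k) {
    p <- Biostrings::subseq(gseq, seg$start[k], seg$end[k])
    if (strand == "-") p <- Biostrings::reverseComplement(p)
    as.character(p)
  }, "")
  gn <- gene %||% (if (!is.null(gr$gene)) as.character(gr$gene)[1] else NULL)
  tid <- id %||% (if (!is.null(gr$Parent) && length(gr$Parent[[1]]))
    as.character(gr$Parent[[1]][1]) else "tx1")
  transcript(id = tid, chrom = chrom, strand = strand, cds_segments = seg,
             cds_sequence = paste(pieces, collapse = ""),
             gene = gn %||% tid, span = span)
}
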