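# Independent oracles used across the suite. Each recomputes an expected
# value along a different route than the implementation under test.

# Splice the CDS of a transcript straight out of a genome string.
oracle_splice_cds <- function(tx, genome) {
  seg <- tx$cds_segments
  pieces <- vapply(seq_len(nrow(seg)), function(k) {
    p <- substr(genome, seg$start[k], seg$end[k])
    if (tx$strand == "-")
      p <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
    p
  }, "")
  paste(pieces, collapse = "")
}

# Genomic position -> spliced CDS index by direct walking (NA if noncoding).
oracle_cds_index <- function(tx, pos) {
  seg <- tx$cds_segments
  off <- 0L
  for (k in seq_len(nrow(seg))) {
    w <- seg$end[k] - seg$start[k] + 1L
    if (pos >= seg$start[k] && pos <= seg$end[k]) {
      return(off + if (tx$strand == "+") pos - seg$start[k] + 1L
             else seg$end[k] - pos + 1L)
    }
    off <- off + w
  }
  NA_integer_
}

# Brute-force consequence oracle: mutate the genome, re-splice, translate the
# whole CDS, and diff the two protein strings (stop included).
oracle_consequence <- function(tx, genome, pos, alt) {
  idx <- oracle_cds_index(tx, pos)
  if (is.na(idx)) {
    seg <- tx$cds_segments
    lo <- min(seg$start); hi <- max(seg$end)
    if (pos < lo || pos > hi)
      return(list(consequence = "utr", protein_change = NA_character_))
    d <- min(abs(pos - (seg$start - 1L)), abs(pos - (seg$end + 1L))) + 1L
    return(list(consequence = if (d <= 2L) "splice_region" else "noncoding",
                protein_change = NA_character_))
  }
  mutated <- genome
  substr(mutated, pos, pos) <- alt
  tr <- function(g) as.character(Biostrings::translate(
    Biostrings::DNAString(oracle_splice_cds(tx, g))))
  p_ref <- strsplit(tr(genome), "")[[1]]
  p_alt <- strsplit(tr(mutated), "")[[1]]
  codon <- (idx - 1L) %/% 3L + 1L
  if (identical(p_ref, p_alt)) {
    return(list(consequence = "synonymous",
                protein_change = paste0("p.", p_ref[codon], codon, "=")))
  }
  diffi <- which(p_ref != p_alt)[1]
  aa_alt <- p_alt[diffi]
  list(consequence = if (aa_alt == "*") "nonsense" else "missense",
       protein_change = paste0("p.", p_ref[diffi], diffi, aa_alt))
}

# All single-nucleotide substitutions across a transcript span, annotated by
# both routes; ref alleles read from the genome so no mismatch can occur.
all_snvs_in_span <- function(tx, genome) {
  pos <- tx$span[1]:tx$span[2]
  do.call(rbind, lapply(pos, function(p) {
    ref <- substr(genome, p, p)
    data.frame(pos = p, ref = ref, alt = setdiff(c("A", "C", "G", "T"), ref),
               stringsAsFactors = FALSE)
  }))
}

# Exhaustive dynamic-programming alignment score oracle with affine gaps
# (gap run of length k costs open + k * extend), memoized over (i, j, state).
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 1) {
  sub <- varodds:::submatrix_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1L, j + 1L, "D"))
    if (i <= n) {
      cost <- if (prev == "U") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1L, j, "U"))
    }
    if (j <= m) {
      cost <- if (prev == "L") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1L, "L"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "start")
}

# Recompute an alignment score from its gapped rows (affine gap recount).
score_gapped_pair <- function(ga, gb, gap_open = 10, gap_extend = 1) {
  sub <- varodds:::submatrix_blosum62()
  av <- strsplit(ga, "")[[1]]; bv <- strsplit(gb, "")[[1]]
  s <- 0; in_a_gap <- FALSE; in_b_gap <- FALSE
  for (k in seq_along(av)) {
    if (av[k] == "-") {
      s <- s - gap_extend - if (in_a_gap) 0 else gap_open
      in_a_gap <- TRUE; in_b_gap <- FALSE
    } else if (bv[k] == "-") {
      s <- s - gap_extend - if (in_b_gap) 0 else gap_open
      in_b_gap <- TRUE; in_a_gap <- FALSE
    } else {
      s <- s + sub[av[k], bv[k]]
      in_a_gap <- in_b_gap <- FALSE
    }
  }
  s
}

# Non-overlapping left-to-right P-P-x-S-P scan by explicit sliding window.
oracle_ppxsp <- function(protein) {
  v <- strsplit(protein, "")[[1]]
  out <- NULL
  i <- 1L
  while (i <= length(v) - 4L) {
    if (v[i] == "P" && v[i + 1L] == "P" && v[i + 3L] == "S" &&
        v[i + 4L] == "P") {
      out <- rbind(out, c(i, i + 4L))
      i <- i + 5L
    } else i <- i + 1L
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = out[, 1], end = out[, 2])
}

random_aa_string <- function(n, alphabet = varodds:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

lrp5_file_for_test <- function(name) {
  system.file("extdata", "lrp5", name, package = "varodds", mustWork = TRUE)
}
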