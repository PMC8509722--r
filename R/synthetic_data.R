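#' Simulation configuration
#'
#' One configuration object drives every generator; identical configurations
#' (seed included) give byte-identical outputs. Each generator draws from its
#' own stream (`seed` plus a fixed per-generator offset), so adding a
#' generator never perturbs the others. Cohort defaults mirror a screen of
#' 128 men with idiopathic low bone mass carrying 11 rare-variant carriers:
#' age 41.6 +/- 8.7 years (truncated to 18-60), lumbar T -2.5 +/- 0.55,
#' lumbar Z -2.48 +/- 0.59, total-hip T -1.07 +/- 0.79, total-hip Z
#' -0.99 +/- 0.72, lumbar/total-hip BMD 0.82 +/- 0.07 and 0.88 +/- 0.11
#' g/cm^2. Variant generation plants truth labels: a pathogenic-profile
#' variant draws each damaging predictor call and each evidence flag
#' positive with probability `p_pathogenic` (default 0.8), a benign-profile
#' variant with `p_benign` (default 0.1).
#'
#' @param seed integer master seed.
#' @param n_subjects cohort size.
#' @param carrier_fraction fraction of carriers; the carrier count is
#'   assigned deterministically as `round(fraction * n)`, not by coin flips.
#' @param n_variants number of variants in the synthetic variant table.
#' @param pathogenic_fraction fraction of variants planted pathogenic
#'   (deterministic count, like carriers).
#' @param p_pathogenic,p_benign class-conditional probabilities that any
#'   single predictor call / evidence flag is positive.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param bmd_l,t_l,z_l,bmd_th,t_th,z_th length-2 `c(mean, sd)` per DXA
#'   measurement.
#' @param unit_length,n_units,unit_mut_rate repeat-protein generator: unit
#'   length, number of units, per-position substitution rate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_subjects = 128L,
                       carrier_fraction = 11 / 128,
                       n_variants = 20L, pathogenic_fraction = 0.5,
                       p_pathogenic = 0.8, p_benign = 0.1,
                       age_mean = 41.6, age_sd = 8.7,
                       age_range = c(18, 60),
                       bmd_l = c(0.82, 0.07), t_l = c(-2.5, 0.55),
                       z_l = c(-2.48, 0.59), bmd_th = c(0.88, 0.11),
                       t_th = c(-1.07, 0.79), z_th = c(-0.99, 0.72),
                       unit_length = 40L, n_units = 4L,
                       unit_mut_rate = 0.2) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              carrier_fraction = carrier_fraction,
              n_variants = as.integer(n_variants),
              pathogenic_fraction = pathogenic_fraction,
              p_pathogenic = p_pathogenic, p_benign = p_benign,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              bmd_l = bmd_l, t_l = t_l, z_l = z_l, bmd_th = bmd_th,
              t_th = t_th, z_th = z_th,
              unit_length = as.integer(unit_length),
              n_units = as.integer(n_units),
              unit_mut_rate = unit_mut_rate)
  probs <- c(cfg$carrier_fraction, cfg$pathogenic_fraction,
             cfg$p_pathogenic, cfg$p_benign, cfg$unit_mut_rate)
  if (any(probs < 0 | probs > 1)) stop_var("probabilities must be in [0,1]")
  if (cfg$n_subjects < 0L || cfg$n_variants < 0L)
    stop_var("counts must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws ages from a truncated normal and DXA scores from normals per the
#' configuration; flags exactly `round(carrier_fraction * n)` subjects as
#' carriers (positions seeded).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `id`, `age`, `bmd_l`, `t_l`, `z_l`,
#'   `bmd_th`, `t_th`, `z_th`, `carrier`.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  n <- cfg$n_subjects
  if (n == 0L) {
    return(data.frame(id = character(0), age = numeric(0),
                      bmd_l = numeric(0), t_l = numeric(0), z_l = numeric(0),
                      bmd_th = numeric(0), t_th = numeric(0),
                      z_th = numeric(0), carrier = logical(0)))
  }
  age <- rnorm(n, cfg$age_mean, cfg$age_sd)
  while (any(out <- age < cfg$age_range[1] | age > cfg$age_range[2]))
    age[out] <- rnorm(sum(out), cfg$age_mean, cfg$age_sd)
  draw <- function(ms) rnorm(n, ms[1], ms[2])
  k <- round(cfg$carrier_fraction * n)
  carrier <- rep(FALSE, n)
  if (k > 0L) carrier[sample.int(n, k)] <- TRUE
  data.frame(id = sprintf("S%04d", seq_len(n)), age = age,
             bmd_l = draw(cfg$bmd_l), t_l = draw(cfg$t_l),
             z_l = draw(cfg$z_l), bmd_th = draw(cfg$bmd_th),
             t_th = draw(cfg$t_th), z_th = draw(cfg$z_th),
             carrier = carrier, stringsAsFactors = FALSE)
}

#' Generate a synthetic variant table with planted truth
#'
#' Emits `n_variants` rare missense variants with predictor calls and
#' evidence contexts drawn from class-conditional probabilities: exactly
#' `round(pathogenic_fraction * n)` variants are planted pathogenic and draw
#' each damaging call / positive flag with probability `p_pathogenic`; the
#' rest use `p_benign`. All MAFs are below 0.01. Truth labels are returned
#' in a separate sidecar table and never appear in the pipeline inputs.
#' When both the literature and dbSNP flags are drawn for a variant the
#' dbSNP flag is dropped (the two are mutually exclusive by definition).
#'
#' @param cfg a [sim_config()].
#' @return list with `variants`, `predictors`, `evidence`, `truth`
#'   data.frames, keyed by the `variant` column.
#' @export
gen_variant_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  n <- cfg$n_variants
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(variants = empty(variant = character(0)),
                predictors = empty(variant = character(0)),
                evidence = empty(variant = character(0)),
                truth = empty(variant = character(0),
                              pathogenic = logical(0))))
  }
  pos <- sort(sample.int(5000L, n))
  ref_aa <- sample(AA20, n, replace = TRUE)
  alt_aa <- vapply(ref_aa, function(a) sample(setdiff(AA20, a), 1L), "")
  label <- paste0("p.", ref_aa, pos, alt_aa)
  n_path <- round(cfg$pathogenic_fraction * n)
  pathogenic <- rep(FALSE, n)
  if (n_path > 0L) pathogenic[sample.int(n, n_path)] <- TRUE
  p <- ifelse(pathogenic, cfg$p_pathogenic, cfg$p_benign)
  bern <- function() runif(n) < p
  polyphen <- ifelse(bern(),
                     sample(c("possibly_damaging", "probably_damaging"), n,
                            replace = TRUE),
                     "benign")
  sift <- ifelse(bern(), "not_tolerated", "tolerated")
  pmut <- ifelse(bern(), "disease", "neutral")
  lit <- bern()
  dbsnp <- bern() & !lit
  evidence <- empty(variant = label,
                    literature_pathogenic = lit,
                    dbsnp_low_freq_no_functional = dbsnp,
                    prior_annotation_in_db = bern(),
                    in_functional_domain = bern(),
                    in_structured_domain = bern(),
                    on_linear_motif = bern(),
                    conserved_position = bern(),
                    low_complexity_context = bern())
  list(variants = empty(variant = label, gene = "GENE1",
                        consequence = "missense", genotype = "het",
                        maf = runif(n, 0, 0.0099)),
       predictors = empty(variant = label, polyphen = polyphen, sift = sift,
                          pmut = pmut, ddg = -runif(n, 0.1, 1.5)),
       evidence = evidence,
       truth = empty(variant = label, pathogenic = pathogenic))
}

#' Generate a synthetic repeat protein
#'
#' Draws a random consensus unit and emits `n_units` copies, each position
#' independently substituted with probability `unit_mut_rate` (always to a
#' different residue), concatenated into one protein with exact unit
#' boundaries. The true consensus is returned for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @return list with `protein` (string), `boundaries` (data.frame `start`,
#'   `end`), `consensus` (string), `units` (character vector).
#' @export
gen_repeat_protein <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_units < 2L) stop_var("n_units must be at least 2")
  set.seed(cfg$seed + 303L)
  L <- cfg$unit_length
  consensus <- sample(AA20, L, replace = TRUE)
  units <- vapply(seq_len(cfg$n_units), function(u) {
    unit <- consensus
    hit <- runif(L) < cfg$unit_mut_rate
    if (any(hit))
      unit[hit] <- vapply(consensus[hit],
                          function(a) sample(setdiff(AA20, a), 1L), "")
    paste(unit, collapse = "")
  }, "")
  starts <- (seq_len(cfg$n_units) - 1L) * L + 1L
  list(protein = paste(units, collapse = ""),
       boundaries = data.frame(start = starts, end = starts + L - 1L),
       consensus = paste(consensus, collapse = ""),
       units = units)
}

FOURFOLD_PREFIX <- c("GC", "GT", "CT", "CG", "AC", "GG", "CC", "TC")
BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_codons <- function(n_codons) {
  vapply(seq_len(n_codons), function(i) {
    if (i %% 2L == 0L) {
      paste0(sample(FOURFOLD_PREFIX, 1L), sample(BASES, 1L))
    } else {
      repeat {
        cd <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
        if (!cd %in% STOPS) return(cd)
      }
    }
  }, "")
}

# Inverse of genomic_to_cds: genomic position of the idx-th spliced CDS base.
cds_to_genomic <- function(tx, idx) {
  off <- 0L
  for (k in seq_len(nrow(tx$cds_segments))) {
    s <- tx$cds_segments$start[k]; e <- tx$cds_segments$end[k]
    w <- e - s + 1L
    if (idx <= off + w) {
      return(if (tx$strand == "+") s + (idx - off - 1L)
             else e - (idx - off - 1L))
    }
    off <- off + w
  }
  stop_var("CDS index out of range")
}

#' Generate a toy multi-exon transcript with planted variants
#'
#' Builds a small transcript (default 10 codons over 3 exons) inside a
#' random genome fragment and plants 20 variants with known expected
#' annotations: 7 that pass the rare-heterozygous-missense filter and 13
#' that each fail exactly one predicate (synonymous, homozygous, common, or
#' non-coding position). Expected consequences are derived directly from the
#' codon table during planting, independently of the annotation code paths.
#'
#' @param cfg a [sim_config()].
#' @param n_codons protein length in codons (stop codon added on top).
#' @param n_exons number of CDS segments.
#' @param strand `"+"` or `"-"`.
#' @return list with `transcript`, `genome` (named character, one contig),
#'   `variants` (unannotated variant table) and `expected` (sidecar truth:
#'   `pos`, `ref`, `alt`, `genotype`, `maf`, `consequence`,
#'   `protein_change`, `qualifies`).
#' @export
gen_toy_transcript <- function(cfg, n_codons = 10L, n_exons = 3L,
                               strand = "+") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 404L)
  chrom <- "chrS"
  syn <- mis <- NULL
  for (attempt in seq_len(100L)) {
    codons <- random_codons(n_codons)
    cds <- paste(c(codons, "TAA"), collapse = "")
    ncds <- 3L * n_codons           # plantable positions (stop excluded)
    # candidate substitutions classified straight from the codon table
    cand <- do.call(rbind, lapply(seq_len(ncds), function(idx) {
      ci <- (idx - 1L) %/% 3L + 1L
      fr <- (idx - 1L) %% 3L + 1L
      codon <- codons[ci]
      ref <- substr(codon, fr, fr)
      do.call(rbind, lapply(setdiff(BASES, ref), function(alt) {
        altc <- codon
        substr(altc, fr, fr) <- alt
        aa_r <- Biostrings::GENETIC_CODE[[codon]]
        aa_a <- Biostrings::GENETIC_CODE[[altc]]
        data.frame(idx = idx, ref = ref, alt = alt, codon_i = ci,
                   aa_ref = aa_r, aa_alt = aa_a,
                   cons = if (aa_r == aa_a) "synonymous"
                          else if (aa_a == "*") "nonsense" else "missense",
                   stringsAsFactors = FALSE)
      }))
    }))
    # one candidate per position, preferring the class we need
    pick_positions <- function(df, k, used) {
      df <- df[!df$idx %in% used, , drop = FALSE]
      df <- df[!duplicated(df$idx), , drop = FALSE]
      if (nrow(df) < k) return(NULL)
      df[seq_len(k), , drop = FALSE]
    }
    used <- integer(0)
    syn <- pick_positions(cand[cand$cons == "synonymous", ], 4L, used)
    if (is.null(syn)) next
    used <- c(used, syn$idx)
    mis <- pick_positions(cand[cand$cons == "missense", ], 13L, used)
    if (is.null(mis)) next
    break
  }
  if (is.null(syn) || is.null(mis))
    stop_var("could not plant the requested variant mixture")

  # genome layout: 25 nt flanks, 12 nt introns
  flank <- 25L; intron_w <- 12L
  lens <- rep(nchar(cds) %/% n_exons, n_exons)
  lens[n_exons] <- lens[n_exons] + nchar(cds) %% n_exons
  genome_cds <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  pieces <- character(n_exons); off <- 0L
  glens <- if (strand == "+") lens else rev(lens)
  for (k in seq_len(n_exons)) {
    pieces[k] <- substr(genome_cds, off + 1L, off + glens[k])
    off <- off + glens[k]
  }
  rnd <- function(w) paste(sample(BASES, w, replace = TRUE), collapse = "")
  genome <- rnd(flank)
  seg <- data.frame(start = integer(n_exons), end = integer(n_exons))
  for (k in seq_len(n_exons)) {
    seg$start[k] <- nchar(genome) + 1L
    genome <- paste0(genome, pieces[k])
    seg$end[k] <- nchar(genome)
    if (k < n_exons) genome <- paste0(genome, rnd(intron_w))
  }
  genome <- paste0(genome, rnd(flank))
  span <- c(min(seg$start) - 20L, max(seg$end) + 20L)
  if (strand == "-") seg <- seg[order(-seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  tx <- transcript(id = "TOY1", chrom = chrom, strand = strand,
                   cds_segments = seg, cds_sequence = cds, gene = "TOYG",
                   span = span)

  to_genomic <- function(idx, base) {
    # sense-strand base -> genomic-strand allele
    list(pos = cds_to_genomic(tx, idx),
         allele = if (strand == "+") base else COMPLEMENT[[base]])
  }
  plant <- function(df, genotype, maf, qualifies) {
    rows <- lapply(seq_len(nrow(df)), function(r) {
      gref <- to_genomic(df$idx[r], df$ref[r])
      galt <- to_genomic(df$idx[r], df$alt[r])
      data.frame(pos = gref$pos, ref = gref$allele, alt = galt$allele,
                 genotype = genotype, maf = maf[r],
                 consequence = df$cons[r],
                 protein_change = hgvs_p(df$aa_ref[r], df$codon_i[r],
                                         df$aa_alt[r]),
                 qualifies = qualifies, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  q_mis <- mis[1:7, ]; hom_mis <- mis[8:10, ]; common_mis <- mis[11:13, ]
  planted <- rbind(
    plant(q_mis, "het", c(runif(5, 0.001, 0.009), NA, NA), TRUE),
    plant(syn, "het", runif(4, 0.001, 0.009), FALSE),
    plant(hom_mis, "hom_alt", runif(3, 0.001, 0.009), FALSE),
    plant(common_mis, "het", runif(3, 0.02, 0.05), FALSE))
  # non-coding plants: splice region, intron interior, UTR
  gseg <- seg[order(seg$start), , drop = FALSE]
  splice_pos <- gseg$end[1] + 1L
  deep_pos <- gseg$end[1] + intron_w %/% 2L
  utr_pos <- span[1] + 2L
  base_at <- function(p) substr(genome, p, p)
  nc <- do.call(rbind, lapply(
    list(c(splice_pos, "splice_region"), c(deep_pos, "noncoding"),
         c(utr_pos, "utr")),
    function(x) {
      p <- as.integer(x[1])
      data.frame(pos = p, ref = base_at(p),
                 alt = sample(setdiff(BASES, base_at(p)), 1L),
                 genotype = "het", maf = NA_real_, consequence = x[2],
                 protein_change = NA_character_, qualifies = FALSE,
                 stringsAsFactors = FALSE)
    }))
  planted <- rbind(planted, nc)
  planted <- planted[order(planted$pos), , drop = FALSE]
  rownames(planted) <- NULL
  variants <- variant_table(chrom = chrom, pos = planted$pos,
                            ref = planted$ref, alt = planted$alt,
                            genotype = planted$genotype, maf = planted$maf)
  list(transcript = tx, genome = setNames(genome, chrom),
       variants = variants, expected = planted)
}
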