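#' Column conservation score and flag
#'
#' Conservation of one alignment column: the frequency of the modal non-gap
#' residue among non-gap entries. The binary descriptor fires when the score
#' reaches `threshold`. An all-gap column scores 0.
#'
#' @param column character vector of single residues; `'-'` marks a gap.
#' @param threshold conservation level above which the position counts as
#'   conserved (default 0.9).
#' @return list with `score` (fraction) and `flag` (0/1).
#' @export
conservation_descriptor <- function(column, threshold = 0.9) {
  if (length(column) == 0L) stop_var("empty column")
  column <- toupper(column)
  bad <- !column %in% c(AA20, "-")
  if (any(bad))
    stop_var("unknown residue symbol(s): ",
             paste(unique(column[bad]), collapse = ", "))
  res <- column[column != "-"]
  if (length(res) == 0L) return(list(score = 0, flag = 0L))
  score <- max(table(res)) / length(res)
  list(score = unname(score), flag = as.integer(score >= threshold))
}

#' Local sequence complexity (Shannon entropy) and low-complexity flag
#'
#' Shannon entropy (base 2) of residue frequencies in a sequence window. Low
#' complexity — entropy below `threshold` bits — is the pathogenicity-relevant
#' context and raises the flag.
#'
#' @param window amino-acid string or character vector, length >= 5.
#' @param threshold entropy cutoff in bits (default 2.0).
#' @return list with `entropy` (bits) and `flag` (0/1, 1 = low complexity).
#' @export
complexity_descriptor <- function(window, threshold = 2.0) {
  if (length(window) == 1L) window <- strsplit(window, "")[[1]]
  window <- toupper(window)
  if (length(window) < 5L) stop_var("window must contain at least 5 residues")
  bad <- !window %in% AA20
  if (any(bad))
    stop_var("unknown residue symbol(s): ",
             paste(unique(window[bad]), collapse = ", "))
  p <- table(window) / length(window)
  entropy <- -sum(p * log2(p))
  list(entropy = unname(entropy), flag = as.integer(entropy < threshold))
}

#' Linear-motif proximity descriptor
#'
#' Fires when a protein position lies inside a motif interval or within
#' `proximity` residues of one (covering, e.g., a substitution sitting
#' between two phosphorylation motifs on a receptor tail).
#'
#' @param protein_pos 1-based residue position.
#' @param motifs data.frame with `start`, `end` columns (1-based inclusive,
#'   sorted), or an empty data.frame.
#' @param proximity flanking distance in residues (default 5).
#' @return 0/1.
#' @export
motif_descriptor <- function(protein_pos, motifs, proximity = 5L) {
  if (NROW(motifs) == 0L) return(0L)
  motifs <- as.data.frame(motifs)
  as.integer(any(protein_pos >= motifs$start - proximity &
                 protein_pos <= motifs$end + proximity))
}

#' Find PPxSP phosphorylation motifs
#'
#' Scans a protein sequence left to right for non-overlapping occurrences of
#' the pattern P-P-x-S-P (x = any residue). The pattern covers both the PPSP
#' and PPPSP spellings of the LRP-family tail motif.
#'
#' @param protein amino-acid string.
#' @return data.frame with `start`, `end` (1-based inclusive); zero rows when
#'   no motif is present.
#' @export
find_ppxsp_motifs <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  m <- gregexpr("PP[A-Z]SP", toupper(protein))[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

POLYPHEN_LEVELS <- c("benign", "possibly_damaging", "probably_damaging")
SIFT_LEVELS <- c("tolerated", "not_tolerated")
PMUT_LEVELS <- c("neutral", "disease")

validate_predictors <- function(p) {
  need <- c("polyphen", "sift", "pmut")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop_var("predictor table lacks columns: ",
                             paste(miss, collapse = ", "))
  if (!all(p$polyphen %in% POLYPHEN_LEVELS))
    stop_var("polyphen must be one of: ",
             paste(POLYPHEN_LEVELS, collapse = ", "))
  if (!all(p$sift %in% SIFT_LEVELS))
    stop_var("sift must be one of: ", paste(SIFT_LEVELS, collapse = ", "))
  if (!all(p$pmut %in% PMUT_LEVELS))
    stop_var("pmut must be one of: ", paste(PMUT_LEVELS, collapse = ", "))
  if (!is.null(p$ddg) && any(!is.finite(p$ddg)))
    stop_var("ddg must be finite")
  invisible(p)
}

#' Count damaging in-silico predictor calls
#'
#' Number of damaging calls among the three categorical predictors:
#' PolyPhen-2-style possibly/probably damaging, SIFT-style not tolerated,
#' Pmut-style disease. The stability change (ddg) is carried in reports but
#' not counted: uniformly destabilizing predictions carry no discrimination.
#'
#' @param p data.frame (or one-row list) with columns `polyphen`, `sift`,
#'   `pmut` and optionally `ddg`.
#' @return integer vector in `[0, 3]`, one per row.
#' @export
predictor_damage_count <- function(p) {
  p <- as.data.frame(p)
  validate_predictors(p)
  as.integer((p$polyphen %in% c("possibly_damaging", "probably_damaging")) +
             (p$sift == "not_tolerated") +
             (p$pmut == "disease"))
}

EVIDENCE_FLAGS <- c("literature_pathogenic", "dbsnp_low_freq_no_functional",
                    "prior_annotation_in_db", "in_functional_domain",
                    "in_structured_domain", "on_linear_motif",
                    "conserved_position", "low_complexity_context")

validate_evidence <- function(e) {
  miss <- setdiff(EVIDENCE_FLAGS, names(e))
  if (length(miss)) stop_var("evidence table lacks columns: ",
                             paste(miss, collapse = ", "))
  for (f in EVIDENCE_FLAGS) {
    v <- e[[f]]
    if (!(is.logical(v) || all(v %in% c(0L, 1L))))
      stop_var("evidence flag ", f, " must be logical or 0/1")
  }
  both <- as.logical(e$literature_pathogenic) &
    as.logical(e$dbsnp_low_freq_no_functional)
  if (any(both))
    stop_var("literature_pathogenic and dbsnp_low_freq_no_functional may ",
             "not both be set (row ", which(both)[1], ")")
  invisible(e)
}

#' Assemble the eight-descriptor evidence profile
#'
#' Combines in-silico predictor calls and the evidence context of each
#' variant into the eight binary descriptors, ordered as: d1 sequence
#' conservation, d2 functional domain, d3 local sequence complexity (low),
#' d4 structured domain, d5 functional linear motif, d6 in-silico predictor
#' agreement (damage count >= `agreement_min`), d7 prior annotation in public
#' databases, d8 literature data. The profile is a pure function of its
#' inputs.
#'
#' @param variants character vector of variant labels (HGVS-p), or a
#'   data.frame with a `variant` column.
#' @param predictors predictor-call table with a `variant` key column.
#' @param evidence evidence-context table with a `variant` key column.
#' @param agreement_min damaging-call count at which d6 fires (default 2).
#' @return data.frame with columns `variant`, `d1`..`d8`.
#' @export
build_profile <- function(variants, predictors, evidence, agreement_min = 2L) {
  labels <- if (is.data.frame(variants)) variants$variant
            else as.character(variants)
  predictors <- as.data.frame(predictors)
  evidence <- as.data.frame(evidence)
  validate_predictors(predictors)
  validate_evidence(evidence)
  ip <- match(labels, predictors$variant)
  ie <- match(labels, evidence$variant)
  if (any(is.na(ip)))
    stop_var("no predictor calls for variant ", labels[which(is.na(ip))[1]])
  if (any(is.na(ie)))
    stop_var("no evidence context for variant ", labels[which(is.na(ie))[1]])
  p <- predictors[ip, , drop = FALSE]
  e <- evidence[ie, , drop = FALSE]
  flag <- function(x) as.integer(as.logical(x))
  data.frame(variant = labels,
             d1 = flag(e$conserved_position),
             d2 = flag(e$in_functional_domain),
             d3 = flag(e$low_complexity_context),
             d4 = flag(e$in_structured_domain),
             d5 = flag(e$on_linear_motif),
             d6 = as.integer(predictor_damage_count(p) >= agreement_min),
             d7 = flag(e$prior_annotation_in_db),
             d8 = flag(e$literature_pathogenic),
             row.names = NULL, stringsAsFactors = FALSE)
}
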