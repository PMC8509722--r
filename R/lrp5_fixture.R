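lrp5_file <- function(name) {
  system.file("extdata", "lrp5", name, package = "varodds", mustWork = TRUE)
}

#' Bundled LRP5 case study: in-silico predictor calls
#'
#' Categorical pathogenicity predictions (PolyPhen-2, SIFT, Pmut styles) and
#' stability changes for the ten rare heterozygous LRP5 missense variants
#' identified in a screen of 128 men with idiopathic low bone mass.
#'
#' @return data.frame with columns `variant`, `polyphen`, `sift`, `pmut`,
#'   `ddg`.
#' @export
lrp5_predictor_calls <- function() {
  read_predictor_calls(lrp5_file("predictor_calls.tsv"))
}

#' Bundled LRP5 case study: reconstructed evidence contexts
#'
#' Per-variant binarization of the eight evidence descriptors for the LRP5
#' case study. The source analysis reports only aggregated scores; these
#' flags are a reconstruction consistent with the reported domain, motif,
#' conservation and database context of each variant, and reproduce the
#' published odd scores and priors. Treat them as a worked illustration, not
#' primary data.
#'
#' @return data.frame with `variant` plus the eight logical flag columns.
#' @export
lrp5_evidence_context <- function() {
  read_evidence_context(lrp5_file("evidence_context_reconstructed.tsv"))
}

#' Bundled LRP5 case study: published score table
#'
#' The published per-variant prediction score, odd score, merged score,
#' prior OR, posterior OR, posterior OR percent, meaning and class for the
#' ten LRP5 variants. Two internal inconsistencies present in the published
#' table are preserved verbatim (a posterior printed as 8.745 whose own
#' percentage implies 8.75, and one merged score that is not the sum of its
#' components); [classify()] flags rather than silently reproduces them.
#'
#' @return data.frame, one row per variant.
#' @export
lrp5_published_scores <- function() {
  read.delim(lrp5_file("published_scores.tsv"), stringsAsFactors = FALSE)
}

#' Bundled LRP5 case study: carrier cohort rows
#'
#' Age and DXA measurements of the eleven carriers of the ten rare LRP5
#' variants (two subjects share one variant).
#'
#' @return data.frame with id, variant, ACMG class, age, BMD and T/Z scores,
#'   and a `carrier` flag (all 1).
#' @export
lrp5_carriers <- function() {
  x <- read.delim(lrp5_file("carriers.tsv"), stringsAsFactors = FALSE)
  x$carrier <- as.logical(x$carrier)
  x
}
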