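PRIOR_LITERATURE <- 19      # 95:5 odds, literature-described pathogenic
PRIOR_DBSNP <- 1.25         # 5:4 odds, low-frequency dbSNP, no functional data
PRIOR_DEFAULT <- 1          # 50:50 odds, everything else

# Maximum merged score (prediction 4 + odd 5); posterior OR is reported as a
# percentage of this ceiling.
MERGED_MAX <- 9

CLASS_LABELS <- c("Neutral", "Likely Neutral", "Uncertain",
                  "Likely Pathogenic", "Pathogenic")
CLASS_ABBREV <- c("N", "LN", "U", "LP", "P")

#' Assign the prior odds ratio from the evidence context
#'
#' Prior odds in favour of pathogenicity before scoring: 19 (95:5) for
#' variants described in the literature as pathogenic, 1.25 (5:4) for
#' variants present in dbSNP at low frequency without functional data, and 1
#' (50:50) otherwise. Precedence: literature > dbSNP > default.
#'
#' @param evidence evidence-context data.frame (see [build_profile()] for the
#'   flag columns); vectorized over rows.
#' @return numeric vector of prior odds ratios in `{19, 1.25, 1}`.
#' @export
assign_prior <- function(evidence) {
  e <- as.data.frame(evidence)
  miss <- setdiff(c("literature_pathogenic", "dbsnp_low_freq_no_functional"),
                  names(e))
  if (length(miss)) stop_var("evidence lacks columns: ",
                             paste(miss, collapse = ", "))
  ifelse(as.logical(e$literature_pathogenic), PRIOR_LITERATURE,
         ifelse(as.logical(e$dbsnp_low_freq_no_functional), PRIOR_DBSNP,
                PRIOR_DEFAULT))
}

#' Prediction score from in-silico predictor calls
#'
#' One plus the damaging-call count over the three categorical predictors,
#' clamped to `[1, 4]`: no damaging call scores 1, unanimity scores 4.
#'
#' @inheritParams predictor_damage_count
#' @return integer vector in `[1, 4]`.
#' @export
prediction_score <- function(p) {
  pmin(pmax(1L + predictor_damage_count(p), 1L), 4L)
}

#' Odd score from the descriptor profile
#'
#' Count of positive structural/annotation descriptors — conservation (d1),
#' functional domain (d2), structured domain (d4), linear motif (d5) and
#' database annotation (d7) — floored at 1. Predictor agreement (d6) enters
#' the prediction score instead and literature evidence (d8) enters the
#' prior, keeping the three evidence channels independent.
#'
#' @param profile data.frame with columns `d1`..`d8` (see [build_profile()]).
#' @return integer vector in `[1, 5]`.
#' @export
odd_score <- function(profile) {
  profile <- as.data.frame(profile)
  need <- c("d1", "d2", "d4", "d5", "d7")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop_var("profile lacks columns: ",
                             paste(miss, collapse = ", "))
  vals <- as.matrix(profile[, need])
  if (!all(vals %in% c(0L, 1L))) stop_var("descriptors must be 0/1")
  pmax(1L, as.integer(rowSums(vals)))
}

class_from_pct <- function(pct) {
  ifelse(pct >= 90, 5L,
         ifelse(pct >= 50, 4L,
                ifelse(pct >= 25, 3L,
                       ifelse(pct >= 12.5, 2L, 1L))))
}

#' Posterior odds ratio and five-class pathogenicity call
#'
#' Merges the two evidence sub-scores (`merged = prediction + odd`),
#' multiplies the prior odds ratio into a posterior odds ratio, expresses it
#' as a percentage of the maximum merged score (9), and assigns one of five
#' classes: Pathogenic (>= 90), Likely Pathogenic (>= 50), Uncertain
#' (>= 25), Likely Neutral (>= 12.5), Neutral (below). The percentage is
#' rounded half-up to two decimals for reporting; the posterior OR itself is
#' unrounded.
#'
#' A `merged` value may be supplied directly (e.g. when reproducing a
#' published score table); if it disagrees with `prediction + odd` the row is
#' computed from the supplied value and flagged via `score_consistent =
#' FALSE` rather than silently overridden.
#'
#' @param prediction integer vector in `[1, 4]`.
#' @param odd integer vector in `[1, 5]`.
#' @param prior prior odds ratio(s), each one of 19, 1.25, 1.
#' @param merged optional externally supplied merged score.
#' @param variant optional variant labels for the report.
#' @return data.frame (class `bayes_result`) with columns `variant`,
#'   `prediction_score`, `odd_score`, `merged_score`, `prior_or`,
#'   `posterior_or`, `posterior_or_pct`, `meaning`, `class_label`,
#'   `class_index`, `score_consistent`.
#' @export
classify <- function(prediction, odd, prior, merged = NULL, variant = NA) {
  prediction <- as.integer(prediction)
  odd <- as.integer(odd)
  if (any(prediction < 1L | prediction > 4L))
    stop_var("prediction score out of [1,4]")
  if (any(odd < 1L | odd > 5L)) stop_var("odd score out of [1,5]")
  if (!all(prior %in% c(PRIOR_LITERATURE, PRIOR_DBSNP, PRIOR_DEFAULT)))
    stop_var("prior OR must be one of 19, 1.25, 1")
  computed <- prediction + odd
  if (is.null(merged)) merged <- computed
  merged <- as.numeric(merged)
  pct_raw <- merged * prior / MERGED_MAX * 100
  cls <- class_from_pct(pct_raw)
  out <- data.frame(variant = as.character(variant),
                    prediction_score = prediction, odd_score = odd,
                    merged_score = merged, prior_or = prior,
                    posterior_or = merged * prior,
                    posterior_or_pct = round_half_up(pct_raw, 2),
                    meaning = CLASS_ABBREV[cls],
                    class_label = CLASS_LABELS[cls],
                    class_index = cls,
                    score_consistent = merged == computed,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("bayes_result", "data.frame")
  out
}

#' Classify a batch of variants from predictor and evidence tables
#'
#' End-to-end classification: builds the eight-descriptor profile per
#' variant, derives prediction score, odd score and prior, and returns one
#' classification row per variant in input order. The per-variant
#' `descriptor_agreement` (positive descriptors / 8) is reported alongside.
#'
#' @inheritParams build_profile
#' @return a `bayes_result` data.frame (see [classify()]) with an extra
#'   `descriptor_agreement` column.
#' @export
classify_batch <- function(variants, predictors, evidence,
                           agreement_min = 2L) {
  labels <- if (is.data.frame(variants)) variants$variant
            else as.character(variants)
  if (length(labels) == 0L) {
    out <- classify(integer(0), integer(0), numeric(0),
                    variant = character(0))
    out$descriptor_agreement <- numeric(0)
    return(out)
  }
  prof <- build_profile(labels, predictors, evidence, agreement_min)
  evidence <- as.data.frame(evidence)
  e <- evidence[match(labels, evidence$variant), , drop = FALSE]
  predictors <- as.data.frame(predictors)
  p <- predictors[match(labels, predictors$variant), , drop = FALSE]
  out <- classify(prediction = prediction_score(p),
                  odd = odd_score(prof),
                  prior = assign_prior(e),
                  variant = labels)
  out$descriptor_agreement <-
    rowSums(prof[, paste0("d", 1:8)]) / 8
  out
}

#' Compare computed prediction scores against a published score table
#'
#' Recomputes the prediction score of each variant from its categorical
#' predictor calls and compares it with an externally published score,
#' flagging disagreements instead of silently matching them.
#'
#' @param predictors predictor-call table with a `variant` column.
#' @param published data.frame with columns `variant`, `prediction_score`.
#' @return data.frame with `variant`, `computed`, `published`, `consistent`.
#' @export
flag_prediction_discrepancies <- function(predictors, published) {
  predictors <- as.data.frame(predictors)
  published <- as.data.frame(published)
  i <- match(published$variant, predictors$variant)
  if (any(is.na(i)))
    stop_var("no predictor calls for variant ",
             published$variant[which(is.na(i))[1]])
  computed <- prediction_score(predictors[i, , drop = FALSE])
  data.frame(variant = published$variant, computed = computed,
             published = as.integer(published$prediction_score),
             consistent = computed == as.integer(published$prediction_score),
             stringsAsFactors = FALSE)
}
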