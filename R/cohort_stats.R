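#' Two-sample comparison of DXA scores between groups
#'
#' Two-sided two-sample t-test, pooled-variance (classic Student) by
#' default, as used to compare mean T and Z scores between variant carriers
#' and non-carriers; Welch's unequal-variance form is available via
#' `welch = TRUE`. When both groups are constant the test is degenerate:
#' equal means return `t = 0, p = 1` by convention, unequal means
#' `t = +/-Inf, p = 0`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2, finite.
#' @param welch use Welch's correction instead of pooled variance.
#' @return list with `t_statistic`, `p_value`, `df`.
#' @export
group_compare <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_var("each group needs at least 2 observations")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop_var("non-finite values in input")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    if (d == 0) return(list(t_statistic = 0, p_value = 1,
                            df = length(values_a) + length(values_b) - 2L))
    return(list(t_statistic = sign(d) * Inf, p_value = 0,
                df = length(values_a) + length(values_b) - 2L))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

COHORT_NUMERIC <- c("age", "bmd_l", "t_l", "z_l", "bmd_th", "t_th", "z_th")

#' Summarize a cohort table
#'
#' Mean and SD for each numeric measurement (age, lumbar and total-hip BMD
#' and T/Z scores), plus the carrier count and carrier fraction as a percent
#' rounded to one decimal. A single-subject cohort reports SD 0 and is
#' flagged degenerate.
#'
#' @param subjects data.frame with the numeric columns above and a logical
#'   `carrier` column.
#' @return list with `stats` (data.frame `field`, `mean`, `sd`),
#'   `n`, `n_carriers`, `carrier_pct`, `degenerate`.
#' @export
summarize_cohort <- function(subjects) {
  if (nrow(subjects) == 0L) stop_var("empty cohort")
  fields <- intersect(COHORT_NUMERIC, names(subjects))
  degenerate <- nrow(subjects) < 2L
  stats_df <- data.frame(
    field = fields,
    mean = vapply(fields, function(f) mean(subjects[[f]]), numeric(1)),
    sd = vapply(fields, function(f)
      if (degenerate) 0 else stats::sd(subjects[[f]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  n_car <- sum(as.logical(subjects$carrier))
  list(stats = stats_df, n = nrow(subjects), n_carriers = n_car,
       carrier_pct = round_half_up(100 * n_car / nrow(subjects), 1),
       degenerate = degenerate)
}

#' Compare carriers and non-carriers on each DXA score
#'
#' Runs [group_compare()] on each of the four standardized scores (lumbar
#' and total-hip T and Z) between carriers and non-carriers.
#'
#' @inheritParams summarize_cohort
#' @param welch passed to [group_compare()].
#' @return data.frame with `field`, `t_statistic`, `p_value`.
#' @export
compare_carriers <- function(subjects, welch = FALSE) {
  carrier <- as.logical(subjects$carrier)
  fields <- intersect(c("t_l", "z_l", "t_th", "z_th"), names(subjects))
  res <- lapply(fields, function(f) {
    gc <- group_compare(subjects[[f]][carrier], subjects[[f]][!carrier],
                        welch = welch)
    data.frame(field = f, t_statistic = gc$t_statistic,
               p_value = gc$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
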