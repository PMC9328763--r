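# Shared statistical layer: depleted/mock ratio summaries and the tests
# used throughout (one-sample t vs 1, exact Wilcoxon signed-rank vs 1,
# Mann-Whitney), plus the co-IP enrichment filter and the replication-foci
# pattern ratio.

#' Depleted/mock ratios of a pooled metric at matched time points
#'
#' @param depleted_stats,mock_stats Lists of `"combing_stats"` objects (or
#'   data frames with a `time_min` column and the metric column, as returned
#'   by [summarize_experiment()]).
#' @param metric Metric name, e.g. `"replicated_fraction"` or
#'   `"fork_density_per_100kb"`.
#' @return Data frame with columns `time_min`, `depleted`, `mock`, `ratio`.
#' @export
ratio_of_stats <- function(depleted_stats, mock_stats,
                           metric = "fork_density_per_100kb") {
  as_df <- function(x) {
    if (is.data.frame(x)) return(x)
    if (inherits(x, "combing_stats")) x <- list(x)
    do.call(rbind, lapply(x, function(s) {
      data.frame(time_min = s$time_min,
                 value = s[[metric]], stringsAsFactors = FALSE)
    }))
  }
  d <- as_df(depleted_stats); m <- as_df(mock_stats)
  if (!"value" %in% names(d)) d$value <- d[[metric]]
  if (!"value" %in% names(m)) m$value <- m[[metric]]
  if (is.null(d$value) || is.null(m$value)) {
    stop(sprintf("metric '%s' not found", metric), call. = FALSE)
  }
  if (!setequal(d$time_min, m$time_min)) {
    stop("unmatched time points between depleted and mock: ",
         paste(union(setdiff(d$time_min, m$time_min),
                     setdiff(m$time_min, d$time_min)), collapse = ", "),
         call. = FALSE)
  }
  m <- m[match(d$time_min, m$time_min), , drop = FALSE]
  if (any(m$value <= 0)) {
    stop("mock metric is zero at time point(s): ",
         paste(m$time_min[m$value <= 0], collapse = ", "), call. = FALSE)
  }
  data.frame(time_min = d$time_min, depleted = d$value, mock = m$value,
             ratio = d$value / m$value)
}

#' One-sample t test against a theoretical mean of 1
#'
#' Standard two-tailed one-sample t test of a set of depleted/mock ratios
#' against the null ratio 1 (no depletion effect).
#'
#' @param values Numeric vector of ratios, length >= 2, non-zero variance.
#' @return List with `statistic` (t), `df`, `p_two_tailed`, `mean`, `sd`,
#'   `n`.
#' @examples
#' one_sample_t_vs_1(c(1.4, 1.6, 1.8))
#' @export
one_sample_t_vs_1 <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  ht <- stats::t.test(values, mu = 1, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_two_tailed = ht$p.value, mean = mean(values), sd = stats::sd(values),
       n = length(values))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-tailed comparison of two independent samples. The exact null
#' distribution is used when the smaller sample has at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_max Largest min-sample size for the exact branch (default 8).
#' @return List with `statistic` (U of the first sample), `p_two_tailed`,
#'   and `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_two_tailed = ht$p.value,
       exact = exact)
}

#' Wilcoxon signed-rank test against 1
#'
#' Two-tailed test of whether a set of ratios is symmetrically distributed
#' around 1. Values exactly equal to 1 are dropped. The exact null
#' distribution is used for up to `exact_max` remaining values when the
#' absolute deviations are tie-free; otherwise the normal approximation
#' with continuity correction.
#'
#' @param values Numeric ratios; at least one must differ from 1.
#' @param exact_max Largest n for the exact branch (default 25).
#' @return List with `statistic` (V, sum of positive ranks),
#'   `p_two_tailed`, `n_used`, `exact`.
#' @examples
#' wilcoxon_vs_1(c(1.2, 1.3, 1.5, 1.7, 1.8, 2.0))  # p = 2/2^6
#' @export
wilcoxon_vs_1 <- function(values, exact_max = 25L) {
  values <- as.numeric(values)
  values <- values[values != 1]
  if (length(values) == 0L) {
    stop("no values differing from 1", call. = FALSE)
  }
  ties <- anyDuplicated(abs(values - 1)) > 0L
  exact <- length(values) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(values, mu = 1, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_two_tailed = ht$p.value,
       n_used = length(values), exact = exact)
}

#' Bundle ratios with their test into a result record
#'
#' @param label What the ratios measure (e.g. `"fork_density early S"`).
#' @param values Numeric depleted/mock ratios.
#' @param test One of `"one_sample_t_vs_1"`, `"wilcoxon_vs_1"`,
#'   `"mann_whitney"` (the last needs `values2`).
#' @param values2 Second sample for `"mann_whitney"`.
#' @return An object of class `"ratio_result"` with `label`, `values`, `n`,
#'   `mean`, `sd`, `test`, `statistic`, `p_two_tailed`.
#' @export
ratio_result <- function(label, values,
                         test = c("one_sample_t_vs_1", "wilcoxon_vs_1",
                                  "mann_whitney"),
                         values2 = NULL) {
  test <- match.arg(test)
  res <- switch(test,
    one_sample_t_vs_1 = one_sample_t_vs_1(values),
    wilcoxon_vs_1 = wilcoxon_vs_1(values),
    mann_whitney = mann_whitney(values, values2)
  )
  structure(list(label = label, values = values, n = length(values),
                 mean = mean(values), sd = stats::sd(values), test = test,
                 statistic = res$statistic, p_two_tailed = res$p_two_tailed),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> %s\n  n = %d, mean = %.3f, sd = %.3f\n  %s: statistic = %.4g, two-tailed p = %.4g\n",
              x$label, x$n, x$mean, x$sd, x$test, x$statistic, x$p_two_tailed))
  invisible(x)
}

#' Filter co-IP records for fold enrichment
#'
#' Keeps proteins whose target-IP abundance is at least `fold_threshold`
#' times the control-IP abundance. A protein absent from the control
#' (abundance 0) is treated as infinitely enriched and kept if its target
#' abundance reaches `min_target_abundance`.
#'
#' @param records Data frame with columns `protein_id`, `abundance_target`,
#'   `abundance_control` (all abundances >= 0).
#' @param fold_threshold Minimum target/control ratio (default 3).
#' @param min_target_abundance Minimum target abundance for zero-control
#'   proteins (default 0).
#' @return The kept rows, with a `ratio` column added (`Inf` for
#'   zero-control).
#' @export
enrichment_filter <- function(records, fold_threshold = 3,
                              min_target_abundance = 0) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "abundance_target", "abundance_control") %in%
                  names(records)))
  if (any(records$abundance_target < 0) || any(records$abundance_control < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  records$ratio <- ifelse(records$abundance_control > 0,
                          records$abundance_target / records$abundance_control,
                          Inf)
  keep <- ifelse(records$abundance_control > 0,
                 records$ratio >= fold_threshold,
                 records$abundance_target >= min_target_abundance &
                   records$abundance_target > 0)
  records[keep, , drop = FALSE]
}

#' Replication-foci pattern ratio per retina
#'
#' Computes `(n_mid + n_late) / n_early` for each retina (the proportion of
#' nuclei showing mid/late-S-like punctate foci relative to early-S-like
#' homogeneous staining), and compares conditions with [mann_whitney()]
#' when exactly two conditions are present. Retinas with no early-pattern
#' nuclei have an undefined ratio and are excluded with a warning.
#'
#' @param counts Data frame with columns `retina_id`, `condition`,
#'   `n_early`, `n_mid`, `n_late` (non-negative counts).
#' @return List with `ratios` (data frame incl. `ratio` column) and `test`
#'   (a [mann_whitney()] result, or `NULL` if not two conditions).
#' @export
foci_pattern_ratio <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("retina_id", "condition", "n_early", "n_mid", "n_late") %in%
                  names(counts)))
  if (any(counts$n_early < 0 | counts$n_mid < 0 | counts$n_late < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  undef <- counts$n_early == 0
  if (any(undef)) {
    warning(sprintf("excluding %d retina(s) with no early-pattern nuclei: %s",
                    sum(undef),
                    paste(counts$retina_id[undef], collapse = ", ")),
            call. = FALSE)
    counts <- counts[!undef, , drop = FALSE]
  }
  counts$ratio <- (counts$n_mid + counts$n_late) / counts$n_early
  conds <- unique(counts$condition)
  test <- NULL
  if (length(conds) == 2L &&
      all(table(counts$condition) >= 1L)) {
    test <- mann_whitney(counts$ratio[counts$condition == conds[1L]],
                         counts$ratio[counts$condition == conds[2L]])
  }
  list(ratios = counts, test = test)
}
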