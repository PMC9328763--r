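# Bulk DNA synthesis kinetics: label-incorporation series, normalization to
# maximum incorporation, four-bin S-phase partition, and per-bin
# depleted/mock ratio analysis.

#' Incorporation time series for one condition of one experiment
#'
#' @param experiment_id Experiment identifier.
#' @param condition Condition label (e.g. `"mock"`, `"depleted"`).
#' @param times_min Strictly increasing sampling times, min.
#' @param values Incorporation values (cpm fraction, cpm, or ng/ul); must be
#'   non-negative.
#' @return An object of class `"incorporation_series"`.
#' @export
incorporation_series <- function(experiment_id, condition, times_min, values) {
  times_min <- as.numeric(times_min); values <- as.numeric(values)
  if (length(times_min) != length(values) || length(values) == 0L) {
    stop("times_min and values must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(diff(times_min) <= 0)) {
    stop("times_min must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  structure(list(experiment_id = as.character(experiment_id),
                 condition = as.character(condition),
                 times_min = times_min, values = values,
                 normalized_pct = NULL),
            class = "incorporation_series")
}

#' @export
print.incorporation_series <- function(x, ...) {
  cat(sprintf("<incorporation_series> %s / %s, %d time points%s\n",
              x$experiment_id, x$condition, length(x$times_min),
              if (is.null(x$normalized_pct)) "" else " (normalized)"))
  invisible(x)
}

#' Total DNA synthesis from fraction of label incorporated
#'
#' Converts the fraction of a radio- or nucleotide-label pool incorporated
#' into DNA into an absolute synthesis concentration. With a dNTP pool of
#' `dCTP_pool_uM` micromolar (= pmol/ul) and assuming equimolar use of the
#' four nucleotides (hence the factor 4), each incorporated pmol of
#' nucleotide adds 0.330 ng of DNA:
#' `ng/ul = 4 * pool * fraction * 0.330`.
#'
#' @param frac_incorporated Fraction of the labeled pool incorporated, in
#'   `[0, 1]`.
#' @param dCTP_pool_uM Endogenous dCTP pool, micromolar (default 50, the
#'   standard egg-extract value).
#' @return DNA synthesized, ng/ul.
#' @examples
#' total_synthesis_ng_per_ul(0.01, 50)  # 0.66 ng/ul
#' @export
total_synthesis_ng_per_ul <- function(frac_incorporated, dCTP_pool_uM = 50) {
  if (any(frac_incorporated < 0 | frac_incorporated > 1)) {
    stop("'frac_incorporated' must be in [0, 1]", call. = FALSE)
  }
  if (any(dCTP_pool_uM <= 0)) stop("'dCTP_pool_uM' must be > 0", call. = FALSE)
  4 * dCTP_pool_uM * frac_incorporated * 0.330
}

#' Normalize an incorporation series to its maximum
#'
#' Each extract replicates with its own kinetics, so absolute incorporation
#' is not comparable between experiments; scaling every series to its own
#' maximum (= 100%) puts them on a common S-phase progression axis.
#'
#' @param series An [incorporation_series()] with at least one positive
#'   value.
#' @return The series with `normalized_pct` filled in (max = 100).
#' @export
normalize_to_max <- function(series) {
  stopifnot(inherits(series, "incorporation_series"))
  mx <- max(series$values)
  if (mx <= 0) stop("all-zero series cannot be normalized", call. = FALSE)
  series$normalized_pct <- 100 * series$values / mx
  series
}

#' Assign an S-phase bin from percent of maximum incorporation
#'
#' Partitions `[0, 100]` into four bins: `[0, 25]` early, `(25, 50]` mid,
#' `(50, 75]` late, `(75, 100]` very late. Exact boundary values fall in
#' the lower bin.
#'
#' @param pct Percent of maximum incorporation, in `[0, 100]`; vectorized.
#' @return Factor with levels `early`, `mid`, `late`, `very_late`.
#' @examples
#' assign_bin(c(25, 25.1, 100))
#' @export
assign_bin <- function(pct) {
  pct <- as.numeric(pct)
  if (any(is.na(pct)) || any(pct < 0 | pct > 100)) {
    stop("'pct' must be in [0, 100]", call. = FALSE)
  }
  cut(pct, breaks = c(0, 25, 50, 75, 100),
      labels = c("early", "mid", "late", "very_late"),
      include.lowest = TRUE, right = TRUE)
}

.as_series_list <- function(x) {
  if (inherits(x, "incorporation_series")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "incorporation_series")))
  names(x) <- vapply(x, `[[`, character(1), "experiment_id")
  x
}

#' Per-bin depleted/mock incorporation ratios
#'
#' For each experiment, ratios are the depleted over mock incorporation at
#' each shared time point; the S-phase bin of each ratio is assigned from
#' the mock (reference) series' normalized percentage at that time. Each
#' bin is then tested against the null ratio 1 with a two-tailed Wilcoxon
#' signed-rank test ([wilcoxon_vs_1()], exact for small n). Shared time
#' points where the mock value is 0 are skipped with a warning.
#'
#' @param depleted,mock Matched [incorporation_series()] objects or lists
#'   of them; experiments are paired by `experiment_id`.
#' @return An object of class `"binned_ratios"`: list with `ratios` (one
#'   row per experiment x shared time: `experiment_id`, `time_min`,
#'   `mock_pct`, `ratio`, `bin`) and `bins` (per-bin `n`, `mean`, `median`,
#'   `p_two_tailed`).
#' @export
paired_bin_ratios <- function(depleted, mock) {
  dl <- .as_series_list(depleted); ml <- .as_series_list(mock)
  ids <- intersect(names(dl), names(ml))
  if (length(ids) == 0L) stop("no experiments shared between conditions",
                              call. = FALSE)
  rows <- list()
  for (id in ids) {
    d <- dl[[id]]; m <- normalize_to_max(ml[[id]])
    shared <- intersect(d$times_min, m$times_min)
    if (length(shared) == 0L) {
      stop(sprintf("experiment '%s': no shared time points", id), call. = FALSE)
    }
    di <- match(shared, d$times_min); mi <- match(shared, m$times_min)
    mock_zero <- m$values[mi] == 0
    if (any(mock_zero)) {
      warning(sprintf("experiment '%s': skipping %d time point(s) with zero mock incorporation",
                      id, sum(mock_zero)), call. = FALSE)
    }
    keep <- !mock_zero
    if (!any(keep)) next
    rows[[id]] <- data.frame(
      experiment_id = id,
      time_min = shared[keep],
      mock_pct = m$normalized_pct[mi][keep],
      ratio = d$values[di][keep] / m$values[mi][keep],
      stringsAsFactors = FALSE
    )
  }
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  ratios$bin <- assign_bin(ratios$mock_pct)
  bins <- do.call(rbind, lapply(levels(ratios$bin), function(b) {
    v <- ratios$ratio[ratios$bin == b]
    p <- if (length(v) >= 1L && any(v != 1)) wilcoxon_vs_1(v)$p_two_tailed else NA_real_
    data.frame(bin = b, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               p_two_tailed = p, stringsAsFactors = FALSE)
  }))
  structure(list(ratios = ratios, bins = bins), class = "binned_ratios")
}

#' @export
print.binned_ratios <- function(x, ...) {
  cat(sprintf("<binned_ratios> %d ratios from %d experiment(s)\n",
              nrow(x$ratios), length(unique(x$ratios$experiment_id))))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Read incorporation series from CSV
#'
#' Expects columns `experiment_id`, `condition`, `time_min`, `value`; one
#' series per experiment x condition.
#'
#' @param path CSV path.
#' @return List of [incorporation_series()] objects.
#' @export
read_incorporation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "condition", "time_min", "value")
  if (!all(need %in% names(df))) {
    stop("incorporation CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$experiment_id, df$condition, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(sub) {
    sub <- sub[order(sub$time_min), , drop = FALSE]
    incorporation_series(sub$experiment_id[1L], sub$condition[1L],
                         sub$time_min, sub$value)
  })
  names(out) <- NULL
  out
}
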