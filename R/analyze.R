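# DNA combing measurement calculus: labeled tracts -> eyes, forks,
# replicated fraction, fork density, eye lengths (EL), eye-to-eye
# distances (ETED), origins.

#' Analysis configuration for the combing calculus
#'
#' The two 1-kb thresholds mirror the scoring rules of the assay: a labeled
#' tract must be at least `min_eye_kb` to be scored at all, and an
#' unlabeled stretch must be at least `min_gap_kb` to count as a real gap
#' (shorter gaps are treated as staining discontinuities and merged).
#'
#' @param min_eye_kb Minimum tract length to score, kb (default 1).
#' @param min_gap_kb Minimum unlabeled gap to keep two tracts separate, kb
#'   (default 1).
#' @param terminal_tolerance_kb A tract whose end lies within this distance
#'   of a fiber extremity is treated as touching it (default 0: exact
#'   coincidence).
#' @param density_window_kb Window for fork density reporting (default 100,
#'   i.e. forks per 100 kb).
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(min_eye_kb = 1, min_gap_kb = 1,
                            terminal_tolerance_kb = 0,
                            density_window_kb = 100) {
  vals <- c(min_eye_kb, min_gap_kb, terminal_tolerance_kb, density_window_kb)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("analysis_config values must be non-negative", call. = FALSE)
  }
  structure(list(min_eye_kb = min_eye_kb, min_gap_kb = min_gap_kb,
                 terminal_tolerance_kb = terminal_tolerance_kb,
                 density_window_kb = density_window_kb),
            class = "analysis_config")
}

#' Merge sub-threshold gaps between labeled tracts
#'
#' Any two adjacent tracts separated by an unlabeled stretch shorter than
#' `min_gap_kb` are fused into one tract (the gap is deemed a labeling
#' discontinuity, not real unreplicated DNA). Gaps of exactly
#' `min_gap_kb` or more are kept. Idempotent.
#'
#' @param tracts Sorted, disjoint tract matrix (or anything
#'   [fiber()] accepts as tracts).
#' @param min_gap_kb Minimum real gap, kb.
#' @return Tract matrix with sub-threshold gaps absorbed.
#' @examples
#' merge_gaps(rbind(c(10, 12), c(12.5, 13.2)), 1)  # -> [10, 13.2]
#' @export
merge_gaps <- function(tracts, min_gap_kb) {
  m <- .as_tract_matrix(tracts)
  if (nrow(m) == 0L) return(m)
  if (any(m[, 2L] <= m[, 1L])) stop("tract end must exceed start", call. = FALSE)
  if (is.unsorted(m[, 1L], strictly = TRUE) ||
      any(m[-1L, 1L] < m[-nrow(m), 2L])) {
    stop("tracts must be sorted and disjoint", call. = FALSE)
  }
  if (nrow(m) == 1L) return(m)
  gaps <- m[-1L, 1L] - m[-nrow(m), 2L]
  grp <- cumsum(c(1L, as.integer(gaps >= min_gap_kb)))
  out <- t(vapply(split(seq_len(nrow(m)), grp), function(i) {
    c(m[i[1L], 1L], m[i[length(i)], 2L])
  }, numeric(2)))
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Call replication eyes and forks on one fiber
#'
#' Applies the scoring rules in order: (1) sub-threshold gaps are merged
#' ([merge_gaps()]), so merging defines the tract before it is scored;
#' (2) tracts shorter than `min_eye_kb` are discarded as detection noise
#' (terminal ones included); (3) surviving tracts touching exactly one
#' fiber extremity are terminal tracks (the product of a single fork, and
#' not scored as eyes); a tract spanning the whole fiber touches both
#' extremities and carries no on-fiber fork; all remaining interior tracts
#' are replication eyes, each the product of two diverging forks.
#'
#' @param fib A [fiber()].
#' @param config An [analysis_config()].
#' @return An object of class `"eye_calls"` with elements `fiber`, `eyes`,
#'   `terminal_tracks`, `discarded_tracts` (tract matrices) and
#'   `fork_count`.
#' @export
call_eyes <- function(fib, config = analysis_config()) {
  stopifnot(inherits(fib, "fiber"), inherits(config, "analysis_config"))
  eps <- 1e-9
  m <- merge_gaps(fib$tracts, config$min_gap_kb)
  len <- if (nrow(m)) m[, 2L] - m[, 1L] else numeric(0)
  keep <- len >= config$min_eye_kb - eps
  disc <- m[!keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  tol <- config$terminal_tolerance_kb + eps
  touch_l <- m[, 1L] <= tol
  touch_r <- m[, 2L] >= fib$length_kb - tol
  terminal <- touch_l | touch_r
  eyes <- m[!terminal, , drop = FALSE]
  term <- m[terminal, , drop = FALSE]
  one_end <- sum(xor(touch_l[terminal], touch_r[terminal]))
  structure(list(fiber = fib, eyes = eyes, terminal_tracks = term,
                 discarded_tracts = disc,
                 fork_count = 2L * nrow(eyes) + as.integer(one_end),
                 config = config),
            class = "eye_calls")
}

#' @export
print.eye_calls <- function(x, ...) {
  cat(sprintf("<eye_calls '%s'> %d eye(s), %d terminal track(s), %d fork(s), %d discarded\n",
              x$fiber$fiber_id, nrow(x$eyes), nrow(x$terminal_tracks),
              x$fork_count, nrow(x$discarded_tracts)))
  invisible(x)
}

#' Per-fiber replication summary
#'
#' Derives the per-fiber quantities from an [call_eyes()] result:
#' replicated length (eyes plus terminal tracks), eye lengths (EL), origins
#' (eye midpoints), and eye-to-eye distances (ETED) between midpoints of
#' adjacent eyes. Terminal tracks contribute to the replicated length but
#' not to EL, origins, or ETED.
#'
#' @param calls An `"eye_calls"` object.
#' @return An object of class `"fiber_summary"`.
#' @export
fiber_summary <- function(calls) {
  stopifnot(inherits(calls, "eye_calls"))
  eyes <- calls$eyes
  el <- if (nrow(eyes)) unname(eyes[, 2L] - eyes[, 1L]) else numeric(0)
  mids <- if (nrow(eyes)) unname((eyes[, 1L] + eyes[, 2L]) / 2) else numeric(0)
  term_kb <- if (nrow(calls$terminal_tracks)) {
    sum(calls$terminal_tracks[, 2L] - calls$terminal_tracks[, 1L])
  } else 0
  structure(list(fiber_id = calls$fiber$fiber_id,
                 condition = calls$fiber$condition,
                 time_min = calls$fiber$time_min,
                 length_kb = calls$fiber$length_kb,
                 replicated_kb = sum(el) + term_kb,
                 n_eyes = nrow(eyes),
                 eye_lengths_kb = el,
                 eteds_kb = if (length(mids) > 1L) diff(mids) else numeric(0),
                 origins_kb = mids,
                 fork_count = calls$fork_count),
            class = "fiber_summary")
}

#' @export
print.fiber_summary <- function(x, ...) {
  cat(sprintf("<fiber_summary '%s'> L=%.3f kb, replicated %.3f kb (%.1f%%), %d eye(s), %d fork(s)\n",
              x$fiber_id, x$length_kb, x$replicated_kb,
              100 * x$replicated_kb / x$length_kb, x$n_eyes, x$fork_count))
  invisible(x)
}

#' Pooled combing statistics for one condition and time point
#'
#' Pools fibers length-weightedly (not as per-fiber averages): the
#' replicated fraction is the summed replicated DNA over the summed fiber
#' DNA, and the fork density is the total fork count per
#' `density_window_kb` of total DNA. EL and ETED lists are pooled across
#' fibers. Per-fiber values are also kept for scatter plots.
#'
#' @param fibers List of [fiber()] objects, all from the same condition and
#'   time point.
#' @param config An [analysis_config()].
#' @param condition,time_min Optional labels; default taken from the fibers.
#' @return An object of class `"combing_stats"`.
#' @export
aggregate_fibers <- function(fibers, config = analysis_config(),
                             condition = NULL, time_min = NULL) {
  if (inherits(fibers, "fiber")) fibers <- list(fibers)
  if (length(fibers) == 0L) stop("no fibers to aggregate", call. = FALSE)
  stopifnot(all(vapply(fibers, inherits, logical(1), "fiber")))
  conds <- unique(vapply(fibers, `[[`, character(1), "condition"))
  times <- unique(vapply(fibers, `[[`, numeric(1), "time_min"))
  if (length(conds[!is.na(conds)]) > 1L || length(times[!is.na(times)]) > 1L) {
    stop("fibers span multiple conditions or time points; aggregate per group",
         call. = FALSE)
  }
  if (is.null(condition)) condition <- conds[1L]
  if (is.null(time_min)) time_min <- times[1L]
  sums <- lapply(fibers, function(f) fiber_summary(call_eyes(f, config)))
  total_kb <- sum(vapply(sums, `[[`, numeric(1), "length_kb"))
  repl_kb <- sum(vapply(sums, `[[`, numeric(1), "replicated_kb"))
  forks <- sum(vapply(sums, `[[`, numeric(1), "fork_count"))
  per_fiber <- data.frame(
    fiber_id = vapply(sums, `[[`, character(1), "fiber_id"),
    length_kb = vapply(sums, `[[`, numeric(1), "length_kb"),
    replicated_kb = vapply(sums, `[[`, numeric(1), "replicated_kb"),
    n_eyes = vapply(sums, function(s) as.numeric(s$n_eyes), numeric(1)),
    fork_count = vapply(sums, `[[`, numeric(1), "fork_count"),
    stringsAsFactors = FALSE
  )
  per_fiber$replicated_fraction <- per_fiber$replicated_kb / per_fiber$length_kb
  per_fiber$fork_density <- config$density_window_kb * per_fiber$fork_count /
    per_fiber$length_kb
  structure(list(
    condition = condition, time_min = time_min,
    n_fibers = length(fibers),
    total_dna_kb = total_kb,
    replicated_fraction = repl_kb / total_kb,
    fork_density_per_100kb = config$density_window_kb * forks / total_kb,
    total_forks = forks,
    eye_lengths_kb = unlist(lapply(sums, `[[`, "eye_lengths_kb"), use.names = FALSE),
    eteds_kb = unlist(lapply(sums, `[[`, "eteds_kb"), use.names = FALSE),
    pct_unreplicated_fibers = 100 * mean(per_fiber$replicated_kb <= 1e-12),
    per_fiber = per_fiber,
    config = config
  ), class = "combing_stats")
}

#' @export
print.combing_stats <- function(x, ...) {
  cat(sprintf("<combing_stats> %s @ %s min: %d fibers, %.1f kb DNA\n",
              if (is.na(x$condition)) "?" else x$condition,
              if (is.na(x$time_min)) "?" else format(x$time_min),
              x$n_fibers, x$total_dna_kb))
  cat(sprintf("  replicated fraction    %.4f\n", x$replicated_fraction))
  cat(sprintf("  fork density           %.3f / %g kb\n",
              x$fork_density_per_100kb, x$config$density_window_kb))
  cat(sprintf("  unreplicated fibers    %.1f%%\n", x$pct_unreplicated_fibers))
  cat(sprintf("  eyes (EL values)       %d, median EL %.2f kb\n",
              length(x$eye_lengths_kb),
              if (length(x$eye_lengths_kb)) stats::median(x$eye_lengths_kb) else NA))
  cat(sprintf("  ETED values            %d, median %.2f kb\n",
              length(x$eteds_kb),
              if (length(x$eteds_kb)) stats::median(x$eteds_kb) else NA))
  invisible(x)
}

#' Pooled statistics for every condition x time group
#'
#' Convenience wrapper: splits a fiber list (or a `"fiber_experiment"`) by
#' condition and sampling time, aggregates each group with
#' [aggregate_fibers()], and returns one row per group.
#'
#' @param fibers List of [fiber()] objects or a `"fiber_experiment"`.
#' @param config An [analysis_config()].
#' @return Data frame with columns `condition`, `time_min`, `n_fibers`,
#'   `total_dna_kb`, `replicated_fraction`, `fork_density_per_100kb`,
#'   `pct_unreplicated_fibers`; the per-group `"combing_stats"` objects are
#'   attached as attribute `"stats"`.
#' @export
summarize_experiment <- function(fibers, config = analysis_config()) {
  if (inherits(fibers, "fiber_experiment")) fibers <- fibers$fibers
  key <- paste(vapply(fibers, `[[`, character(1), "condition"),
               vapply(fibers, `[[`, numeric(1), "time_min"), sep = "@")
  groups <- split(fibers, key)
  stats_list <- lapply(groups, aggregate_fibers, config = config)
  df <- do.call(rbind, lapply(stats_list, function(s) {
    data.frame(condition = s$condition, time_min = s$time_min,
               n_fibers = s$n_fibers, total_dna_kb = s$total_dna_kb,
               replicated_fraction = s$replicated_fraction,
               fork_density_per_100kb = s$fork_density_per_100kb,
               pct_unreplicated_fibers = s$pct_unreplicated_fibers,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$condition, df$time_min), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "stats") <- stats_list
  df
}
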