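# Fiber tract table I/O.
#
# Dialect: TSV with header
#   condition  time_min  fiber_id  fiber_length_kb  tract_start_kb  tract_end_kb
# one row per tract, 0-based half-open kb coordinates written with 3-decimal
# fixed point. A fiber with no tracts emits a single row with empty tract
# fields (so unreplicated fibers still count toward totals).

.FIBER_COLS <- c("condition", "time_min", "fiber_id", "fiber_length_kb",
                 "tract_start_kb", "tract_end_kb")

#' Write fibers as a tract table
#'
#' @param fibers List of [fiber()] objects or a `"fiber_experiment"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(fibers, path) {
  if (inherits(fibers, "fiber_experiment")) fibers <- fibers$fibers
  if (inherits(fibers, "fiber")) fibers <- list(fibers)
  rows <- lapply(fibers, function(f) {
    n <- nrow(f$tracts)
    if (n == 0L) {
      data.frame(condition = f$condition, time_min = f$time_min,
                 fiber_id = f$fiber_id,
                 fiber_length_kb = sprintf("%.3f", f$length_kb),
                 tract_start_kb = "", tract_end_kb = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(condition = f$condition, time_min = f$time_min,
                 fiber_id = f$fiber_id,
                 fiber_length_kb = sprintf("%.3f", f$length_kb),
                 tract_start_kb = sprintf("%.3f", f$tracts[, 1L]),
                 tract_end_kb = sprintf("%.3f", f$tracts[, 2L]),
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fiber tract table
#'
#' Parses and validates the TSV dialect written by [write_fiber_table()].
#' Malformed rows are rejected with their line number; coordinate errors
#' (end <= start, tract outside the fiber, overlapping tracts) name the
#' offending `fiber_id`.
#'
#' @param path TSV path.
#' @return List of [fiber()] objects.
#' @export
read_fiber_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(.FIBER_COLS, names(df))
  if (length(missing_cols)) {
    stop("fiber table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df$time_min_n <- num(df$time_min)
  df$length_n <- num(df$fiber_length_kb)
  df$start_n <- num(df$tract_start_kb)
  df$end_n <- num(df$tract_end_kb)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- is.na(df$length_n) | df$length_n <= 0 | is.na(df$time_min_n) |
    df$fiber_id == "" |
    (is.na(df$start_n) != is.na(df$end_n)) |
    ((df$tract_start_kb != "") & is.na(df$start_n)) |
    ((df$tract_end_kb != "") & is.na(df$end_n))
  if (any(bad)) {
    stop("malformed fiber table row(s) at line(s): ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  }
  key <- paste(df$condition, df$time_min, df$fiber_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(i) {
    sub <- df[i, , drop = FALSE]
    if (length(unique(sub$length_n)) != 1L) {
      stop(sprintf("fiber '%s': inconsistent fiber_length_kb across rows",
                   sub$fiber_id[1L]), call. = FALSE)
    }
    has_tract <- !is.na(sub$start_n)
    tr <- if (any(has_tract)) cbind(sub$start_n[has_tract], sub$end_n[has_tract]) else NULL
    fiber(sub$fiber_id[1L], sub$length_n[1L], tr,
          condition = sub$condition[1L], time_min = sub$time_min_n[1L])
  })
  names(out) <- NULL
  out
}

#' Write pooled and per-fiber summaries
#'
#' Writes up to four files under `dir`: `pooled_stats.tsv` and
#' `pooled_stats.json` (one record per condition x time), `per_fiber.tsv`
#' (per-fiber replicated fractions, fork counts), and `el_eted.tsv`
#' (long-format pooled EL and ETED values for plotting).
#'
#' @param stats A `"combing_stats"` object or a list of them (e.g. the
#'   `"stats"` attribute of [summarize_experiment()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_summaries <- function(stats, dir) {
  if (inherits(stats, "combing_stats")) stats <- list(stats)
  stopifnot(all(vapply(stats, inherits, logical(1), "combing_stats")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pooled <- do.call(rbind, lapply(stats, function(s) {
    data.frame(condition = s$condition, time_min = s$time_min,
               n_fibers = s$n_fibers, total_dna_kb = s$total_dna_kb,
               replicated_fraction = s$replicated_fraction,
               fork_density_per_100kb = s$fork_density_per_100kb,
               total_forks = s$total_forks,
               pct_unreplicated_fibers = s$pct_unreplicated_fibers,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(pooled, file.path(dir, "pooled_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pooled, file.path(dir, "pooled_stats.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  per_fiber <- do.call(rbind, lapply(stats, function(s) {
    cbind(condition = s$condition, time_min = s$time_min, s$per_fiber,
          stringsAsFactors = FALSE)
  }))
  utils::write.table(per_fiber, file.path(dir, "per_fiber.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  long <- do.call(rbind, lapply(stats, function(s) {
    rbind(
      if (length(s$eye_lengths_kb)) {
        data.frame(condition = s$condition, time_min = s$time_min,
                   metric = "EL", value_kb = s$eye_lengths_kb,
                   stringsAsFactors = FALSE)
      },
      if (length(s$eteds_kb)) {
        data.frame(condition = s$condition, time_min = s$time_min,
                   metric = "ETED", value_kb = s$eteds_kb,
                   stringsAsFactors = FALSE)
      }
    )
  }))
  if (is.null(long)) {
    long <- data.frame(condition = character(0), time_min = numeric(0),
                       metric = character(0), value_kb = numeric(0))
  }
  utils::write.table(long, file.path(dir, "el_eted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Export replication eyes as BED3
#'
#' One BED record per called eye, with the fiber id as chromosome name and
#' 0-based half-open coordinates in bp (kb x 1000, rounded).
#'
#' @param calls_list List of `"eye_calls"` objects (or a single one).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_eyes_bed <- function(calls_list, path) {
  if (inherits(calls_list, "eye_calls")) calls_list <- list(calls_list)
  rows <- lapply(calls_list, function(cl) {
    if (nrow(cl$eyes) == 0L) return(NULL)
    data.frame(chrom = cl$fiber$fiber_id,
               start = as.integer(round(cl$eyes[, 1L] * 1000)),
               end = as.integer(round(cl$eyes[, 2L] * 1000)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
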