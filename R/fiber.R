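# Fiber container: a single combed DNA molecule with labeled tracts.

# normalise any tract input (NULL, 2-col matrix, data.frame, list of pairs)
# to an n x 2 numeric matrix with columns start/end
.as_tract_matrix <- function(tracts) {
  if (is.null(tracts) || length(tracts) == 0L) {
    m <- matrix(numeric(0), ncol = 2L)
  } else if (is.matrix(tracts)) {
    m <- tracts
  } else if (is.data.frame(tracts)) {
    m <- as.matrix(tracts[, 1:2])
  } else if (is.list(tracts)) {
    m <- do.call(rbind, lapply(tracts, function(x) as.numeric(x[1:2])))
  } else if (is.numeric(tracts) && length(tracts) == 2L) {
    m <- matrix(tracts, ncol = 2L)
  } else {
    stop("cannot interpret 'tracts' as a set of intervals", call. = FALSE)
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

# union of intervals: sort, error on strict overlap (if check_overlap),
# merge abutting/overlapping intervals
.merge_intervals <- function(m, check_overlap = FALSE, id = NULL, eps = 1e-9) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  if (check_overlap && any(m[-1L, 1L] < m[-nrow(m), 2L] - eps)) {
    stop(sprintf("overlapping tracts%s",
                 if (is.null(id)) "" else paste0(" in fiber '", id, "'")),
         call. = FALSE)
  }
  out_s <- m[1L, 1L]; out_e <- m[1L, 2L]
  res <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= out_e + eps) {
      out_e <- max(out_e, m[i, 2L])
    } else {
      res <- rbind(res, c(out_s, out_e))
      out_s <- m[i, 1L]; out_e <- m[i, 2L]
    }
  }
  res <- rbind(res, c(out_s, out_e))
  dimnames(res) <- list(NULL, c("start", "end"))
  res
}

# set difference a \ b for two merged interval matrices
.interval_diff <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  pieces <- list()
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1L]; e <- a[i, 2L]
    cur <- s
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1L]; be <- b[j, 2L]
      if (be <= cur || bs >= e) next
      if (bs > cur) pieces[[length(pieces) + 1L]] <- c(cur, bs)
      cur <- max(cur, be)
      if (cur >= e) break
    }
    if (cur < e) pieces[[length(pieces) + 1L]] <- c(cur, e)
  }
  m <- if (length(pieces)) do.call(rbind, pieces) else matrix(numeric(0), ncol = 2L)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Construct a combed DNA fiber
#'
#' A fiber is one combed DNA molecule: a total length in kb plus an ordered
#' set of disjoint half-open labeled tracts `[start, end)` marking replicated
#' (label-incorporating) DNA. Tracts are sorted and abutting tracts are merged
#' on construction; overlapping tracts are an error.
#'
#' @param fiber_id Character identifier.
#' @param length_kb Fiber length in kb (> 0).
#' @param tracts Labeled tracts: a two-column matrix/data frame of start/end
#'   coordinates in kb, a list of length-2 vectors, or `NULL` for an
#'   unlabeled fiber.
#' @param condition Experimental condition, normally `"mock"` or `"depleted"`.
#' @param time_min Sampling time in minutes.
#' @return An object of class `"fiber"`.
#' @examples
#' fiber("f1", 100, list(c(10, 12), c(40, 45)))
#' @export
fiber <- function(fiber_id, length_kb, tracts = NULL,
                  condition = NA_character_, time_min = NA_real_) {
  stopifnot(is.character(fiber_id) || is.factor(fiber_id), length(fiber_id) == 1L)
  fiber_id <- as.character(fiber_id)
  if (!is.numeric(length_kb) || length(length_kb) != 1L || !is.finite(length_kb) ||
      length_kb <= 0) {
    stop(sprintf("fiber '%s': length_kb must be a positive number", fiber_id),
         call. = FALSE)
  }
  m <- .as_tract_matrix(tracts)
  if (nrow(m)) {
    if (any(!is.finite(m))) {
      stop(sprintf("fiber '%s': non-finite tract coordinates", fiber_id),
           call. = FALSE)
    }
    if (any(m[, 2L] <= m[, 1L])) {
      stop(sprintf("fiber '%s': tract end must exceed tract start", fiber_id),
           call. = FALSE)
    }
    if (any(m[, 1L] < 0) || any(m[, 2L] > length_kb + 1e-9)) {
      stop(sprintf("fiber '%s': tract coordinates outside [0, %g]",
                   fiber_id, length_kb), call. = FALSE)
    }
    m <- .merge_intervals(m, check_overlap = TRUE, id = fiber_id)
    m[, 2L] <- pmin(m[, 2L], length_kb)
  }
  structure(
    list(fiber_id = fiber_id, condition = condition, time_min = time_min,
         length_kb = length_kb, tracts = m),
    class = "fiber"
  )
}

#' @export
print.fiber <- function(x, ...) {
  cat(sprintf("<fiber '%s'> %.3f kb, %d tract(s)", x$fiber_id, x$length_kb,
              nrow(x$tracts)))
  if (!is.na(x$condition) || !is.na(x$time_min)) {
    cat(sprintf(" [%s @ %g min]", x$condition, x$time_min))
  }
  cat("\n")
  if (nrow(x$tracts)) {
    cat(paste(sprintf("  [%.3f, %.3f)", x$tracts[, 1L], x$tracts[, 2L]),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# total labeled length of a fiber, kb
.labeled_kb <- function(fib) {
  if (nrow(fib$tracts) == 0L) 0 else sum(fib$tracts[, 2L] - fib$tracts[, 1L])
}
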