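# Independent brute-force oracles and fixture generators.

# Literal, iterative re-implementation of the scoring rules, deliberately
# written in a different style from the package (repeated pairwise scans
# instead of vectorized grouping). Input: plain numeric matrix of tracts.
oracle_eyes <- function(length_kb, tracts, min_eye = 1, min_gap = 1, tol = 0) {
  m <- tracts
  # rule 1: an unlabeled stretch shorter than min_gap is not a real gap
  repeat {
    if (is.null(m) || nrow(m) <= 1L) break
    merged <- FALSE
    for (i in seq_len(nrow(m) - 1L)) {
      if (m[i + 1L, 1L] - m[i, 2L] < min_gap) {
        m[i, 2L] <- m[i + 1L, 2L]
        m <- m[-(i + 1L), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  eyes <- list(); terminal <- list(); discarded <- list(); forks <- 0L
  if (!is.null(m)) for (i in seq_len(nrow(m))) {
    s <- m[i, 1L]; e <- m[i, 2L]
    at_left <- s <= tol + 1e-9
    at_right <- e >= length_kb - tol - 1e-9
    if (e - s < min_eye - 1e-9) {
      # rule 2: sub-threshold label is not significant
      discarded[[length(discarded) + 1L]] <- c(s, e)
    } else if (at_left && at_right) {
      # spans the whole fiber: both forks ran off the ends
      terminal[[length(terminal) + 1L]] <- c(s, e)
    } else if (at_left || at_right) {
      # rule 3: an extremity track is the product of one fork, not an eye
      terminal[[length(terminal) + 1L]] <- c(s, e)
      forks <- forks + 1L
    } else {
      # rule 4: an interior eye is the product of two forks
      eyes[[length(eyes) + 1L]] <- c(s, e)
      forks <- forks + 2L
    }
  }
  to_mat <- function(l) if (length(l)) do.call(rbind, l) else
    matrix(numeric(0), ncol = 2L)
  eyes <- to_mat(eyes); terminal <- to_mat(terminal)
  el <- if (nrow(eyes)) unname(eyes[, 2L] - eyes[, 1L]) else numeric(0)
  mids <- if (nrow(eyes)) unname(rowMeans(eyes)) else numeric(0)
  repl <- sum(el) + (if (nrow(terminal)) sum(terminal[, 2L] - terminal[, 1L]) else 0)
  list(eyes = eyes, terminal = terminal, discarded = to_mat(discarded),
       forks = forks, replicated_kb = repl, el = el, origins = mids,
       eted = if (length(mids) > 1L) diff(mids) else numeric(0))
}

# Random fiber with up to max_tracts disjoint tracts. Coordinates are drawn
# on a 0.25-kb grid so exact-threshold gaps/eyes (1.00 kb) and
# extremity-touching tracts occur with non-trivial probability.
random_fiber <- function(id, max_tracts = 10L) {
  L <- round(stats::runif(1, 30, 150) * 4) / 4
  n <- sample(0:max_tracts, 1L)
  tr <- NULL
  if (n > 0L) {
    pts <- sort(sample(seq(0, L, by = 0.25), min(2L * n, length(seq(0, L, by = 0.25)))))
    if (length(pts) >= 2L) {
      st <- pts[seq(1L, length(pts) - 1L, by = 2L)]
      en <- pts[seq(2L, length(pts), by = 2L)]
      ok <- en > st
      if (any(ok)) tr <- cbind(st[ok], en[ok])
    }
  }
  fiber(id, L, tr)
}

# Exact two-tailed Mann-Whitney p by full enumeration of rank assignments.
enum_mw_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  allr <- seq_len(n + m)
  us <- apply(combs, 2L, function(i) sum(allr[i]) - n * (n + 1) / 2)
  c_mid <- n * m / 2
  mean(abs(us - c_mid) >= abs(u_obs - c_mid) - 1e-9)
}

# Exact two-tailed signed-rank p by full enumeration of sign patterns.
enum_wsr_p <- function(values, mu = 1) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  c_mid <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mean(abs(vs - c_mid) >= abs(v_obs - c_mid) - 1e-9)
}
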