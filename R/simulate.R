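# Stochastic single-fiber replication simulator.
#
# Model: potential ("licensed") origins are a homogeneous Poisson process
# along the fiber. The fiber is partitioned into alternating early- and
# late-firing domains with exponentially distributed lengths. Each origin
# fires at an exponential waiting time with rate I0 (early domains) or
# I0 * s (late domains), where the suppression multiplier s depends on the
# condition: s_mock for mock-depleted extract, s_depleted for the
# target-depleted extract (depletion derepresses late firing, so
# s_mock <= s_depleted). Forks progress bidirectionally at constant speed v;
# an origin overtaken by a fork before its firing time is passively
# replicated and never fires. Labeling is continuous from label_start_min,
# so labeled tracts are the DNA replicated since that time.

#' Simulation parameters for the fiber replication model
#'
#' Bundles and validates every knob of the single-fiber simulator. Defaults
#' describe an embryonic-type S phase: licensed origins every ~3 kb (so that
#' after passive replication, activated origins end up 5-15 kb apart), fork
#' speed 0.5 kb/min, per-origin firing rate 0.01/min, alternating early/late
#' domains of mean length 150 kb covering half the genome each, late firing
#' 10-fold suppressed in mock extract and fully derepressed after depletion.
#'
#' @param n_fibers Fibers per condition per sampling time.
#' @param fiber_length_kb Fiber length, kb.
#' @param lic_spacing_kb Mean spacing of licensed (potential) origins, kb.
#' @param fork_speed_kb_per_min Fork speed v, kb/min.
#' @param firing_rate_per_origin_per_min Per-origin firing rate I0, 1/min.
#' @param cluster_mean_length_kb Mean length of early/late domains, kb.
#' @param late_cluster_fraction Proportion of fiber length in late domains,
#'   in `[0, 1]`.
#' @param suppression_mock Multiplier on I0 in late domains, mock condition,
#'   in `[0, 1]`.
#' @param suppression_depleted Same for the depleted condition; must be
#'   `>= suppression_mock`.
#' @param sample_times_min Strictly increasing sampling times, min.
#' @param label_start_min Time labeling begins (default 0: every replicated
#'   base is labeled, as with label present throughout the reaction).
#' @param seed Integer RNG seed; per-fiber substreams are derived
#'   deterministically from it.
#' @return An object of class `"sim_params"`.
#' @examples
#' sim_params(n_fibers = 10)
#' @export
sim_params <- function(n_fibers = 100,
                       fiber_length_kb = 100,
                       lic_spacing_kb = 3,
                       fork_speed_kb_per_min = 0.5,
                       firing_rate_per_origin_per_min = 0.01,
                       cluster_mean_length_kb = 150,
                       late_cluster_fraction = 0.5,
                       suppression_mock = 0.1,
                       suppression_depleted = 1.0,
                       sample_times_min = c(10, 20, 30, 40),
                       label_start_min = 0,
                       seed = 1L) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
    }
  }
  chk_pos(n_fibers, "n_fibers"); chk_pos(fiber_length_kb, "fiber_length_kb")
  chk_pos(lic_spacing_kb, "lic_spacing_kb")
  chk_pos(fork_speed_kb_per_min, "fork_speed_kb_per_min")
  chk_pos(firing_rate_per_origin_per_min, "firing_rate_per_origin_per_min")
  chk_pos(cluster_mean_length_kb, "cluster_mean_length_kb")
  if (late_cluster_fraction < 0 || late_cluster_fraction > 1) {
    stop("'late_cluster_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (suppression_mock < 0 || suppression_mock > 1 ||
      suppression_depleted < 0 || suppression_depleted > 1) {
    stop("suppression multipliers must be in [0, 1]", call. = FALSE)
  }
  if (suppression_mock > suppression_depleted) {
    stop("'suppression_mock' must be <= 'suppression_depleted' ",
         "(depletion derepresses late firing)", call. = FALSE)
  }
  if (length(sample_times_min) < 1L || any(sample_times_min <= 0) ||
      any(diff(sample_times_min) <= 0)) {
    stop("'sample_times_min' must be positive and strictly increasing",
         call. = FALSE)
  }
  if (label_start_min < 0) stop("'label_start_min' must be >= 0", call. = FALSE)
  structure(
    list(n_fibers = as.integer(n_fibers),
         fiber_length_kb = fiber_length_kb,
         lic_spacing_kb = lic_spacing_kb,
         fork_speed_kb_per_min = fork_speed_kb_per_min,
         firing_rate_per_origin_per_min = firing_rate_per_origin_per_min,
         cluster_mean_length_kb = cluster_mean_length_kb,
         late_cluster_fraction = late_cluster_fraction,
         suppression_mock = suppression_mock,
         suppression_depleted = suppression_depleted,
         sample_times_min = as.numeric(sample_times_min),
         label_start_min = label_start_min,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-32s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# alternating early/late domain breaks covering [0, length_kb].
# Mean domain lengths are scaled so the long-run late fraction equals
# late_cluster_fraction while the average domain length stays at
# cluster_mean_length_kb.
.draw_domains <- function(length_kb, params) {
  f <- params$late_cluster_fraction
  if (f <= 0) {
    return(data.frame(start = 0, end = length_kb, class = "early"))
  }
  if (f >= 1) {
    return(data.frame(start = 0, end = length_kb, class = "late"))
  }
  m <- params$cluster_mean_length_kb
  mean_late <- 2 * f * m
  mean_early <- 2 * (1 - f) * m
  cls <- if (stats::runif(1) < f) "late" else "early"
  starts <- numeric(0); ends <- numeric(0); classes <- character(0)
  pos <- 0
  while (pos < length_kb) {
    len <- stats::rexp(1, rate = 1 / if (cls == "late") mean_late else mean_early)
    starts <- c(starts, pos)
    ends <- c(ends, min(pos + len, length_kb))
    classes <- c(classes, cls)
    pos <- pos + len
    cls <- if (cls == "late") "early" else "late"
  }
  data.frame(start = starts, end = ends, class = classes)
}

#' Place licensed origins along a fiber
#'
#' Draws potential (licensed) origin positions as a homogeneous Poisson
#' process with mean spacing `lic_spacing_kb`, and labels each with the
#' firing class (`"early"` or `"late"`) of the alternating cluster domain
#' that contains it. Uses the current RNG stream; call [set.seed()] for
#' reproducibility, or use [simulate_fiber()] which manages substreams.
#'
#' @param length_kb Fiber length, kb (> 0).
#' @param params A [sim_params()] object.
#' @return A data frame with columns `position_kb` (strictly increasing) and
#'   `cluster_class`.
#' @export
place_origins <- function(length_kb, params) {
  if (!is.numeric(length_kb) || length(length_kb) != 1L || length_kb <= 0) {
    stop("'length_kb' must be a single positive number", call. = FALSE)
  }
  stopifnot(inherits(params, "sim_params"))
  n <- stats::rpois(1L, length_kb / params$lic_spacing_kb)
  pos <- sort(stats::runif(n, 0, length_kb))
  dom <- .draw_domains(length_kb, params)
  idx <- findInterval(pos, dom$start)
  data.frame(position_kb = pos,
             cluster_class = if (n) dom$class[idx] else character(0))
}

#' Replicated tracts from a set of firing events
#'
#' Deterministic geometry core of the simulator. Each origin that actually
#' fires at time `t_f <= t` contributes a replication eye
#' `[x - v (t - t_f), x + v (t - t_f)]` clipped to the fiber; the union of
#' all eyes is returned. An origin whose position is already inside
#' replicated DNA at its scheduled firing time is passively replicated and
#' fires no forks of its own (with a common fork speed this never changes
#' the replicated set, only which origins count as fired).
#'
#' @param events A data frame (or 2-column matrix) with columns
#'   `position_kb` and `fire_time_min`; `fire_time_min` may be `Inf` for
#'   origins that never fire.
#' @param v Fork speed, kb/min (> 0).
#' @param t Observation time, min (>= 0).
#' @param length_kb Fiber length, kb.
#' @return A merged tract matrix (columns `start`, `end`).
#' @examples
#' replicate_from_events(data.frame(position_kb = 50, fire_time_min = 10),
#'                       v = 0.5, t = 20, length_kb = 100)
#' @export
replicate_from_events <- function(events, v, t, length_kb) {
  if (!is.numeric(v) || v <= 0) stop("'v' must be > 0", call. = FALSE)
  if (!is.numeric(t) || t < 0) stop("'t' must be >= 0", call. = FALSE)
  if (is.matrix(events)) {
    events <- data.frame(position_kb = events[, 1L], fire_time_min = events[, 2L])
  }
  if (is.null(events) || nrow(events) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  ev <- events[events$fire_time_min <= t, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  ev <- ev[order(ev$fire_time_min), , drop = FALSE]
  act_x <- numeric(0); act_t <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    x <- ev$position_kb[i]; tf <- ev$fire_time_min[i]
    covered <- any(abs(x - act_x) <= v * (tf - act_t) + 1e-12)
    if (!covered) {
      act_x <- c(act_x, x); act_t <- c(act_t, tf)
    }
  }
  eyes <- cbind(pmax(0, act_x - v * (t - act_t)),
                pmin(length_kb, act_x + v * (t - act_t)))
  eyes <- eyes[eyes[, 2L] > eyes[, 1L], , drop = FALSE]
  if (nrow(eyes) == 0L) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  .merge_intervals(eyes)
}

# deterministic substream seed from (seed, condition, time index, fiber index)
.substream_seed <- function(seed, condition, time_index, fiber_index) {
  cond_code <- match(condition, c("mock", "depleted"))
  if (is.na(cond_code)) stop("condition must be 'mock' or 'depleted'", call. = FALSE)
  as.integer(((abs(as.double(seed)) %% 1e6) * 2011 +
                cond_code * 700001 +
                time_index * 90017 +
                fiber_index * 7919) %% 2147483629)
}

.time_index <- function(params, time_min) {
  i <- match(time_min, params$sample_times_min)
  if (is.na(i)) i <- 1000L + (round(time_min * 64) %% 100000L)
  i
}

#' Simulate one fiber
#'
#' Draws licensed origins and firing times for the requested condition, then
#' replays fork progression to `time_min` with passive-replication
#' bookkeeping, returning the labeled fiber. Fully deterministic given
#' `params$seed`, the condition, the time, and `fiber_index`; the session
#' RNG state is left untouched.
#'
#' @param params A [sim_params()] object.
#' @param condition `"mock"` or `"depleted"`.
#' @param time_min Sampling time, min.
#' @param fiber_index Index used to derive the per-fiber RNG substream.
#' @return A [fiber()] object.
#' @export
simulate_fiber <- function(params, condition, time_min, fiber_index = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(time_min) || time_min < 0) stop("'time_min' must be >= 0",
                                                  call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(.substream_seed(params$seed, condition,
                           .time_index(params, time_min), fiber_index))
  L <- params$fiber_length_kb
  org <- place_origins(L, params)
  s <- if (condition == "mock") params$suppression_mock else params$suppression_depleted
  i0 <- params$firing_rate_per_origin_per_min
  rate <- ifelse(org$cluster_class == "late", i0 * s, i0)
  fire <- ifelse(rate > 0, stats::rexp(nrow(org), rate = pmax(rate, 1e-300)), Inf)
  # rexp is drawn even for rate 0 origins via pmax, then overridden to Inf,
  # keeping the substream consumption independent of s
  ev <- data.frame(position_kb = org$position_kb, fire_time_min = fire)
  tracts <- replicate_from_events(ev, params$fork_speed_kb_per_min, time_min, L)
  if (params$label_start_min > 0) {
    pre <- replicate_from_events(ev, params$fork_speed_kb_per_min,
                                 min(params$label_start_min, time_min), L)
    tracts <- .interval_diff(tracts, pre)
  }
  fiber(sprintf("%s_t%g_f%d", condition, time_min, fiber_index),
        L, tracts, condition = condition, time_min = time_min)
}

#' Simulate a full two-condition combing experiment
#'
#' Generates `n_fibers` fibers for each condition (mock, depleted) at every
#' sampling time in `params$sample_times_min`, together with a manifest
#' recording all parameters.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `"fiber_experiment"`: a list with elements
#'   `fibers` (list of [fiber()] objects) and `manifest` (parameter list).
#' @examples
#' ex <- simulate_experiment(sim_params(n_fibers = 5,
#'                                      sample_times_min = c(20, 40)))
#' length(ex$fibers)  # 5 fibers x 2 conditions x 2 times
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  fibers <- list()
  k <- 0L
  for (cond in c("mock", "depleted")) {
    for (tm in params$sample_times_min) {
      for (i in seq_len(params$n_fibers)) {
        k <- k + 1L
        fibers[[k]] <- simulate_fiber(params, cond, tm, fiber_index = i)
      }
    }
  }
  structure(list(fibers = fibers,
                 manifest = c(unclass(params),
                              list(generator = "replidyn::simulate_experiment"))),
            class = "fiber_experiment")
}

#' @export
print.fiber_experiment <- function(x, ...) {
  cat(sprintf("<fiber_experiment> %d fibers (%d per condition x time)\n",
              length(x$fibers), x$manifest$n_fibers))
  invisible(x)
}

#' Write a simulation manifest
#'
#' Records every simulation parameter (including the seed) as YAML so a
#' dataset can be regenerated exactly.
#'
#' @param experiment A `"fiber_experiment"` from [simulate_experiment()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(experiment, path) {
  stopifnot(inherits(experiment, "fiber_experiment"))
  yaml::write_yaml(experiment$manifest, path)
  invisible(path)
}
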