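# Closed-form 1-D nucleation-growth (KJMA) references used to validate the
# stochastic simulator in its homogeneous regime.

#' KJMA replicated fraction
#'
#' Closed-form replicated fraction for a homogeneous, infinite fiber with
#' constant nucleation rate `I` (initiations per kb per min) and constant
#' bidirectional fork speed `v`: `f(t) = 1 - exp(-I v t^2)`.
#'
#' In the simulator this regime corresponds to `late_cluster_fraction = 0`
#' with licensed-origin spacing much smaller than typical eye lengths, and
#' `I = I0 / lic_spacing_kb`.
#'
#' @param I_kb_min Nucleation rate, initiations/kb/min (>= 0).
#' @param v Fork speed, kb/min (>= 0).
#' @param t Time, min (>= 0); may be a vector.
#' @return Replicated fraction(s) in `[0, 1)`.
#' @examples
#' kjma_fraction(0.001, 0.5, 20)  # 1 - exp(-0.2)
#' @export
kjma_fraction <- function(I_kb_min, v, t) {
  if (any(I_kb_min < 0) || any(v < 0) || any(t < 0)) {
    stop("kjma_fraction: arguments must be non-negative", call. = FALSE)
  }
  1 - exp(-I_kb_min * v * t^2)
}

#' KJMA fork density
#'
#' Closed-form density of active forks (per kb) in the same homogeneous
#' regime as [kjma_fraction()]: `rho(t) = 2 I t exp(-I v t^2)`. The density
#' rises as origins fire, peaks at `t* = 1 / sqrt(2 I v)`, and decays as
#' converging forks merge.
#'
#' @inheritParams kjma_fraction
#' @return Fork density(ies), forks/kb (multiply by 100 for forks/100 kb).
#' @examples
#' 100 * kjma_fork_density(0.001, 0.5, 20)  # forks per 100 kb
#' @export
kjma_fork_density <- function(I_kb_min, v, t) {
  if (any(I_kb_min < 0) || any(v < 0) || any(t < 0)) {
    stop("kjma_fork_density: arguments must be non-negative", call. = FALSE)
  }
  2 * I_kb_min * t * exp(-I_kb_min * v * t^2)
}
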