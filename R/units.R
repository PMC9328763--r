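# Concentration unit helpers.

#' Approximate molecular weight of Xenopus Yap, kDa
#'
#' Used to interconvert the mass and molar concentrations of Yap in egg
#' extract (11 ng/ul of a ~65 kDa protein is ~169 nM).
#' @export
YAP_MW_KDA <- 65

#' Convert a protein mass concentration to molar
#'
#' `nM = ng/ul * 1e6 / (MW in Da)`: 1 ng/ul equals 1 mg/L, and dividing by
#' the molecular weight in g/mol gives mmol/L * 1e-3, i.e. `1e6 / MW` nM.
#'
#' @param ng_per_ul Mass concentration, ng/ul.
#' @param mw_kda Molecular weight, kDa.
#' @return Molar concentration, nM.
#' @examples
#' protein_mass_to_molar(11, YAP_MW_KDA)  # ~169 nM
#' @export
protein_mass_to_molar <- function(ng_per_ul, mw_kda) {
  if (any(ng_per_ul < 0)) stop("'ng_per_ul' must be >= 0", call. = FALSE)
  if (any(mw_kda <= 0)) stop("'mw_kda' must be > 0", call. = FALSE)
  ng_per_ul * 1e6 / (mw_kda * 1000)
}

#' Convert a protein molar concentration to mass
#'
#' Inverse of [protein_mass_to_molar()].
#'
#' @param nM Molar concentration, nM.
#' @param mw_kda Molecular weight, kDa.
#' @return Mass concentration, ng/ul.
#' @export
protein_molar_to_mass <- function(nM, mw_kda) {
  if (any(nM < 0)) stop("'nM' must be >= 0", call. = FALSE)
  if (any(mw_kda <= 0)) stop("'mw_kda' must be > 0", call. = FALSE)
  nM * mw_kda * 1000 / 1e6
}
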