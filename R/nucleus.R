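# Nucleus fluorescence quantification: corrected total fluorescence (CTF)
# per nucleus, percent positive nuclei, depleted/mock fold change, and a
# table-level synthetic generator.

.check_nucleus_df <- function(nuclei) {
  need <- c("nucleus_id", "slide_id", "condition", "integrated_density", "area")
  if (!is.data.frame(nuclei) || !all(need %in% names(nuclei))) {
    stop("nucleus table must have columns: ", paste(need, collapse = ", "),
         " (plus optionally experiment_id)", call. = FALSE)
  }
  if (any(nuclei$area <= 0)) stop("nucleus area must be > 0", call. = FALSE)
  if (any(nuclei$integrated_density < 0)) {
    stop("integrated_density must be >= 0", call. = FALSE)
  }
  invisible(nuclei)
}

#' Corrected total fluorescence per nucleus
#'
#' `CTF = integrated density - area x mean background fluorescence`, with
#' one background value per slide. Negative CTFs can occur for dim nuclei
#' and are kept (truncating them would bias condition means) but flagged.
#'
#' @param nuclei Data frame with columns `nucleus_id`, `slide_id`,
#'   `condition`, `integrated_density`, `area` (and optionally
#'   `experiment_id`).
#' @param backgrounds Data frame with columns `slide_id`,
#'   `mean_background` (AU per area unit, >= 0).
#' @return `nuclei` with `ctf` and `ctf_negative` columns added.
#' @examples
#' ctf(data.frame(nucleus_id = "n1", slide_id = "s1", condition = "mock",
#'                integrated_density = 5000, area = 200),
#'     data.frame(slide_id = "s1", mean_background = 10))
#' @export
ctf <- function(nuclei, backgrounds) {
  .check_nucleus_df(nuclei)
  stopifnot(is.data.frame(backgrounds),
            all(c("slide_id", "mean_background") %in% names(backgrounds)))
  if (any(backgrounds$mean_background < 0)) {
    stop("mean_background must be >= 0", call. = FALSE)
  }
  idx <- match(nuclei$slide_id, backgrounds$slide_id)
  if (anyNA(idx)) {
    stop("no background for slide(s): ",
         paste(unique(nuclei$slide_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  bg <- backgrounds$mean_background[idx]
  nuclei$ctf <- nuclei$integrated_density - nuclei$area * bg
  nuclei$ctf_negative <- nuclei$ctf < 0
  nuclei
}

#' Percent of nuclei above a CTF threshold
#'
#' @inheritParams ctf
#' @param threshold Positivity threshold on CTF (default 0: any signal
#'   above background counts as positive).
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(nuclei, backgrounds, threshold = 0) {
  if (nrow(nuclei) == 0L) stop("no nucleus records", call. = FALSE)
  x <- ctf(nuclei, backgrounds)
  100 * mean(x$ctf > threshold)
}

#' Depleted/mock CTF fold change per experiment
#'
#' For each experiment, the fold change is the mean CTF of depleted nuclei
#' over the mean CTF of mock nuclei. Across experiments the fold changes
#' are tested against 1 with a two-tailed one-sample t test
#' ([one_sample_t_vs_1()]) when at least two experiments are available.
#'
#' @inheritParams ctf
#' @param mock,depleted Condition labels (defaults `"mock"`,
#'   `"depleted"`).
#' @return List with `ratios` (data frame `experiment_id`, `mean_mock`,
#'   `mean_depleted`, `ratio`) and `test` (a [ratio_result()] or `NULL`).
#' @export
condition_fold_change <- function(nuclei, backgrounds,
                                  mock = "mock", depleted = "depleted") {
  x <- ctf(nuclei, backgrounds)
  if (is.null(x$experiment_id)) x$experiment_id <- "exp1"
  rows <- lapply(split(x, x$experiment_id), function(sub) {
    mm <- mean(sub$ctf[sub$condition == mock])
    md <- mean(sub$ctf[sub$condition == depleted])
    if (is.nan(mm) || is.nan(md)) {
      stop(sprintf("experiment '%s': both conditions must be present",
                   sub$experiment_id[1L]), call. = FALSE)
    }
    if (mm <= 0) {
      stop(sprintf("experiment '%s': mock mean CTF is not positive",
                   sub$experiment_id[1L]), call. = FALSE)
    }
    data.frame(experiment_id = sub$experiment_id[1L], mean_mock = mm,
               mean_depleted = md, ratio = md / mm, stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  test <- NULL
  if (nrow(ratios) >= 2L && stats::sd(ratios$ratio) > 0) {
    test <- ratio_result("CTF fold change depleted/mock", ratios$ratio,
                         test = "one_sample_t_vs_1")
  }
  list(ratios = ratios, test = test)
}

#' Simulate a nucleus measurement table
#'
#' Synthetic stand-in for ROI measurement tables: per-nucleus signal is
#' log-normal, the condition effect is a multiplicative factor on the
#' depleted signal, areas are log-normal, and each slide contributes a
#' uniform mean background that is added into the integrated density (so
#' [ctf()] recovers the signal). One slide per condition.
#'
#' @param n_nuclei Nuclei per condition (>= 1).
#' @param condition_effect Multiplicative depleted/mock signal ratio.
#' @param noise_params List with `meanlog`, `sdlog` (signal), `area_meanlog`,
#'   `area_sdlog`, `background` (AU per area unit).
#' @param seed Integer seed; same seed gives an identical table.
#' @param experiment_id Experiment label.
#' @return List with `nuclei` and `backgrounds` data frames, ready for
#'   [ctf()] / [condition_fold_change()].
#' @export
simulate_nucleus_table <- function(n_nuclei, condition_effect = 1.5,
                                   noise_params = list(meanlog = 8, sdlog = 0.4,
                                                       area_meanlog = 5.3,
                                                       area_sdlog = 0.1,
                                                       background = 10),
                                   seed = 1L, experiment_id = "exp1") {
  if (n_nuclei < 1L) stop("'n_nuclei' must be >= 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  np <- noise_params
  mk <- function(cond, slide, mult) {
    signal <- mult * stats::rlnorm(n_nuclei, np$meanlog, np$sdlog)
    area <- stats::rlnorm(n_nuclei, np$area_meanlog, np$area_sdlog)
    data.frame(nucleus_id = sprintf("%s_%s_%d", experiment_id, cond,
                                    seq_len(n_nuclei)),
               experiment_id = experiment_id,
               slide_id = slide, condition = cond,
               integrated_density = signal + area * np$background,
               area = area, stringsAsFactors = FALSE)
  }
  nuclei <- rbind(mk("mock", paste0(experiment_id, "_s1"), 1),
                  mk("depleted", paste0(experiment_id, "_s2"), condition_effect))
  backgrounds <- data.frame(
    slide_id = paste0(experiment_id, c("_s1", "_s2")),
    mean_background = np$background, stringsAsFactors = FALSE
  )
  list(nuclei = nuclei, backgrounds = backgrounds)
}
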