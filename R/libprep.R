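# Sequencing-library pooling arithmetic: molarity from fragment-analyzer
# summaries, median split, dilution-to-median, sub-nanomolar discard, and an
# equimolar pooling plan.

#' Library molarity from a fragment-analyzer summary
#'
#' `molarity_nM = conc_ng_per_ul * 1e6 / (avg_fragment_bp * 650)`, using the
#' standard 650 g/mol per base pair of double-stranded DNA. The average
#' fragment size is taken from the 200-1,500 bp analysis window.
#'
#' @param conc_ng_per_ul Concentration in ng/uL (>= 0).
#' @param avg_fragment_bp Average fragment size in bp (> 0).
#' @return Molarity in nM (vectorized).
#' @examples
#' molarity_from_profile(1, 1000)  # ~1.538 nM
#' @export
molarity_from_profile <- function(conc_ng_per_ul, avg_fragment_bp) {
  if (any(conc_ng_per_ul < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(avg_fragment_bp <= 0)) stop("fragment size must be > 0", call. = FALSE)
  conc_ng_per_ul * 1e6 / (avg_fragment_bp * 650)
}

#' Equimolar pooling plan
#'
#' Samples below `min_molarity_nM` (default 1 nM) are discarded. The cohort
#' median molarity is computed over the kept samples; samples strictly above
#' it are diluted down to the median (samples at or below the median are used
#' neat, the documented tie rule). Each kept sample then contributes
#' `target_fmol` femtomoles; since 1 nM = 1 fmol/uL, the transfer volume is
#' `target_fmol / working_molarity_nM` microliters. `target_fmol` defaults to
#' the median molarity x 1 uL.
#'
#' @param samples data.frame with `sample_id`, `conc_ng_per_ul`,
#'   `avg_fragment_bp` (or a precomputed `molarity_nM` column).
#' @param target_fmol Femtomoles per sample in the pool (default: median nM).
#' @param min_molarity_nM Discard threshold (default 1).
#' @return List of class `ctc_pooling_plan`: `plan` (per-sample `molarity_nM`,
#'   `group` above/below median, `keep`, `dilution_factor`,
#'   `working_molarity_nM`, `volume_ul`, `discard_reason`),
#'   `median_molarity_nM`, `target_fmol`.
#' @export
plan_pooling <- function(samples, target_fmol = NULL, min_molarity_nM = 1.0) {
  s <- as.data.frame(samples)
  if (is.null(s$molarity_nM))
    s$molarity_nM <- molarity_from_profile(s$conc_ng_per_ul, s$avg_fragment_bp)
  s$keep <- s$molarity_nM >= min_molarity_nM
  if (!any(s$keep))
    stop("all samples below ", min_molarity_nM, " nM", call. = FALSE)
  med <- stats::median(s$molarity_nM[s$keep])
  if (is.null(target_fmol)) target_fmol <- med
  s$group <- ifelse(s$molarity_nM > med, "above_median", "below_median")
  s$dilution_factor <- ifelse(s$keep & s$group == "above_median",
                              s$molarity_nM / med, 1)
  s$working_molarity_nM <- ifelse(s$keep, s$molarity_nM / s$dilution_factor,
                                  NA_real_)
  s$volume_ul <- ifelse(s$keep, target_fmol / s$working_molarity_nM, NA_real_)
  s$discard_reason <- ifelse(s$keep, "",
                             sprintf("molarity %.3g nM < %.3g nM",
                                     s$molarity_nM, min_molarity_nM))
  structure(list(plan = s, median_molarity_nM = med, target_fmol = target_fmol),
            class = "ctc_pooling_plan")
}
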