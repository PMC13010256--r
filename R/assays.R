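#' Delta-delta-Ct relative expression
#'
#' Standard two-step relative quantification of qPCR data with an assumed
#' amplification efficiency of 2 (perfect doubling per cycle, no
#' efficiency correction): per sample,
#' \deqn{\Delta Ct = Ct_{target} - Ct_{reference}, \quad
#'   \Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator},
#'   \quad fold = 2^{-\Delta\Delta Ct}}
#' where the calibrator mean is taken over the samples of
#' `calibrator_group` (typically the vehicle-treated group), so the
#' calibrator group's pooled mean fold change is exactly 1.
#'
#' @param measurements Tibble with columns `sample_id`, `group`,
#'   `target_ct`, `reference_ct` (e.g. from [read_ct_table()] or
#'   [simulate_qpcr()]). Ct values far outside 5--40 cycles trigger a
#'   warning.
#' @param calibrator_group Group label whose mean \eqn{\Delta}Ct anchors
#'   the scale (default `"vehicle"`).
#' @return The input tibble with added columns `delta_ct`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
ddct_relative_expression <- function(measurements,
                                     calibrator_group = "vehicle") {
  required <- c("sample_id", "group", "target_ct", "reference_ct")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurements lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_ref <- is.na(measurements$reference_ct) |
    !is.finite(measurements$reference_ct)
  if (any(bad_ref)) {
    stop("missing reference Ct for sample(s): ",
         paste(measurements$sample_id[bad_ref], collapse = ", "),
         call. = FALSE)
  }
  bad_tgt <- is.na(measurements$target_ct) |
    !is.finite(measurements$target_ct)
  if (any(bad_tgt)) {
    stop("missing target Ct for sample(s): ",
         paste(measurements$sample_id[bad_tgt], collapse = ", "),
         call. = FALSE)
  }
  cts <- c(measurements$target_ct, measurements$reference_ct)
  if (any(cts < 5 | cts > 40)) {
    warning("Ct value(s) outside the typical 5-40 cycle range",
            call. = FALSE)
  }
  if (!calibrator_group %in% measurements$group) {
    stop("calibrator group '", calibrator_group, "' is empty",
         call. = FALSE)
  }
  delta_ct <- measurements$target_ct - measurements$reference_ct
  calib_mean <- mean(delta_ct[measurements$group == calibrator_group])
  ddct <- delta_ct - calib_mean
  out <- measurements
  out$delta_ct <- delta_ct
  out$delta_delta_ct <- ddct
  out$fold_change <- 2^(-ddct)
  out
}

#' Percent fluorescence indicator displacement
#'
#' \deqn{\%FID = 100 - 100 \cdot F / F_0}
#' where `F` is the fluorescence at a given ligand concentration and `F0`
#' the ligand-free baseline. 0% means no displacement, 100% complete
#' displacement. Values below 0 (F above F0, i.e. fluorescence
#' enhancement) are reported as computed, not clipped, since they signal a
#' qualitatively different binding mode.
#'
#' @param F_signal Fluorescence value(s), >= 0.
#' @param F0 Baseline fluorescence, > 0 (recycled).
#' @return Numeric vector of %FID values.
#' @examples
#' percent_fid(c(100, 50, 0), 100)  # 0, 50, 100
#' @export
percent_fid <- function(F_signal, F0) {
  if (!is.numeric(F_signal) || !is.numeric(F0)) {
    stop("F and F0 must be numeric", call. = FALSE)
  }
  n <- max(length(F_signal), length(F0))
  f <- rep_len(F_signal, n)
  f0 <- rep_len(F0, n)
  if (any(!is.finite(f0) | f0 <= 0)) {
    stop("F0 must be positive and finite", call. = FALSE)
  }
  if (any(!is.na(f) & (f < 0 | !is.finite(f)))) {
    stop("F must be nonnegative and finite", call. = FALSE)
  }
  100 - 100 * f / f0
}
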