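#' Percent spliced in (PSI) from inclusion and exclusion signals
#'
#' PSI is the percentage of transcripts that include a cassette exon,
#' computed from any pair of nonnegative inclusion/exclusion signals
#' (junction read counts, capillary-electrophoresis RFU values, ...):
#' \deqn{PSI = 100 \cdot \frac{inclusion}{inclusion + exclusion}}
#'
#' The ratio form makes PSI invariant to any common positive rescaling of
#' the two channels, so RFU-based and count-based PSIs are directly
#' comparable.
#'
#' @param inclusion_signal Numeric vector of nonnegative inclusion signals.
#' @param exclusion_signal Numeric vector of nonnegative exclusion signals,
#'   recycled against `inclusion_signal`.
#' @return Numeric vector of PSI values in `[0, 100]`.
#' @examples
#' compute_psi(30, 10)  # 75
#' compute_psi(c(5, 0), c(5, 7))  # 50, 0
#' @export
compute_psi <- function(inclusion_signal, exclusion_signal) {
  if (!is.numeric(inclusion_signal) || !is.numeric(exclusion_signal)) {
    stop("inclusion and exclusion signals must be numeric", call. = FALSE)
  }
  n <- max(length(inclusion_signal), length(exclusion_signal))
  inc <- rep_len(inclusion_signal, n)
  exc <- rep_len(exclusion_signal, n)
  if (any(!is.finite(inc) | !is.finite(exc))) {
    stop("inclusion and exclusion signals must be finite", call. = FALSE)
  }
  if (any(inc < 0) || any(exc < 0)) {
    stop("inclusion and exclusion signals must be nonnegative", call. = FALSE)
  }
  zero <- inc + exc == 0
  if (any(zero)) {
    stop(
      "PSI undefined: inclusion + exclusion is zero at position(s) ",
      paste(which(zero), collapse = ", "),
      call. = FALSE
    )
  }
  100 * inc / (inc + exc)
}

#' Convert rMATS inclusion levels to PSI
#'
#' rMATS reports exon inclusion on a 0--1 scale; PSI is that level
#' multiplied by 100. Missing replicates (`NA`) propagate.
#'
#' @param inclusion_level Numeric vector of inclusion levels in `[0, 1]`,
#'   `NA` allowed.
#' @return Numeric vector of PSI values (percent), `NA` where input was `NA`.
#' @examples
#' inc_level_to_psi(c(0.42, NA, 1))
#' @export
inc_level_to_psi <- function(inclusion_level) {
  if (!is.numeric(inclusion_level)) {
    stop("inclusion_level must be numeric", call. = FALSE)
  }
  bad <- !is.na(inclusion_level) &
    (inclusion_level < 0 | inclusion_level > 1 | !is.finite(inclusion_level))
  if (any(bad)) {
    stop(
      "inclusion levels out of [0, 1] at position(s) ",
      paste(which(bad), collapse = ", "),
      call. = FALSE
    )
  }
  100 * inclusion_level
}

#' Category thresholds for rescue scores
#'
#' Events are called "Rescue" when the percent-rescue score is at least
#' `rescue_min` and "MisRescue" (the Methods' "opposite-direction" label is
#' an alias for the same category) when the score is at most
#' `misrescue_max`; everything in the open interval between the two is
#' "NoChange". Both boundaries are inclusive.
#'
#' @param rescue_min Lower bound (percent) for the Rescue call; default +10.
#' @param misrescue_max Upper bound (percent) for the MisRescue call;
#'   default -10. Must be strictly below `rescue_min`.
#' @return A list of class `category_thresholds`.
#' @export
category_thresholds <- function(rescue_min = 10, misrescue_max = -10) {
  stopifnot(is.numeric(rescue_min), is.numeric(misrescue_max),
            length(rescue_min) == 1, length(misrescue_max) == 1)
  if (!is.finite(rescue_min) || !is.finite(misrescue_max) ||
      misrescue_max >= rescue_min) {
    stop("misrescue_max must be finite and strictly below rescue_min",
         call. = FALSE)
  }
  structure(list(rescue_min = rescue_min, misrescue_max = misrescue_max),
            class = "category_thresholds")
}

#' Categorize percent-rescue scores
#'
#' Partitions the real line into the three response categories: every
#' finite score receives exactly one of `"Rescue"`, `"MisRescue"`,
#' `"NoChange"`.
#'
#' @param value Numeric vector of percent-rescue scores.
#' @param thresholds A [category_thresholds()] object.
#' @return Factor with levels `Rescue`, `MisRescue`, `NoChange`; `NA` scores
#'   yield `NA` categories.
#' @examples
#' categorize_score(c(10, -10, 0, 150))
#' @export
categorize_score <- function(value, thresholds = category_thresholds()) {
  stopifnot(inherits(thresholds, "category_thresholds"))
  if (!is.numeric(value)) stop("value must be numeric", call. = FALSE)
  if (any(is.infinite(value))) {
    stop("rescue scores must be finite", call. = FALSE)
  }
  out <- ifelse(
    value >= thresholds$rescue_min, "Rescue",
    ifelse(value <= thresholds$misrescue_max, "MisRescue", "NoChange")
  )
  factor(out, levels = c("Rescue", "MisRescue", "NoChange"))
}

#' Splicing percent-rescue score
#'
#' Measures how far treatment moved a dysregulated event's PSI back toward
#' the unaffected level:
#' \deqn{\%rescue = 100 \cdot
#'   \frac{PSI_{affected} - PSI_{treated}}{PSI_{affected} - PSI_{unaffected}}}
#'
#' A score of 100 means the treated PSI equals the unaffected PSI (full
#' rescue); 0 means no movement; negative scores mean the treated PSI moved
#' further away from the unaffected level. Scores are not capped: values
#' above 100 (overshoot past the unaffected level) and below -100 are
#' reported as computed.
#'
#' @param affected_psi,unaffected_psi,treated_psi PSI values (percent).
#'   Vectors are recycled to common length.
#' @param thresholds A [category_thresholds()] object.
#' @return A tibble with columns `value` (percent) and `category`.
#' @examples
#' splicing_rescue_score(20, 70, 45)   # 50, Rescue
#' splicing_rescue_score(20, 70, 10)   # -20, MisRescue
#' @export
splicing_rescue_score <- function(affected_psi, unaffected_psi, treated_psi,
                                  thresholds = category_thresholds()) {
  n <- max(length(affected_psi), length(unaffected_psi), length(treated_psi))
  a <- rep_len(as.numeric(affected_psi), n)
  u <- rep_len(as.numeric(unaffected_psi), n)
  t_ <- rep_len(as.numeric(treated_psi), n)
  denom_zero <- !is.na(a) & !is.na(u) & a == u
  if (any(denom_zero)) {
    stop(
      "rescue score undefined (affected PSI equals unaffected PSI) at ",
      "position(s) ", paste(which(denom_zero), collapse = ", "),
      call. = FALSE
    )
  }
  value <- 100 * (a - t_) / (a - u)
  tibble::tibble(value = value, category = categorize_score(value, thresholds))
}

#' Percent rescue from replicate PSIs per group
#'
#' Reduces each group of replicate PSIs to its arithmetic mean (missing
#' replicates dropped) and applies the percent-rescue score to the three
#' group means.
#'
#' @param affected,unaffected,treated Numeric vectors of replicate PSI
#'   values (percent) for the affected-untreated, unaffected (control), and
#'   treated groups. Each must contain at least one non-missing value.
#' @param thresholds A [category_thresholds()] object.
#' @return A one-row tibble with columns `value` and `category`.
#' @export
group_rescue_score <- function(affected, unaffected, treated,
                               thresholds = category_thresholds()) {
  means <- vapply(
    list(affected = affected, unaffected = unaffected, treated = treated),
    function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_real_)
      mean(x)
    },
    numeric(1)
  )
  if (anyNA(means)) {
    stop(
      "empty group(s): ", paste(names(means)[is.na(means)], collapse = ", "),
      call. = FALSE
    )
  }
  splicing_rescue_score(means[["affected"]], means[["unaffected"]],
                        means[["treated"]], thresholds)
}
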