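#' Expression percent-rescue score
#'
#' Scores how far treatment moved a differentially expressed gene back
#' toward the unaffected expression level, on the normalized-count scale.
#' Two modes are exposed because the published formula, evaluated exactly
#' as typeset,
#' \deqn{100 \cdot \left[1 - \frac{(unaff - aff) + (treated - aff)}
#'   {unaff - aff}\right] = -100 \cdot \frac{treated - aff}{unaff - aff},}
#' assigns negative scores to genes that move toward the unaffected level.
#' That sign contradicts the accompanying use of "Rescue" for scores of at
#' least +10%, so the default `symmetric` mode returns
#' `+100 * (treated - aff) / (unaff - aff)` — positive when expression
#' moves toward the unaffected level, matching the splicing score's
#' orientation — while `as_printed` evaluates the typeset formula
#' verbatim. The two modes are exact negations of one another.
#'
#' @param unaff_expr,aff_expr,treated_expr Normalized expression of the
#'   unaffected (control), affected, and treated groups (group means).
#'   Vectors are recycled to a common length.
#' @param mode `"symmetric"` (default) or `"as_printed"`.
#' @param thresholds A [category_thresholds()] object.
#' @return Tibble with columns `value` (percent), `mode`, `category`.
#' @examples
#' expression_rescue_score(100, 10, 55)                      # 50, Rescue
#' expression_rescue_score(100, 10, 55, mode = "as_printed") # -50
#' @export
expression_rescue_score <- function(unaff_expr, aff_expr, treated_expr,
                                    mode = c("symmetric", "as_printed"),
                                    thresholds = category_thresholds()) {
  mode <- match.arg(mode)
  n <- max(length(unaff_expr), length(aff_expr), length(treated_expr))
  u <- rep_len(as.numeric(unaff_expr), n)
  a <- rep_len(as.numeric(aff_expr), n)
  t_ <- rep_len(as.numeric(treated_expr), n)
  denom_zero <- !is.na(u) & !is.na(a) & u == a
  if (any(denom_zero)) {
    stop("expression rescue score undefined (affected equals unaffected) ",
         "at position(s) ", paste(which(denom_zero), collapse = ", "),
         call. = FALSE)
  }
  value <- 100 * (t_ - a) / (u - a)
  if (mode == "as_printed") value <- -value
  tibble::tibble(value = value, mode = mode,
                 category = categorize_score(value, thresholds))
}

#' Call differentially expressed genes
#'
#' A gene is differentially expressed between affected and control groups
#' when its absolute log2 fold change is at least `lfc_min` and its
#' adjusted p-value is at most `p_max`. Both statistics are consumed as
#' reported by the upstream differential-expression tool (or the
#' simulator's [expression_records()]).
#'
#' @param records Tibble with columns `log2_fold_change` and `adjusted_p`
#'   (e.g. from [expression_records()]).
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param p_max Maximum adjusted p-value (default 0.05).
#' @return Logical vector, one flag per record row.
#' @export
call_differential <- function(records, lfc_min = 2, p_max = 0.05) {
  required <- c("log2_fold_change", "adjusted_p")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  !is.na(records$log2_fold_change) & !is.na(records$adjusted_p) &
    abs(records$log2_fold_change) >= lfc_min &
    records$adjusted_p <= p_max
}

#' Categorize the expression response of DE genes at every dose
#'
#' For each differentially expressed gene and each treated group, computes
#' the symmetric-mode expression rescue score from the group mean
#' expressions and assigns the Rescue / MisRescue / NoChange category.
#' Genes whose affected and control means coincide are excluded and
#' counted separately, so the category counts always sum to the number of
#' DE genes.
#'
#' @param records Per-gene tibble with `gene`, `mean_control`,
#'   `mean_affected` and one `mean_<treated group>` column per dose.
#' @param flags Logical DE flags from [call_differential()].
#' @param thresholds A [category_thresholds()] object.
#' @return List with `scores` (tibble: `gene`, `group`, `score`,
#'   `category`, `scorable`) and `summary` (per treated group category
#'   counts plus `n_unscorable` and `n_de`).
#' @export
classify_expression_response <- function(records, flags,
                                         thresholds = category_thresholds()) {
  stopifnot(length(flags) == nrow(records))
  treated_cols <- grep("^mean_treated", names(records), value = TRUE)
  if (length(treated_cols) == 0) {
    stop("records contain no mean_treated_* columns", call. = FALSE)
  }
  de <- records[flags, ]
  scores <- purrr::map(treated_cols, function(col) {
    group <- sub("^mean_", "", col)
    u <- de$mean_control
    a <- de$mean_affected
    t_ <- de[[col]]
    scorable <- !is.na(u) & !is.na(a) & !is.na(t_) & u != a
    score <- rep(NA_real_, nrow(de))
    if (any(scorable)) {
      score[scorable] <- expression_rescue_score(
        u[scorable], a[scorable], t_[scorable],
        mode = "symmetric", thresholds = thresholds
      )$value
    }
    tibble::tibble(gene = de$gene, group = group, score = score,
                   category = categorize_score(score, thresholds),
                   scorable = scorable)
  })
  scores <- dplyr::bind_rows(scores)
  summary <- scores |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_rescue = sum(.data$category == "Rescue", na.rm = TRUE),
      n_misrescue = sum(.data$category == "MisRescue", na.rm = TRUE),
      n_nochange = sum(.data$category == "NoChange", na.rm = TRUE),
      n_unscorable = sum(!.data$scorable),
      n_de = dplyr::n(),
      .groups = "drop"
    )
  list(scores = scores, summary = summary)
}
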