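#' One-way ANOVA gate with Dunnett many-to-one comparisons
#'
#' The significance gate used before reporting an EC50: a one-way ANOVA
#' across dose groups followed by Dunnett-style many-to-one comparisons of
#' every group against the reference (vehicle) group, with family-wise
#' adjustment from the exact multivariate-t distribution of the joint
#' contrasts. A compound/event passes the gate when any comparison's
#' adjusted p-value is at most `alpha`.
#'
#' When every group has zero within-group variance the linear-model
#' machinery degenerates (exact separation); that path is handled
#' explicitly: comparisons whose means equal the reference mean get p = 1,
#' all others p = 0, and the overall p follows the same rule.
#'
#' @param data Tibble with columns `group` and `value` (replicate PSIs or
#'   \eqn{\Delta}PSIs); at least two groups with two replicates each.
#' @param reference Label of the reference (vehicle) group.
#' @param alpha Family-wise significance level for the gate (default 0.05).
#' @return List with `overall_p` (ANOVA F-test), `comparisons` (tibble:
#'   `group`, `estimate` = mean difference vs reference, `p_raw`,
#'   `adjusted_p`), and `significant` (any adjusted p <= `alpha`).
#' @export
anova_gate <- function(data, reference, alpha = 0.05) {
  stopifnot(all(c("group", "value") %in% names(data)))
  if (!reference %in% data$group) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  counts <- table(data$group)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need at least two groups with two replicates each", call. = FALSE)
  }
  others <- setdiff(names(counts), reference)
  g <- factor(data$group, levels = c(reference, others))
  y <- data$value

  group_means <- tapply(y, g, mean)
  group_vars <- tapply(y, g, stats::var)
  estimates <- group_means[others] - group_means[[reference]]

  if (all(group_vars == 0)) {
    # Exact separation: no residual variance.
    p_cmp <- ifelse(estimates == 0, 1, 0)
    comparisons <- tibble::tibble(
      group = others, estimate = unname(estimates),
      p_raw = unname(p_cmp), adjusted_p = unname(p_cmp)
    )
    overall_p <- if (all(estimates == 0)) 1 else 0
    return(list(overall_p = overall_p, comparisons = comparisons,
                significant = any(comparisons$adjusted_p <= alpha)))
  }

  df <- data.frame(y = y, g = g)
  fit <- stats::aov(y ~ g, data = df)
  overall_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  adj <- summary(gl)$test
  raw <- summary(gl, test = multcomp::adjusted("none"))$test
  comparisons <- tibble::tibble(
    group = others,
    estimate = unname(adj$coefficients),
    p_raw = unname(as.numeric(raw$pvalues)),
    adjusted_p = pmax(unname(as.numeric(adj$pvalues)),
                      unname(as.numeric(raw$pvalues)))
  )
  list(overall_p = overall_p, comparisons = comparisons,
       significant = any(comparisons$adjusted_p <= alpha))
}

#' Fit a Hill dose-response curve with zero bottom
#'
#' Least-squares fit of
#' \deqn{\Delta PSI(d) = EC_{max} \cdot \frac{d^h}{EC_{50}^h + d^h}}
#' to replicate responses, with the bottom fixed at 0, `EC50` estimated on
#' the log10 scale, and the Hill coefficient `h` box-bounded to `[0.3, 5]`
#' (started at 1) to stabilize small-n fits. Levenberg-Marquardt
#' optimization via `minpack.lm::nlsLM`.
#'
#' A fit is rejected (`converged = FALSE`, no EC50) when the optimizer
#' fails, the fitted plateau is not positive, or the fitted EC50 falls more
#' than 100-fold outside the tested dose range — all symptoms of a flat or
#' uninformative response.
#'
#' @param data Tibble with columns `dose` (nM, >= 0; 0-dose rows anchor the
#'   bottom) and `response` (\eqn{\Delta}PSI, PSI units). At least four
#'   distinct positive doses are required.
#' @param hill_bounds Length-2 bounds on the Hill coefficient.
#' @return List of class `dose_response_fit`: `ec50` (nM or `NA`),
#'   `ecmax_fitted`, `hill`, `converged`, `rss`, `n_doses`, `reason`.
#' @export
fit_dose_response <- function(data, hill_bounds = c(0.3, 5)) {
  stopifnot(all(c("dose", "response") %in% names(data)))
  data <- data[!is.na(data$dose) & !is.na(data$response), ]
  if (any(data$dose < 0)) stop("doses must be nonnegative", call. = FALSE)
  pos <- unique(data$dose[data$dose > 0])
  if (length(pos) < 4) {
    stop("need at least four distinct positive doses", call. = FALSE)
  }
  reject <- function(reason) {
    structure(list(ec50 = NA_real_, ecmax_fitted = NA_real_,
                   hill = NA_real_, converged = FALSE, rss = NA_real_,
                   n_doses = length(pos), reason = reason),
              class = "dose_response_fit")
  }
  start <- list(
    log_ec50 = stats::median(log10(pos)),
    ecmax = max(tapply(data$response, data$dose, mean)),
    h = 1
  )
  if (!is.finite(start$ecmax) || start$ecmax <= 0) start$ecmax <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ ecmax * dose^h / ((10^log_ec50)^h + dose^h),
      data = data, start = start,
      lower = c(log_ec50 = log10(min(pos)) - 3, ecmax = -Inf,
                h = hill_bounds[1]),
      upper = c(log_ec50 = log10(max(pos)) + 3, ecmax = Inf,
                h = hill_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(reject("optimizer failed"))
  est <- stats::coef(fit)
  ec50 <- 10^est[["log_ec50"]]
  if (!is.finite(ec50) || est[["ecmax"]] <= 0) {
    return(reject("no positive plateau"))
  }
  if (ec50 < min(pos) / 100 || ec50 > max(pos) * 100) {
    return(reject("EC50 outside informative dose range"))
  }
  structure(list(
    ec50 = ec50, ecmax_fitted = est[["ecmax"]], hill = est[["h"]],
    converged = TRUE, rss = sum(stats::resid(fit)^2),
    n_doses = length(pos), reason = "converged"
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<dose_response_fit> EC50 = %.4g nM, ECmax(fitted) = %.4g PSI, hill = %.3g, RSS = %.3g\n",
      x$ec50, x$ecmax_fitted, x$hill, x$rss
    ))
  } else {
    cat("<dose_response_fit> not converged:", x$reason, "\n")
  }
  invisible(x)
}

#' Compound screening summary with significance-gated EC50
#'
#' Reproduces the semantics of a compound screening table: for each
#' compound/event pair, replicate PSIs at a vehicle (dose 0) group and a
#' dose ladder are reduced to (i) a significance gate — one-way ANOVA with
#' Dunnett comparisons of every dose against vehicle — (ii) the observed
#' ECmax, i.e. the maximum group-mean \eqn{\Delta}PSI reached at any dose,
#' and (iii) a Hill-fit EC50, reported only when the gate is significant
#' and the fit converged (non-significant rows keep their ECmax but show no
#' EC50).
#'
#' @param data Tibble with columns `compound`, `event`, `dose` (nM, 0 =
#'   vehicle) and `psi` (replicate PSI or \eqn{\Delta}PSI values).
#' @param alpha Family-wise significance level of the gate.
#' @param thresholds Passed to [fit_dose_response()] as `hill_bounds`.
#' @return Tibble with one row per compound/event: `ec50`, `ecmax`
#'   (observed maximum \eqn{\Delta}PSI), `ecmax_fitted`, `hill`,
#'   `significant`, `anova_p`, `min_adjusted_p`, `fit_converged`.
#' @export
summarize_compound <- function(data, alpha = 0.05,
                               thresholds = c(0.3, 5)) {
  stopifnot(all(c("compound", "event", "dose", "psi") %in% names(data)))
  if (!any(data$dose == 0)) {
    stop("a vehicle (dose 0) group is required", call. = FALSE)
  }
  groups <- dplyr::group_split(dplyr::group_by(data, .data$compound,
                                               .data$event))
  rows <- purrr::map(groups, function(d) {
    vehicle_mean <- mean(d$psi[d$dose == 0])
    delta <- d$psi - vehicle_mean
    gate_data <- tibble::tibble(
      group = format(d$dose, trim = TRUE, scientific = FALSE),
      value = d$psi
    )
    gate <- anova_gate(gate_data, reference = format(0, trim = TRUE),
                       alpha = alpha)
    delta_means <- tapply(delta[d$dose > 0], d$dose[d$dose > 0], mean)
    ecmax_obs <- max(delta_means)
    fit <- tryCatch(
      fit_dose_response(tibble::tibble(dose = d$dose, response = delta),
                        hill_bounds = thresholds),
      error = function(e) NULL
    )
    converged <- !is.null(fit) && fit$converged
    tibble::tibble(
      compound = d$compound[1], event = d$event[1],
      ec50 = if (gate$significant && converged) fit$ec50 else NA_real_,
      ecmax = ecmax_obs,
      ecmax_fitted = if (converged) fit$ecmax_fitted else NA_real_,
      hill = if (converged) fit$hill else NA_real_,
      significant = gate$significant,
      anova_p = gate$overall_p,
      min_adjusted_p = min(gate$comparisons$adjusted_p),
      fit_converged = converged
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$compound, .data$event)
}
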