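#' Simulate a splicing-rescue study with planted ground truth
#'
#' Generates rMATS-JCEC-style skipped-exon tables for the full study
#' design: one affected-vs-control baseline contrast and one
#' treated-vs-control contrast per dose. A configurable fraction of events
#' is planted as dysregulated (control and affected PSI differ by a known
#' shift); treatment moves the affected PSI back toward control along a
#' Hill dose-response,
#' \deqn{PSI_{treated}(d) = PSI_{aff} + E_{max} \cdot
#'   \frac{d^h}{EC_{50}^h + d^h} \cdot (PSI_{ctrl} - PSI_{aff}).}
#' Optionally a fraction of events is planted as off-target: identical to
#' control at baseline but shifted under treatment.
#'
#' Replicate inclusion levels are drawn with beta-binomial noise: the
#' replicate-level inclusion probability is beta-distributed around the
#' group PSI with intraclass correlation `bb_dispersion`, junction totals
#' are Poisson around `mean_coverage`, and the reported inclusion level
#' follows the rMATS length normalization (two inclusion junctions versus
#' one skipping junction): `IncLevel = I / (I + 2 S)`. Per-contrast
#' p-values come from a two-sided moderated t-test (limma empirical-Bayes
#' variance shrinkage, the standard small-n choice) on replicate inclusion
#' levels, with Benjamini-Hochberg FDR across events. The control
#' replicates are drawn once and shared by every contrast, as in a real
#' study where all comparisons are made against the same control samples.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{contrasts}{Named list of event tables (one per contrast).
#'       Names are `affected_vs_control` and `treated_<dose>nM_vs_control`;
#'       each table carries `contrast`, `dose` and `type` attributes.
#'       `IncLevel1` holds the affected/treated replicates, `IncLevel2` the
#'       control replicates.}
#'     \item{truth}{Planted ground truth: `dysregulated_event_keys`,
#'       `off_target_event_keys`, a `true_psi` table (event x group x dose,
#'       PSI units), `true_ec50`, `true_emax`, and the config.}
#'   }
#' @export
simulate_splicing_study <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_events
    n_dys <- round(n * config$frac_dysregulated)
    n_ot <- round(n * config$frac_off_target)
    status <- rep("null", n)
    if (n_dys > 0) status[seq_len(n_dys)] <- "dysregulated"
    if (n_ot > 0) status[n_dys + seq_len(n_ot)] <- "off_target"

    anno <- simulate_event_annotation(n)

    # Planted group-level PSI (0-1 scale). Dysregulated events draw their
    # control PSI so that the full planted shift stays inside [0.01, 0.99].
    delta <- stats::runif(n, config$delta_psi_range[1] / 100,
                          config$delta_psi_range[2] / 100)
    direction <- sample(c(-1, 1), n, replace = TRUE)
    psi_control <- stats::runif(n, 0.05, 0.95)
    shifted <- status != "null"
    lo <- ifelse(direction == 1, 0.01, 0.01 + delta)
    hi <- ifelse(direction == 1, 0.99 - delta, 0.99)
    psi_control[shifted] <- lo[shifted] +
      stats::runif(sum(shifted)) * (hi[shifted] - lo[shifted])

    psi_affected <- psi_control
    dys <- status == "dysregulated"
    psi_affected[dys] <- psi_control[dys] + direction[dys] * delta[dys]

    reps <- config$n_replicates_per_group
    ctrl_reps <- draw_replicate_inc_levels(psi_control, reps, config)
    aff_reps <- draw_replicate_inc_levels(psi_affected, reps, config)

    contrasts <- list()
    contrasts[["affected_vs_control"]] <- build_contrast_table(
      anno, aff_reps, ctrl_reps, "affected_vs_control", NA_real_, "baseline"
    )

    truth_psi <- list(
      tibble::tibble(event_key = anno$event_key, group = "control",
                     dose = NA_real_, psi = 100 * psi_control),
      tibble::tibble(event_key = anno$event_key, group = "affected",
                     dose = NA_real_, psi = 100 * psi_affected)
    )

    for (d in config$doses) {
      f <- hill_fraction(d, config$true_ec50, config$hill)
      psi_treated <- psi_affected +
        config$true_emax * f * (psi_control - psi_affected)
      ot <- status == "off_target"
      psi_treated[ot] <- psi_control[ot] + direction[ot] * delta[ot] * f
      trt_reps <- draw_replicate_inc_levels(psi_treated, reps, config)
      label <- treated_contrast_label(d)
      contrasts[[label]] <- build_contrast_table(
        anno, trt_reps, ctrl_reps, label, d, "treated"
      )
      truth_psi[[length(truth_psi) + 1]] <- tibble::tibble(
        event_key = anno$event_key, group = "treated", dose = d,
        psi = 100 * psi_treated
      )
    }

    truth <- list(
      dysregulated_event_keys = anno$event_key[dys],
      off_target_event_keys = anno$event_key[status == "off_target"],
      true_psi = dplyr::bind_rows(truth_psi),
      true_ec50 = config$true_ec50,
      true_emax = config$true_emax,
      config = config
    )
    list(contrasts = contrasts, truth = truth)
  })
}

treated_contrast_label <- function(dose) {
  paste0("treated_", format(dose, trim = TRUE, scientific = FALSE),
         "nM_vs_control")
}

# Random but internally consistent SE annotation on a fictional genome,
# 0-based half-open, upstream < cassette < downstream in storage order.
simulate_event_annotation <- function(n) {
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  up_start <- sample.int(1e8L, n, replace = TRUE)
  up_len <- sample(80:300, n, replace = TRUE)
  int1 <- sample(500:5000, n, replace = TRUE)
  ex_len <- sample(30:250, n, replace = TRUE)
  int2 <- sample(500:5000, n, replace = TRUE)
  down_len <- sample(80:300, n, replace = TRUE)
  up_end <- up_start + up_len
  ex_start <- up_end + int1
  ex_end <- ex_start + ex_len
  down_start <- ex_end + int2
  down_end <- down_start + down_len
  anno <- tibble::tibble(
    GeneID = sprintf("ENSG%011d", seq_len(n)),
    geneSymbol = sprintf("SYNG%04d", seq_len(n)),
    chr = chrom, strand = strand,
    exonStart_0base = ex_start, exonEnd = ex_end,
    upstreamES = up_start, upstreamEE = up_end,
    downstreamES = down_start, downstreamEE = down_end
  )
  anno$event_key <- make_event_key(anno)
  anno
}

# Beta-binomial replicate inclusion levels around the group PSI (0-1).
# Returns an n_events x n_reps matrix; NA where the Poisson total is 0.
draw_replicate_inc_levels <- function(psi, n_reps, config) {
  n <- length(psi)
  mu <- matrix(rep(psi, n_reps), nrow = n)
  rho <- config$bb_dispersion
  if (rho > 0) {
    s <- (1 - rho) / rho
    p <- matrix(stats::rbeta(n * n_reps, mu * s, (1 - mu) * s), nrow = n)
  } else {
    p <- mu
  }
  total <- matrix(stats::rpois(n * n_reps, config$mean_coverage), nrow = n)
  # Two inclusion junctions vs one skipping junction: a read from an
  # including transcript is twice as likely to be observed.
  q <- 2 * p / (1 + p)
  inc_reads <- matrix(
    stats::rbinom(n * n_reps, as.vector(total), as.vector(q)),
    nrow = n
  )
  skip_reads <- total - inc_reads
  lev <- inc_reads / (inc_reads + 2 * skip_reads)
  lev[total == 0] <- NA_real_
  lev
}

# Moderated-t p-value per row of two replicate matrices (limma empirical
# Bayes variance shrinkage), the standard choice at n = 3 per group. Rows
# where the moderated statistic is undefined (all replicates identical)
# fall back to the exact-separation rule: equal means -> 1, different -> 0.
row_moderated_p <- function(m1, m2) {
  n1 <- ncol(m1)
  n2 <- ncol(m2)
  if (n1 + n2 < 3) return(row_welch_p(m1, m2))
  mat <- cbind(m1, m2)
  design <- cbind(Intercept = 1, Group = c(rep(1, n1), rep(0, n2)))
  p <- tryCatch({
    # limma warns when rows have zero sample variance; those rows are
    # re-tested by the exact-separation fallback below.
    fit <- suppressWarnings(limma::eBayes(limma::lmFit(mat, design)))
    fit$p.value[, "Group"]
  }, error = function(e) rep(NA_real_, nrow(m1)))
  fallback <- is.na(p)
  if (any(fallback)) {
    p[fallback] <- row_welch_p(m1[fallback, , drop = FALSE],
                               m2[fallback, , drop = FALSE])
  }
  unname(p)
}

# Welch t p-value per row of two replicate matrices, with a documented
# zero-variance fallback: equal means -> 1, different means -> 0.
row_welch_p <- function(m1, m2) {
  vapply(seq_len(nrow(m1)), function(i) {
    x <- m1[i, ][!is.na(m1[i, ])]
    y <- m2[i, ][!is.na(m2[i, ])]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    tryCatch(stats::t.test(x, y)$p.value,
             error = function(e) if (mean(x) == mean(y)) 1 else 0)
  }, numeric(1))
}

build_contrast_table <- function(anno, reps1, reps2, label, dose, type) {
  p <- row_moderated_p(reps1, reps2)
  fdr <- stats::p.adjust(p, method = "BH")
  mean1 <- rowMeans(reps1, na.rm = TRUE)
  mean2 <- rowMeans(reps2, na.rm = TRUE)
  tab <- tibble::tibble(
    GeneID = anno$GeneID, geneSymbol = anno$geneSymbol,
    chr = anno$chr, strand = anno$strand,
    exonStart_0base = anno$exonStart_0base, exonEnd = anno$exonEnd,
    upstreamES = anno$upstreamES, upstreamEE = anno$upstreamEE,
    downstreamES = anno$downstreamES, downstreamEE = anno$downstreamEE,
    IncLevel1 = lapply(seq_len(nrow(reps1)), function(i) unname(reps1[i, ])),
    IncLevel2 = lapply(seq_len(nrow(reps2)), function(i) unname(reps2[i, ])),
    IncLevelDifference = mean1 - mean2,
    PValue = p, FDR = fdr
  )
  new_event_table(tab, contrast = label, dose = dose, type = type)
}

new_event_table <- function(tab, contrast, dose = NA_real_,
                            type = c("baseline", "treated")) {
  attr(tab, "contrast") <- contrast
  attr(tab, "dose") <- dose
  attr(tab, "type") <- match.arg(type)
  class(tab) <- c("event_table", class(tab))
  tab
}

#' Simulate a capillary-electrophoresis isoform table
#'
#' For each event and sample, emits nonnegative inclusion and exclusion
#' relative fluorescence unit (RFU) values whose ratio encodes a true PSI.
#' Gaussian noise of SD `rfu_noise_sd` is added to each channel and
#' truncated at zero, mimicking baseline-subtracted electropherogram peak
#' quantification.
#'
#' @param config A [sim_config()] object; `n_events`,
#'   `n_replicates_per_group`, `rfu_noise_sd` and `seed` are used.
#' @param true_psi Optional numeric vector of true PSI values (percent),
#'   recycled to `n_events`; drawn uniformly from `[5, 95]` when `NULL`.
#' @param total_rfu Total signal per lane before noise (RFU).
#' @return Tibble with columns `event_id`, `sample_id`, `true_psi`,
#'   `inclusion_rfu`, `exclusion_rfu`.
#' @export
simulate_isoform_rfu <- function(config, true_psi = NULL, total_rfu = 1000) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed + 1L, {
    n <- config$n_events
    psi <- if (is.null(true_psi)) {
      stats::runif(n, 5, 95)
    } else {
      rep_len(as.numeric(true_psi), n)
    }
    if (any(psi < 0 | psi > 100)) {
      stop("true_psi must lie in [0, 100]", call. = FALSE)
    }
    reps <- config$n_replicates_per_group
    grid <- tidyr::expand_grid(
      event = seq_len(n), replicate = seq_len(reps)
    )
    inc <- total_rfu * psi[grid$event] / 100
    exc <- total_rfu * (100 - psi[grid$event]) / 100
    if (config$rfu_noise_sd > 0) {
      inc <- inc + stats::rnorm(nrow(grid), 0, config$rfu_noise_sd)
      exc <- exc + stats::rnorm(nrow(grid), 0, config$rfu_noise_sd)
    }
    tibble::tibble(
      event_id = sprintf("EV%05d", grid$event),
      sample_id = sprintf("S%03d", grid$replicate),
      true_psi = psi[grid$event],
      inclusion_rfu = pmax(inc, 0),
      exclusion_rfu = pmax(exc, 0)
    )
  })
}

#' Simulate a normalized gene-expression matrix with planted DE genes
#'
#' Baseline expression is log-normal. A planted fraction of genes is
#' shifted in the affected group by `de_log2fc` log2 units (random sign);
#' each treated group moves back toward control by the same Hill rescue
#' fraction used for splicing, `true_emax * d^h / (EC50^h + d^h)`.
#' Per-gene summary records (group means, affected-vs-control log2 fold
#' change, BH-adjusted Welch p) emulate the output of an upstream
#' differential-expression tool.
#'
#' @param config A [sim_config()] object.
#' @return A list with `expr` (gene x sample tibble of normalized counts),
#'   `samples` (sample annotation), `records` (per-gene summary tibble with
#'   `log2_fold_change` and `adjusted_p`), and `truth` (planted DE genes
#'   with signed log2 fold changes).
#' @export
simulate_expression_matrix <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed + 2L, {
    n <- config$n_genes
    genes <- sprintf("GSYN%04d", seq_len(n))
    n_de <- round(n * config$frac_de)
    de_sign <- sample(c(-1, 1), n, replace = TRUE)
    is_de <- seq_len(n) <= n_de

    log2_control <- stats::rnorm(n, mean = 8, sd = 2)
    log2_affected <- log2_control + ifelse(is_de, de_sign * config$de_log2fc, 0)

    group_log2 <- list(control = log2_control, affected = log2_affected)
    for (d in config$doses) {
      f <- config$true_emax * hill_fraction(d, config$true_ec50, config$hill)
      group_log2[[paste0("treated_", format(d, trim = TRUE,
                                            scientific = FALSE), "nM")]] <-
        log2_affected + f * (log2_control - log2_affected)
    }

    reps <- config$n_replicates_per_group
    cols <- list(gene = genes)
    samples <- list()
    for (g in names(group_log2)) {
      for (r in seq_len(reps)) {
        nm <- paste0(g, "_", r)
        noise <- if (config$expr_noise_sd > 0) {
          stats::rnorm(n, 0, config$expr_noise_sd)
        } else 0
        cols[[nm]] <- 2^(group_log2[[g]] + noise)
        samples[[length(samples) + 1]] <- tibble::tibble(
          sample_id = nm, group = g,
          dose = if (startsWith(g, "treated_")) {
            as.numeric(sub("treated_([0-9.e+-]+)nM", "\\1", g))
          } else NA_real_
        )
      }
    }
    expr <- tibble::as_tibble(cols)
    samples <- dplyr::bind_rows(samples)

    records <- expression_records(expr, samples)
    truth <- list(
      true_de_genes = tibble::tibble(
        gene = genes[is_de],
        log2fc = (de_sign * config$de_log2fc)[is_de]
      ),
      config = config
    )
    list(expr = expr, samples = samples, records = records, truth = truth)
  })
}

#' Per-gene group means and affected-vs-control test statistics
#'
#' Summarizes a normalized expression matrix into the per-gene records the
#' expression-rescue scorer consumes: group mean expression, log2 fold
#' change of affected vs control group means, and a BH-adjusted Welch
#' t-test p-value on log2 expression. In the study this table comes from a
#' dedicated differential-expression tool; this summarizer provides the
#' same fields for simulated matrices.
#'
#' @param expr Gene x sample tibble (first column `gene`).
#' @param samples Sample annotation with `sample_id`, `group`, `dose`.
#' @return Tibble with one row per gene: `mean_control`, `mean_affected`,
#'   one `mean_<treated group>` column per dose, `log2_fold_change`,
#'   `p_value`, `adjusted_p`.
#' @export
expression_records <- function(expr, samples) {
  stopifnot("gene" %in% names(expr))
  groups <- split(samples$sample_id, samples$group)
  if (!all(c("control", "affected") %in% names(groups))) {
    stop("samples must contain 'control' and 'affected' groups",
         call. = FALSE)
  }
  mat <- as.matrix(expr[, setdiff(names(expr), "gene")])
  rec <- tibble::tibble(gene = expr$gene)
  for (g in names(groups)) {
    rec[[paste0("mean_", g)]] <- rowMeans(mat[, groups[[g]], drop = FALSE])
  }
  ctrl <- log2(mat[, groups$control, drop = FALSE])
  aff <- log2(mat[, groups$affected, drop = FALSE])
  rec$log2_fold_change <- log2(rec$mean_affected / rec$mean_control)
  rec$p_value <- row_welch_p(aff, ctrl)
  rec$adjusted_p <- stats::p.adjust(rec$p_value, method = "BH")
  rec
}

#' Simulate a qPCR Ct table with a planted fold change
#'
#' Ct values follow the ideal amplification model
#' `Ct = intercept - log2(expression) + noise`; the reference gene's
#' expression is constant across groups, so group differences in
#' `target_ct - reference_ct` reflect the planted fold change of the
#' target. Vehicle samples carry the baseline expression; treated samples
#' carry `qpcr_fold_change` times the baseline.
#'
#' @param config A [sim_config()] object; `n_replicates_per_group`,
#'   `ct_noise_sd`, `qpcr_fold_change` and `seed` are used.
#' @param intercept Ct of one expression unit (cycles).
#' @return Tibble with `sample_id`, `group` (`vehicle`/`treated`),
#'   `target_ct`, `reference_ct`.
#' @export
simulate_qpcr <- function(config, intercept = 25) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed + 3L, {
    reps <- config$n_replicates_per_group
    grid <- tibble::tibble(
      group = rep(c("vehicle", "treated"), each = reps),
      replicate = rep(seq_len(reps), 2)
    )
    expr <- ifelse(grid$group == "vehicle", 1, config$qpcr_fold_change)
    ref_expr <- 1
    noise <- function(n) {
      if (config$ct_noise_sd > 0) stats::rnorm(n, 0, config$ct_noise_sd) else 0
    }
    n <- nrow(grid)
    tibble::tibble(
      sample_id = paste0(grid$group, "_", grid$replicate),
      group = grid$group,
      target_ct = intercept - log2(expr) + noise(n),
      reference_ct = intercept - log2(ref_expr) + noise(n)
    )
  })
}

#' Simulate a fluorescence indicator displacement (FID) series
#'
#' Fluorescence of a nucleic-acid-bound indicator decreases from `F0` as
#' increasing ligand displaces it, following a one-site displacement
#' isotherm:
#' \deqn{F(L) = F_{floor} + (F_0 - F_{floor}) \cdot \frac{K_d}{K_d + L}}
#' so that half of the maximal displacement is reached at `L = fid_kd`.
#' Gaussian noise of SD `rfu_noise_sd` is added and truncated at zero.
#'
#' @param config A [sim_config()] object; `fid_kd`, `fid_floor`, `fid_f0`,
#'   `rfu_noise_sd` and `seed` are used.
#' @param concentrations Ligand concentrations (uM, >= 0); defaults to a
#'   zero point plus a 12-point geometric ladder over 0.01--10 uM.
#' @return Tibble with `concentration_um`, `fluorescence`, `f0`.
#' @export
simulate_fid <- function(config,
                         concentrations = c(0, 10^seq(-2, 1, length.out = 12))) {
  config <- validate_sim_config(config)
  if (any(concentrations < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  withr::with_seed(config$seed + 4L, {
    floor_f <- config$fid_floor * config$fid_f0
    f <- floor_f + (config$fid_f0 - floor_f) *
      config$fid_kd / (config$fid_kd + concentrations)
    if (config$rfu_noise_sd > 0) {
      f <- f + stats::rnorm(length(f), 0, config$rfu_noise_sd)
    }
    tibble::tibble(
      concentration_um = concentrations,
      fluorescence = pmax(f, 0),
      f0 = config$fid_f0
    )
  })
}
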