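#' Simulation configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator that emulates the
#' study design the pipeline was built for: an unaffected control group, an
#' affected (disease) group with a planted set of dysregulated skipped-exon
#' events, and treated groups at a ladder of compound doses whose splicing
#' moves back toward control along a Hill dose-response.
#'
#' @param n_events Number of skipped-exon events to simulate.
#' @param frac_dysregulated Fraction of events planted as dysregulated in
#'   the affected group; the planted count is `round(n_events * frac)`.
#' @param n_replicates_per_group Biological replicates per group (the study
#'   design uses 3).
#' @param mean_coverage Mean junction-read coverage per event and replicate
#'   (Poisson-distributed totals).
#' @param bb_dispersion Beta-binomial overdispersion of replicate-level
#'   inclusion in `[0, 1)`; 0 disables the beta draw (pure binomial noise).
#' @param delta_psi_range Length-2 numeric, PSI units: the planted |control
#'   - affected| PSI shift of each dysregulated event is drawn uniformly
#'   from this range.
#' @param doses Compound concentrations in nM, sorted ascending; `0` is the
#'   vehicle (DMSO) arm. One treated-vs-control contrast is generated per
#'   dose.
#' @param true_ec50 True half-maximal concentration (nM) of the planted
#'   dose-response.
#' @param true_emax Fraction of the planted PSI shift restored at
#'   saturating dose, in `[0, 1]`.
#' @param hill Hill coefficient of the planted dose-response (> 0).
#' @param frac_off_target Fraction of non-dysregulated events planted as
#'   off-target: unchanged at baseline but shifted under treatment.
#' @param rfu_noise_sd Gaussian noise SD (RFU) of the capillary
#'   electrophoresis simulator.
#' @param ct_noise_sd Gaussian noise SD (cycles) of the qPCR simulator.
#' @param n_genes,frac_de,de_log2fc,expr_noise_sd Expression-matrix
#'   simulator: number of genes, fraction planted differentially expressed,
#'   planted |log2 fold change| (>= 2 to exceed the DE threshold), and
#'   log2-scale Gaussian noise SD.
#' @param qpcr_fold_change Planted target-gene fold change (treated vs
#'   vehicle) for the qPCR simulator.
#' @param fid_kd Displacement constant (uM) of the one-site fluorescence
#'   indicator displacement isotherm; the ligand concentration at which
#'   half of the maximal displacement is reached.
#' @param fid_floor Residual fluorescence at saturating ligand, as a
#'   fraction of F0 in `[0, 1)`.
#' @param fid_f0 Baseline fluorescence F0 (> 0, arbitrary units).
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce bit-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_events = 1000,
                       frac_dysregulated = 0.3,
                       n_replicates_per_group = 3,
                       mean_coverage = 100,
                       bb_dispersion = 0.01,
                       delta_psi_range = c(10, 50),
                       doses = c(8, 32, 125),
                       true_ec50 = 3.5,
                       true_emax = 0.8,
                       hill = 1,
                       frac_off_target = 0,
                       rfu_noise_sd = 5,
                       ct_noise_sd = 0.1,
                       n_genes = 500,
                       frac_de = 0.1,
                       de_log2fc = 3,
                       expr_noise_sd = 0.25,
                       qpcr_fold_change = 2,
                       fid_kd = 1,
                       fid_floor = 0,
                       fid_f0 = 100,
                       seed = 1L) {
  cfg <- list(
    n_events = n_events, frac_dysregulated = frac_dysregulated,
    n_replicates_per_group = n_replicates_per_group,
    mean_coverage = mean_coverage, bb_dispersion = bb_dispersion,
    delta_psi_range = delta_psi_range, doses = doses,
    true_ec50 = true_ec50, true_emax = true_emax, hill = hill,
    frac_off_target = frac_off_target,
    rfu_noise_sd = rfu_noise_sd, ct_noise_sd = ct_noise_sd,
    n_genes = n_genes, frac_de = frac_de, de_log2fc = de_log2fc,
    expr_noise_sd = expr_noise_sd, qpcr_fold_change = qpcr_fold_change,
    fid_kd = fid_kd, fid_floor = fid_floor, fid_f0 = fid_f0,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  num_fields <- setdiff(names(cfg), "seed")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || any(!is.finite(cfg[[f]]))) {
      stop("configuration error: '", f, "' must be finite numeric",
           call. = FALSE)
    }
  }
  check <- function(ok, msg) if (!ok) stop("configuration error: ", msg,
                                           call. = FALSE)
  check(cfg$n_events >= 1 && cfg$n_events == round(cfg$n_events),
        "n_events must be a count >= 1")
  check(cfg$n_replicates_per_group >= 1 &&
          cfg$n_replicates_per_group == round(cfg$n_replicates_per_group),
        "n_replicates_per_group must be a count >= 1")
  check(cfg$n_genes >= 1, "n_genes must be a count >= 1")
  for (f in c("frac_dysregulated", "frac_off_target", "frac_de",
              "true_emax")) {
    check(cfg[[f]] >= 0 && cfg[[f]] <= 1,
          paste0(f, " must lie in [0, 1]"))
  }
  check(cfg$frac_dysregulated + cfg$frac_off_target <= 1,
        "frac_dysregulated + frac_off_target must not exceed 1")
  check(cfg$bb_dispersion >= 0 && cfg$bb_dispersion < 1,
        "bb_dispersion must lie in [0, 1)")
  check(cfg$mean_coverage > 0, "mean_coverage must be positive")
  check(length(cfg$delta_psi_range) == 2 &&
          cfg$delta_psi_range[1] > 0 &&
          cfg$delta_psi_range[1] <= cfg$delta_psi_range[2] &&
          cfg$delta_psi_range[2] <= 100,
        "delta_psi_range must be increasing positive PSI bounds <= 100")
  check(length(cfg$doses) >= 1 && all(cfg$doses >= 0) &&
          !is.unsorted(cfg$doses, strictly = TRUE),
        "doses must be nonnegative and strictly ascending (0 = vehicle)")
  check(cfg$true_ec50 > 0, "true_ec50 must be positive")
  check(cfg$hill > 0, "hill must be positive")
  for (f in c("rfu_noise_sd", "ct_noise_sd", "expr_noise_sd")) {
    check(cfg[[f]] >= 0, paste0(f, " must be nonnegative"))
  }
  check(cfg$de_log2fc >= 0, "de_log2fc must be nonnegative")
  check(cfg$qpcr_fold_change > 0, "qpcr_fold_change must be positive")
  check(cfg$fid_kd > 0, "fid_kd must be positive")
  check(cfg$fid_floor >= 0 && cfg$fid_floor < 1, "fid_floor must be in [0, 1)")
  check(cfg$fid_f0 > 0, "fid_f0 must be positive")
  check(!is.na(cfg$seed), "seed must be an integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-24s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write and read a simulation configuration as JSON
#'
#' Serializes a [sim_config()] to a single structured text file (JSON) so
#' a simulated study is fully reproducible from the file plus the package
#' version; reading validates the configuration exactly as [sim_config()]
#' does.
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  config <- validate_sim_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON does not distinguish integer from double; restore storage modes.
  raw <- lapply(raw, function(v) if (is.numeric(v)) as.double(v) else v)
  raw$seed <- as.integer(raw$seed)
  validate_sim_config(structure(raw, class = "sim_config"))
}

# Hill fractional occupancy; f(0) = 0, f(Inf) = 1.
hill_fraction <- function(dose, ec50, hill) {
  ifelse(dose <= 0, 0, dose^hill / (ec50^hill + dose^hill))
}
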