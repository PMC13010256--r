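test_that("configuration validation rejects out-of-range values", {
  expect_error(sim_config(n_events = 0), "n_events")
  expect_error(sim_config(frac_dysregulated = 1.2), "frac_dysregulated")
  expect_error(sim_config(bb_dispersion = 1), "bb_dispersion")
  expect_error(sim_config(doses = c(10, 5)), "doses")
  expect_error(sim_config(doses = c(-1, 5)), "doses")
  expect_error(sim_config(true_ec50 = NaN), "finite")
  expect_error(sim_config(mean_coverage = Inf), "finite")
  expect_error(sim_config(delta_psi_range = c(40, 10)), "delta_psi_range")
})

test_that("configurations round-trip through their JSON file form", {
  cfg <- sim_config(n_events = 25, doses = c(0, 8, 125), seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  got <- read_sim_config(path)
  expect_equal(got, cfg)
  expect_identical(simulate_splicing_study(got), simulate_splicing_study(cfg))
})

test_that("planted dysregulated set honours the configured fraction", {
  # nothing planted
  sim0 <- simulate_splicing_study(sim_config(n_events = 50,
                                             frac_dysregulated = 0,
                                             seed = 5))
  expect_length(sim0$truth$dysregulated_event_keys, 0)
  # exact planted count under the rounding rule
  sim <- simulate_splicing_study(sim_config(n_events = 200,
                                            frac_dysregulated = 0.3,
                                            seed = 1))
  expect_length(sim$truth$dysregulated_event_keys, round(200 * 0.3))
  expect_length(sim$truth$dysregulated_event_keys, 60)
  # every planted key exists in the generated tables
  keys <- make_event_key(sim$contrasts$affected_vs_control)
  expect_true(all(sim$truth$dysregulated_event_keys %in% keys))
})

test_that("planted shifts respect the configured minimum and PSI bounds", {
  cfg <- sim_config(n_events = 300, frac_dysregulated = 0.4,
                    delta_psi_range = c(15, 40), seed = 3)
  sim <- simulate_splicing_study(cfg)
  truth <- sim$truth$true_psi
  ctrl <- truth[truth$group == "control", ]
  aff <- truth[truth$group == "affected", ]
  stopifnot(identical(ctrl$event_key, aff$event_key))
  dys <- ctrl$event_key %in% sim$truth$dysregulated_event_keys
  gap <- abs(ctrl$psi - aff$psi)
  expect_true(all(gap[dys] >= 15 - 1e-9))
  expect_true(all(gap[dys] <= 40 + 1e-9))
  expect_true(all(gap[!dys] == 0))
  expect_true(all(truth$psi >= 0 & truth$psi <= 100))
  # generated inclusion levels bounded in [0, 1]
  for (tab in sim$contrasts) {
    levs <- unlist(c(tab$IncLevel1, tab$IncLevel2))
    expect_true(all(is.na(levs) | (levs >= 0 & levs <= 1)))
  }
})

test_that("treated PSI approaches control in the noiseless saturating limit", {
  cfg <- sim_config(n_events = 100, frac_dysregulated = 0.5,
                    bb_dispersion = 0, mean_coverage = 1e6,
                    doses = 1e7, true_ec50 = 3.5, true_emax = 1, seed = 2)
  sim <- simulate_splicing_study(cfg)
  trt <- sim$contrasts[[2]]
  ctrl_psi <- 100 * vapply(trt$IncLevel2, mean, numeric(1))
  trt_psi <- 100 * vapply(trt$IncLevel1, mean, numeric(1))
  expect_true(all(abs(trt_psi - ctrl_psi) < 1))
})

test_that("identical config and seed give identical outputs, different seeds differ", {
  cfg <- sim_config(n_events = 40, seed = 99)
  s1 <- simulate_splicing_study(cfg)
  s2 <- simulate_splicing_study(cfg)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_jcec(s1$contrasts[[1]], f1)
  write_jcec(s2$contrasts[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_splicing_study(sim_config(n_events = 40, seed = 100))
  expect_false(identical(s1$contrasts[[1]]$IncLevel1,
                         s3$contrasts[[1]]$IncLevel1))
})

test_that("null simulation keeps the significant fraction calibrated", {
  fracs <- vapply(c(21, 22, 23), function(seed) {
    sim <- simulate_splicing_study(
      sim_config(n_events = 400, frac_dysregulated = 0, seed = seed)
    )
    mean(sim$contrasts$affected_vs_control$FDR <= 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(fracs <= 0.1))
})

test_that("isoform RFU tables encode the true PSI in their channel ratio", {
  cfg0 <- sim_config(n_events = 4, rfu_noise_sd = 0, seed = 8)
  # PSI 50: equal channels; PSI 75: inclusion = 3 x exclusion
  tab50 <- simulate_isoform_rfu(cfg0, true_psi = 50)
  expect_equal(tab50$inclusion_rfu, tab50$exclusion_rfu)
  tab75 <- simulate_isoform_rfu(cfg0, true_psi = 75)
  expect_equal(tab75$inclusion_rfu, 3 * tab75$exclusion_rfu)
  expect_true(all(tab75$inclusion_rfu >= 0 & tab75$exclusion_rfu >= 0))
  # Monte-Carlo recovery under noise
  cfg <- sim_config(n_events = 1000, n_replicates_per_group = 1,
                    rfu_noise_sd = 5, seed = 12)
  noisy <- simulate_isoform_rfu(cfg, true_psi = 62)
  rec <- compute_psi(noisy$inclusion_rfu, noisy$exclusion_rfu)
  expect_equal(mean(rec), 62, tolerance = 1 / 62)
})

test_that("expression matrix plants DE genes and rescues them with dose", {
  # noiseless, planted log2FC exactly 2, full rescue at saturating dose
  cfg <- sim_config(n_genes = 60, frac_de = 0.25, de_log2fc = 2,
                    expr_noise_sd = 0, doses = 1e7, true_ec50 = 1,
                    true_emax = 1, seed = 4)
  out <- simulate_expression_matrix(cfg)
  rec <- out$records
  de <- rec$gene %in% out$truth$true_de_genes$gene
  ratio <- rec$mean_affected / rec$mean_control
  # planted |log2FC| = 2 exactly: affected/control ratio is 4 or 1/4
  expect_true(all(pmin(abs(ratio[de] - 4), abs(ratio[de] - 0.25)) < 1e-9))
  expect_equal(unname(ratio[!de]), rep(1, sum(!de)))
  treated_col <- grep("^mean_treated", names(rec), value = TRUE)[1]
  expect_equal(rec[[treated_col]], rec$mean_control, tolerance = 1e-6)
  # zero planted DE genes: group means differ only by sampling noise
  cfg0 <- sim_config(n_genes = 200, frac_de = 0, expr_noise_sd = 0.25,
                     seed = 5)
  out0 <- simulate_expression_matrix(cfg0)
  lfc <- out0$records$log2_fold_change
  expect_lt(max(abs(lfc)), 2)
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("qPCR simulator encodes the planted fold change in Ct space", {
  # noiseless 2-fold knockdown shifts delta-Ct by +1
  cfg <- sim_config(ct_noise_sd = 0, qpcr_fold_change = 0.5, seed = 6)
  ct <- simulate_qpcr(cfg)
  dct <- ct$target_ct - ct$reference_ct
  expect_equal(mean(dct[ct$group == "treated"]) -
                 mean(dct[ct$group == "vehicle"]), 1)
  # equal expression: delta-delta-Ct identically zero
  cfg1 <- sim_config(ct_noise_sd = 0, qpcr_fold_change = 1, seed = 6)
  ct1 <- ddct_relative_expression(simulate_qpcr(cfg1))
  expect_equal(ct1$delta_delta_ct, rep(0, nrow(ct1)))
})

test_that("FID series follows the one-site displacement isotherm", {
  cfg <- sim_config(rfu_noise_sd = 0, fid_kd = 1, fid_floor = 0,
                    fid_f0 = 100, seed = 7)
  fid <- simulate_fid(cfg, concentrations = c(0, 1, 1e6))
  # zero ligand: F = F0
  expect_equal(fid$fluorescence[1], 100)
  # half-displacement at the configured displacement constant
  expect_equal(fid$fluorescence[2], 50)
  expect_equal(percent_fid(fid$fluorescence[2], fid$f0[2]), 50)
  # saturating ligand approaches the residual floor
  expect_lt(fid$fluorescence[3], 0.001)
  cfg_floor <- sim_config(rfu_noise_sd = 0, fid_kd = 1, fid_floor = 0.2,
                          fid_f0 = 100, seed = 7)
  fid_floor <- simulate_fid(cfg_floor, concentrations = c(0, 1e6))
  expect_equal(fid_floor$fluorescence[2], 20, tolerance = 1e-4)
  expect_true(all(fid$fluorescence >= 0))
})
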