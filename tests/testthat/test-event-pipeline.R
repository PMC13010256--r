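test_that("event keys are deterministic, discriminating, and parseable", {
  tab <- tiny_event_table(3)
  k1 <- make_event_key(tab)
  expect_equal(make_event_key(tab), k1)
  # structurally identical events share a key
  expect_equal(make_event_key(tab[c(1, 1), ])[1],
               make_event_key(tab[c(1, 1), ])[2])
  # any differing field changes the key
  mod <- tab
  mod$exonEnd[1] <- mod$exonEnd[1] + 1
  expect_false(make_event_key(mod)[1] == k1[1])
  mod2 <- tab
  mod2$geneSymbol[1] <- "OTHER"
  expect_false(make_event_key(mod2)[1] == k1[1])
  # round trip through the parser
  parsed <- parse_event_key(k1)
  expect_equal(make_event_key(parsed), k1)
  expect_error(make_event_key(tab[, -1]), "missing field")
})

test_that("matching a table with itself is the identity", {
  tab <- tiny_event_table(5)
  m <- match_events(list(a = tab, b = tab))
  expect_equal(nrow(m), 5)
  expect_equal(sort(m$event_key), sort(make_event_key(tab)))
  expect_equal(m$a.delta, m$b.delta)
})

test_that("disjoint tables produce an empty inner match", {
  t1 <- tiny_event_table(3)
  t2 <- tiny_event_table(3)
  t2$GeneID <- paste0(t2$GeneID, "X")
  expect_equal(nrow(match_events(list(a = t1, b = t2))), 0)
  outer <- match_events(list(a = t1, b = t2), require_all = FALSE)
  expect_equal(nrow(outer), 6)
})

test_that("matching equals the quadratic brute-force matcher on overlap", {
  sim <- simulate_splicing_study(sim_config(n_events = 120, seed = 31))
  t1 <- sim$contrasts[[1]]
  t2 <- sim$contrasts[[2]]
  # 30% overlap: keep a random subset in each table
  withr::with_seed(31, {
    keep1 <- sort(sample(120, 80))
    keep2 <- sort(c(sample(keep1, 36), sample(setdiff(1:120, keep1), 30)))
  })
  t1s <- t1[keep1, ]
  t2s <- t2[keep2, ]
  m <- match_events(list(x = t1s, y = t2s))
  oracle <- brute_force_match(list(t1s, t2s))
  expect_equal(nrow(m), length(oracle))
  oracle_keys <- sort(make_event_key(t1s)[vapply(oracle, `[`, 1L, 1)])
  expect_equal(m$event_key, oracle_keys)
  # element-wise content agrees with the brute-force row pairing
  for (h in oracle) {
    key <- make_event_key(t1s)[h[1]]
    row <- m[m$event_key == key, ]
    expect_equal(row$x.delta, t1s$IncLevelDifference[h[1]])
    expect_equal(row$y.delta, t2s$IncLevelDifference[h[2]])
    expect_equal(row$x.inc1[[1]], t1s$IncLevel1[[h[1]]])
  }
})

test_that("matching is independent of row and table order", {
  sim <- simulate_splicing_study(sim_config(n_events = 50, seed = 32))
  t1 <- sim$contrasts[[1]]
  t2 <- sim$contrasts[[2]]
  m1 <- match_events(list(a = t1, b = t2))
  withr::with_seed(1, {
    perm1 <- t1[sample(nrow(t1)), ]
    perm2 <- t2[sample(nrow(t2)), ]
  })
  m2 <- match_events(list(a = perm1, b = perm2))
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("duplicate keys within one table raise an error listing keys", {
  tab <- tiny_event_table(3)
  dup <- tab[c(1, 2, 1, 3), ]
  expect_error(match_events(list(a = dup, b = tab)), "duplicate event key")
  m <- match_events(list(a = dup, b = tab), keep_first = TRUE)
  expect_equal(nrow(m), 3)
})

test_that("filters remove exactly the rows an independent oracle removes", {
  sim <- simulate_splicing_study(
    sim_config(n_events = 400, bb_dispersion = 0.25, mean_coverage = 8,
               seed = 41)
  )
  m <- match_events(sim$contrasts)
  suppressMessages(f <- filter_events(m, sd_max = 20))
  keep_oracle <- filter_oracle(m, sd_max = 20)
  expect_equal(f$event_key, m$event_key[keep_oracle])
  log <- attr(f, "filter_log")
  expect_equal(log$n_kept, sum(keep_oracle))
  expect_equal(log$n_input - log$n_missing_removed - log$n_sd_removed,
               log$n_kept)
  # low coverage must actually exercise both filter paths
  expect_gt(log$n_missing_removed + log$n_sd_removed, 0)
})

test_that("noiseless tables pass the filters untouched", {
  sim <- simulate_splicing_study(
    sim_config(n_events = 100, bb_dispersion = 0, mean_coverage = 1e5,
               seed = 42)
  )
  m <- match_events(sim$contrasts)
  suppressMessages(f <- filter_events(m))
  expect_equal(nrow(f), 100)
})

test_that("one missing control replicate removes that row", {
  tab <- tiny_event_table(3)
  tab$IncLevel2[[2]] <- c(0.2, NA, 0.3)
  trt <- tiny_event_table(3, contrast = "treated_8nM_vs_control", dose = 8,
                          type = "treated")
  m <- match_events(list(affected_vs_control = tab,
                         treated_8nM_vs_control = trt))
  suppressMessages(f <- filter_events(m))
  expect_equal(nrow(f), 2)
  expect_false(make_event_key(tab)[2] %in% f$event_key)
})

test_that("dysregulation calls apply both thresholds jointly", {
  tab <- tiny_event_table(3)
  tab$IncLevelDifference <- c(0.099, 0.30, 0.30)
  tab$FDR <- c(0.01, 0.20, 0.01)
  trt <- tiny_event_table(3, contrast = "treated_8nM_vs_control", dose = 8,
                          type = "treated")
  m <- match_events(list(affected_vs_control = tab,
                         treated_8nM_vs_control = trt))
  calls <- call_dysregulated(m)
  calls <- calls[match(make_event_key(tab), calls$event_key), ]
  # below the inclusion-difference threshold; FDR too high; both pass
  expect_equal(calls$is_dysregulated, c(FALSE, FALSE, TRUE))
  expect_equal(calls$delta_psi, 100 * calls$inc_level_difference)
  tab$FDR[1] <- NA
  m2 <- match_events(list(affected_vs_control = tab,
                          treated_8nM_vs_control = trt))
  expect_error(call_dysregulated(m2), "missing FDR")
})

test_that("planted events are recovered with high sensitivity and few false calls", {
  cfg <- sim_config(n_events = 1000, frac_dysregulated = 0.3,
                    delta_psi_range = c(30, 30), mean_coverage = 100,
                    n_replicates_per_group = 3, seed = 7)
  res <- run_pipeline(cfg, quiet = TRUE)
  truth_dys <- res$truth$dysregulated_event_keys
  called <- res$calls$event_key[res$calls$is_dysregulated]
  surviving <- intersect(res$calls$event_key, truth_dys)
  sens <- mean(surviving %in% called)
  null_keys <- setdiff(res$calls$event_key, truth_dys)
  false_rate <- mean(null_keys %in% called)
  expect_gte(sens, 0.8)
  expect_lte(false_rate, 0.1)
})

test_that("response categories match an independent per-event oracle", {
  cfg <- sim_config(n_events = 300, frac_dysregulated = 0.4, seed = 51)
  sim <- simulate_splicing_study(cfg)
  m <- match_events(sim$contrasts)
  suppressMessages(f <- filter_events(m))
  calls <- call_dysregulated(f)
  resp <- classify_treatment_response(f, calls)
  dys_keys <- calls$event_key[calls$is_dysregulated]
  for (label in unique(resp$categories$contrast)) {
    oracle <- categorize_oracle(f, dys_keys, label)
    got <- resp$categories[resp$categories$contrast == label, ]
    got_vec <- ifelse(got$scorable, as.character(got$category), "unscorable")
    names(got_vec) <- got$event_key
    expect_equal(got_vec[names(oracle)], oracle)
  }
})

test_that("category counts are conserved at every dose", {
  cfg <- sim_config(n_events = 400, frac_dysregulated = 0.35, seed = 52)
  res <- run_pipeline(cfg, quiet = TRUE)
  s <- res$summary
  expect_true(all(
    s$n_rescue + s$n_misrescue + s$n_nochange + s$n_unscorable ==
      s$n_dysregulated
  ))
})

test_that("off-target flags match the thresholds and planted truth", {
  # planted off-target events, noiseless: all flagged at saturating dose
  cfg <- sim_config(n_events = 200, frac_dysregulated = 0.2,
                    frac_off_target = 0.1, bb_dispersion = 0,
                    mean_coverage = 1e5, doses = c(0, 1e6),
                    true_ec50 = 5, true_emax = 1,
                    delta_psi_range = c(20, 40), seed = 61)
  res <- run_pipeline(cfg, quiet = TRUE)
  ot_truth <- res$truth$off_target_event_keys
  top <- res$off_target[res$off_target$dose == 1e6, ]
  expect_setequal(top$event_key, ot_truth)
  # no treatment effect on null events: nothing flagged at vehicle
  veh <- res$off_target[res$off_target$dose == 0, ]
  expect_equal(nrow(veh), 0)
  # brute-force recomputation on a noisy seeded fixture
  cfg2 <- sim_config(n_events = 300, frac_dysregulated = 0.3,
                     frac_off_target = 0.1, seed = 62)
  sim2 <- simulate_splicing_study(cfg2)
  m2 <- match_events(sim2$contrasts)
  suppressMessages(f2 <- filter_events(m2))
  calls2 <- call_dysregulated(f2)
  ot2 <- flag_off_target(f2, calls2)
  non_dys <- calls2$event_key[!calls2$is_dysregulated]
  for (label in setdiff(unique(ot2$contrast), "affected_vs_control")) {
    delta <- f2[[paste0(label, ".delta")]]
    fdr <- f2[[paste0(label, ".fdr")]]
    idx <- f2$event_key %in% non_dys & !is.na(delta) & !is.na(fdr) &
      abs(delta) >= 0.1 & fdr <= 0.05
    expect_setequal(ot2$event_key[ot2$contrast == label],
                    f2$event_key[idx])
  }
})
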