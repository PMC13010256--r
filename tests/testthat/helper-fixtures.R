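# Shared fixtures and independent oracles used across test files.
# Everything is generated in code; no fixture files on disk.

# A small, fully valid event table built by hand (not via the simulator).
tiny_event_table <- function(n = 3, contrast = "affected_vs_control",
                             dose = NA_real_, type = "baseline") {
  base <- 1000 * seq_len(n)
  tab <- tibble::tibble(
    GeneID = sprintf("ENSG%011d", seq_len(n)),
    geneSymbol = sprintf("GENE%d", seq_len(n)),
    chr = rep("chr1", n),
    strand = rep(c("+", "-"), length.out = n),
    exonStart_0base = base + 200, exonEnd = base + 300,
    upstreamES = base, upstreamEE = base + 100,
    downstreamES = base + 400, downstreamEE = base + 500,
    IncLevel1 = replicate(n, c(0.5, 0.6, 0.55), simplify = FALSE),
    IncLevel2 = replicate(n, c(0.2, 0.25, 0.3), simplify = FALSE),
    IncLevelDifference = rep(0.3, n),
    PValue = rep(0.001, n),
    FDR = rep(0.01, n)
  )
  splicerescue:::new_event_table(tab, contrast = contrast, dose = dose,
                                 type = type)
}

# Quadratic brute-force event matcher: compares every row of every table
# against every row of the first table on the raw component fields, never
# through make_event_key or joins.
brute_force_match <- function(tables) {
  key_fields <- c("chr", "strand", "upstreamES", "upstreamEE",
                  "exonStart_0base", "exonEnd", "downstreamES",
                  "downstreamEE", "GeneID", "geneSymbol")
  same_event <- function(t1, i, t2, j) {
    all(vapply(key_fields, function(f) {
      identical(as.character(t1[[f]][i]), as.character(t2[[f]][j]))
    }, logical(1)))
  }
  t1 <- tables[[1]]
  hits <- list()
  for (i in seq_len(nrow(t1))) {
    idx <- rep(NA_integer_, length(tables))
    idx[1] <- i
    found_all <- TRUE
    for (k in seq_along(tables)[-1]) {
      tk <- tables[[k]]
      match_j <- NA_integer_
      for (j in seq_len(nrow(tk))) {
        if (same_event(t1, i, tk, j)) {
          match_j <- j
          break
        }
      }
      if (is.na(match_j)) {
        found_all <- FALSE
        break
      }
      idx[k] <- match_j
    }
    if (found_all) hits[[length(hits) + 1]] <- idx
  }
  hits
}

# Independent recomputation of the missing-value and SD filters, row by
# row with plain loops.
filter_oracle <- function(matched, sd_max = 20,
                          baseline = "affected_vs_control") {
  inc1 <- matched[[paste0(baseline, ".inc1")]]
  inc2 <- matched[[paste0(baseline, ".inc2")]]
  keep <- logical(nrow(matched))
  for (i in seq_len(nrow(matched))) {
    a <- inc1[[i]]
    c_ <- inc2[[i]]
    if (length(a) == 0 || length(c_) == 0 || any(is.na(a)) ||
        any(is.na(c_))) {
      keep[i] <- FALSE
      next
    }
    sd_a <- if (length(a) > 1) stats::sd(100 * a) else 0
    sd_c <- if (length(c_) > 1) stats::sd(100 * c_) else 0
    keep[i] <- sd_a <= sd_max && sd_c <= sd_max
  }
  keep
}

# Independent per-event reimplementation of the response categorization:
# mean PSIs, the rescue ratio and threshold rules written out longhand.
categorize_oracle <- function(matched, dys_keys, treated_label,
                              baseline = "affected_vs_control") {
  out <- character(0)
  for (i in seq_len(nrow(matched))) {
    key <- matched$event_key[i]
    if (!key %in% dys_keys) next
    aff <- matched[[paste0(baseline, ".inc1")]][[i]]
    ctrl <- matched[[paste0(baseline, ".inc2")]][[i]]
    trt <- matched[[paste0(treated_label, ".inc1")]][[i]]
    a <- 100 * mean(aff, na.rm = TRUE)
    u <- 100 * mean(ctrl, na.rm = TRUE)
    t_ <- 100 * mean(trt, na.rm = TRUE)
    if (is.nan(a) || is.nan(u) || is.nan(t_) || a == u) {
      out[key] <- "unscorable"
      next
    }
    s <- 100 * (a - t_) / (a - u)
    out[key] <- if (s >= 10) "Rescue" else if (s <= -10) "MisRescue" else
      "NoChange"
  }
  out
}

# Max-t permutation reference for Dunnett-style many-to-one adjusted
# p-values (equal-n one-way layout).
permutation_dunnett <- function(values, groups, reference, n_perm = 4000,
                                seed = 42) {
  groups <- as.character(groups)
  others <- setdiff(unique(groups), reference)
  tstat <- function(y, g) {
    s2 <- 0
    df <- 0
    for (lev in unique(g)) {
      yi <- y[g == lev]
      s2 <- s2 + sum((yi - mean(yi))^2)
      df <- df + length(yi) - 1
    }
    s2 <- s2 / df
    vapply(others, function(o) {
      (mean(y[g == o]) - mean(y[g == reference])) /
        sqrt(s2 * (1 / sum(g == o) + 1 / sum(g == reference)))
    }, numeric(1))
  }
  obs <- tstat(values, groups)
  withr::with_seed(seed, {
    max_null <- replicate(n_perm, {
      max(abs(tstat(sample(values), groups)))
    })
  })
  vapply(abs(obs), function(t0) mean(max_null >= t0), numeric(1))
}
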