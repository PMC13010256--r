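#' Canonical skipped-exon event identifier
#'
#' Builds the unique event ID used to match skipped-exon events across
#' contrasts: chromosome, strand, upstream exon coordinates, regulated
#' (cassette) exon coordinates, downstream exon coordinates, Ensembl gene
#' ID and gene symbol, joined by `|` in that fixed order. Two events with
#' identical component fields always receive identical keys; any differing
#' field changes the key.
#'
#' @param events Tibble with rMATS-style columns (`GeneID`, `geneSymbol`,
#'   `chr`, `strand`, `upstreamES`, `upstreamEE`, `exonStart_0base`,
#'   `exonEnd`, `downstreamES`, `downstreamEE`).
#' @return Character vector of canonical keys, one per row.
#' @export
make_event_key <- function(events) {
  fields <- c("chr", "strand", "upstreamES", "upstreamEE",
              "exonStart_0base", "exonEnd", "downstreamES", "downstreamEE",
              "GeneID", "geneSymbol")
  missing_cols <- setdiff(fields, names(events))
  if (length(missing_cols) > 0) {
    stop("key error: missing field(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(fields, function(f) {
    v <- events[[f]]
    if (any(is.na(v)) || any(!nzchar(as.character(v)))) {
      stop("key error: missing values in field '", f, "'", call. = FALSE)
    }
    if (is.numeric(v)) format(v, trim = TRUE, scientific = FALSE) else
      as.character(v)
  })
  do.call(paste, c(vals, sep = "|"))
}

#' Parse canonical event keys back into their component fields
#'
#' Inverse of [make_event_key()]; useful for reporting and for verifying
#' that keys round-trip through serialization.
#'
#' @param keys Character vector of keys produced by [make_event_key()].
#' @return Tibble with the ten component columns.
#' @export
parse_event_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  bad <- lengths(parts) != 10
  if (any(bad)) {
    stop("malformed event key(s) at position(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  tibble::tibble(
    chr = m[, 1], strand = m[, 2],
    upstreamES = as.numeric(m[, 3]), upstreamEE = as.numeric(m[, 4]),
    exonStart_0base = as.numeric(m[, 5]), exonEnd = as.numeric(m[, 6]),
    downstreamES = as.numeric(m[, 7]), downstreamEE = as.numeric(m[, 8]),
    GeneID = m[, 9], geneSymbol = m[, 10]
  )
}

contrast_meta <- function(tables) {
  tibble::tibble(
    label = names(tables),
    dose = vapply(tables, function(t) {
      d <- attr(t, "dose")
      if (is.null(d)) NA_real_ else as.numeric(d)
    }, numeric(1)),
    type = vapply(tables, function(t) {
      ty <- attr(t, "type")
      if (is.null(ty)) NA_character_ else ty
    }, character(1))
  )
}

#' Match skipped-exon events across contrasts by canonical key
#'
#' Aligns several contrast tables (e.g. affected-vs-control plus one
#' treated-vs-control table per dose) into one wide table keyed by the
#' canonical event ID. With `require_all = TRUE` (inner join) only events
#' present in every contrast are kept; otherwise an outer join keeps all
#' events with explicit missing entries. Duplicate keys within any single
#' table are an error by default, since silently collapsing them would
#' corrupt downstream counts.
#'
#' @param tables Named list of event tables (from [read_jcec()] or
#'   [simulate_splicing_study()]); names become column prefixes.
#' @param require_all Keep only events present in every table (default).
#' @param keep_first Opt-in duplicate handling: keep the first occurrence
#'   of each duplicated key instead of raising an error.
#' @return A matched-event tibble with column `event_key` plus, per
#'   contrast `L`: `L.inc1`, `L.inc2` (list columns of replicate inclusion
#'   levels), `L.delta` (inclusion-level difference), `L.pvalue`, `L.fdr`.
#'   Rows are sorted by key, so the result is independent of input row and
#'   table order. Contrast metadata is kept in the `"contrasts"` attribute.
#' @export
match_events <- function(tables, require_all = TRUE, keep_first = FALSE) {
  if (!is.list(tables) || length(tables) < 2) {
    stop("need at least two contrast tables to match", call. = FALSE)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("contrast tables must be named", call. = FALSE)
  }
  meta <- contrast_meta(tables)
  slim <- purrr::imap(tables, function(tab, label) {
    key <- make_event_key(tab)
    dup <- duplicated(key)
    if (any(dup)) {
      if (!keep_first) {
        stop(
          "duplicate event key(s) in contrast '", label, "': ",
          paste(utils::head(unique(key[dup]), 5), collapse = "; "),
          if (length(unique(key[dup])) > 5) " ..." else "",
          call. = FALSE
        )
      }
      tab <- tab[!dup, ]
      key <- key[!dup]
    }
    out <- tibble::tibble(
      event_key = key,
      inc1 = tab$IncLevel1, inc2 = tab$IncLevel2,
      delta = tab$IncLevelDifference,
      pvalue = tab$PValue, fdr = tab$FDR
    )
    names(out)[-1] <- paste0(label, ".", names(out)[-1])
    out
  })
  join <- if (require_all) dplyr::inner_join else dplyr::full_join
  matched <- purrr::reduce(slim, join, by = "event_key")
  matched <- dplyr::arrange(matched, .data$event_key)
  attr(matched, "contrasts") <- meta
  matched
}

matched_contrasts <- function(matched) {
  meta <- attr(matched, "contrasts")
  if (is.null(meta)) {
    labels <- unique(sub("\\.(inc1|inc2|delta|pvalue|fdr)$", "",
                         setdiff(names(matched), "event_key")))
    meta <- tibble::tibble(label = labels, dose = NA_real_,
                           type = NA_character_)
  }
  meta
}

baseline_label <- function(matched) {
  meta <- matched_contrasts(matched)
  lab <- meta$label[!is.na(meta$type) & meta$type == "baseline"]
  if (length(lab) == 1) return(lab)
  if ("affected_vs_control" %in% meta$label) return("affected_vs_control")
  stop("cannot identify the baseline (affected-vs-control) contrast; ",
       "pass `baseline` explicitly", call. = FALSE)
}

#' Filter matched events on missing baseline replicates and variability
#'
#' Applies the two pre-analysis filters used before calling dysregulation:
#' rows with any missing replicate inclusion level in either baseline,
#' untreated group (control or affected) are removed, and rows whose
#' replicate PSI standard deviation within any baseline group exceeds
#' `sd_max` PSI units are removed. Removal counts are reported via
#' `message()` and kept in the `"filter_log"` attribute.
#'
#' @param matched A matched-event tibble from [match_events()].
#' @param sd_max Maximum within-group replicate PSI standard deviation
#'   (percent; default 20).
#' @param baseline Label of the affected-vs-control contrast; detected
#'   automatically for simulated studies.
#' @return The filtered matched tibble.
#' @export
filter_events <- function(matched, sd_max = 20,
                          baseline = baseline_label(matched)) {
  inc1 <- matched[[paste0(baseline, ".inc1")]]
  inc2 <- matched[[paste0(baseline, ".inc2")]]
  if (is.null(inc1) || is.null(inc2)) {
    stop("baseline contrast '", baseline, "' not present in matched table",
         call. = FALSE)
  }
  has_missing <- vapply(seq_along(inc1), function(i) {
    anyNA(inc1[[i]]) || anyNA(inc2[[i]]) ||
      length(inc1[[i]]) == 0 || length(inc2[[i]]) == 0
  }, logical(1))
  group_sd_psi <- function(x) {
    if (length(x) < 2) return(0)
    100 * stats::sd(x)
  }
  high_sd <- !has_missing & vapply(seq_along(inc1), function(i) {
    group_sd_psi(inc1[[i]]) > sd_max || group_sd_psi(inc2[[i]]) > sd_max
  }, logical(1))
  keep <- !has_missing & !high_sd
  out <- matched[keep, ]
  attr(out, "contrasts") <- attr(matched, "contrasts")
  attr(out, "filter_log") <- list(
    n_input = nrow(matched),
    n_missing_removed = sum(has_missing),
    n_sd_removed = sum(high_sd),
    n_kept = sum(keep)
  )
  message(sprintf(
    "filter_events: %d rows in; %d removed (missing baseline replicates), %d removed (group SD > %g PSI); %d kept",
    nrow(matched), sum(has_missing), sum(high_sd), sd_max, sum(keep)
  ))
  out
}

#' Call dysregulated events from the baseline contrast
#'
#' A skipped-exon event is dysregulated when the absolute inclusion-level
#' difference between affected and control groups is at least `delta_min`
#' (0--1 scale) and its FDR is at most `fdr_max`. FDR values are consumed
#' as reported by the upstream tool (or the simulator); they are never
#' recomputed here.
#'
#' @param matched A matched-event tibble, typically after [filter_events()].
#' @param delta_min Minimum absolute inclusion-level difference (default
#'   0.1, i.e. 10 PSI units).
#' @param fdr_max Maximum FDR (default 0.05).
#' @param baseline Label of the affected-vs-control contrast.
#' @return Tibble with `event_key`, `inc_level_difference`, `delta_psi`
#'   (PSI units), `fdr`, `is_dysregulated`.
#' @export
call_dysregulated <- function(matched, delta_min = 0.1, fdr_max = 0.05,
                              baseline = baseline_label(matched)) {
  delta <- matched[[paste0(baseline, ".delta")]]
  fdr <- matched[[paste0(baseline, ".fdr")]]
  if (is.null(delta) || is.null(fdr)) {
    stop("baseline contrast '", baseline, "' not present in matched table",
         call. = FALSE)
  }
  if (anyNA(fdr)) {
    stop("missing FDR for event(s): ",
         paste(utils::head(matched$event_key[is.na(fdr)], 5), collapse = "; "),
         call. = FALSE)
  }
  tibble::tibble(
    event_key = matched$event_key,
    inc_level_difference = delta,
    delta_psi = 100 * delta,
    fdr = fdr,
    is_dysregulated = !is.na(delta) & abs(delta) >= delta_min & fdr <= fdr_max
  )
}

#' Categorize treatment response of dysregulated events at every dose
#'
#' For each dysregulated event and each treated contrast, computes the
#' percent-rescue score from the group mean PSIs (control and affected
#' means from the baseline contrast, treated mean from the treated
#' contrast) and assigns the Rescue / MisRescue / NoChange category. Events
#' whose affected and control group means coincide have an undefined score;
#' they are excluded from categorization and counted separately, so that
#' `n_rescue + n_misrescue + n_nochange + n_unscorable` always equals the
#' number of dysregulated events.
#'
#' @param matched A matched-event tibble.
#' @param calls Output of [call_dysregulated()].
#' @param thresholds A [category_thresholds()] object.
#' @param baseline Label of the affected-vs-control contrast.
#' @return List with `categories` (tibble: `event_key`, `contrast`, `dose`,
#'   `score`, `category`, `scorable`) and `summary` (tibble per treated
#'   contrast: category counts, `n_unscorable`, `n_dysregulated`).
#' @export
classify_treatment_response <- function(matched, calls,
                                        thresholds = category_thresholds(),
                                        baseline = baseline_label(matched)) {
  meta <- matched_contrasts(matched)
  treated <- meta[meta$label != baseline, , drop = FALSE]
  if (nrow(treated) == 0) {
    stop("no treated contrasts present", call. = FALSE)
  }
  dys_keys <- calls$event_key[calls$is_dysregulated]
  rows <- matched$event_key %in% dys_keys
  sub <- matched[rows, ]

  group_mean_psi <- function(lst) {
    vapply(lst, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else 100 * mean(x)
    }, numeric(1))
  }
  aff_psi <- group_mean_psi(sub[[paste0(baseline, ".inc1")]])
  unaff_psi <- group_mean_psi(sub[[paste0(baseline, ".inc2")]])

  cats <- purrr::pmap(treated, function(label, dose, type) {
    trt_psi <- group_mean_psi(sub[[paste0(label, ".inc1")]])
    scorable <- !is.na(aff_psi) & !is.na(unaff_psi) & !is.na(trt_psi) &
      aff_psi != unaff_psi
    score <- rep(NA_real_, nrow(sub))
    if (any(scorable)) {
      score[scorable] <- splicing_rescue_score(
        aff_psi[scorable], unaff_psi[scorable], trt_psi[scorable],
        thresholds
      )$value
    }
    tibble::tibble(
      event_key = sub$event_key, contrast = label, dose = dose,
      score = score,
      category = categorize_score(score, thresholds),
      scorable = scorable
    )
  })
  categories <- dplyr::bind_rows(cats)

  summary <- categories |>
    dplyr::group_by(.data$contrast, .data$dose) |>
    dplyr::summarise(
      n_rescue = sum(.data$category == "Rescue", na.rm = TRUE),
      n_misrescue = sum(.data$category == "MisRescue", na.rm = TRUE),
      n_nochange = sum(.data$category == "NoChange", na.rm = TRUE),
      n_unscorable = sum(!.data$scorable),
      n_dysregulated = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dose)
  list(categories = categories, summary = summary)
}

#' Flag off-target splicing events
#'
#' Off-target events are those that did not meet the dysregulation
#' threshold at baseline (affected vs control) but changed significantly
#' under treatment: treated-vs-control FDR at most `fdr_max` and absolute
#' inclusion-level difference at least `delta_min` at some dose.
#'
#' @param matched A matched-event tibble.
#' @param calls Output of [call_dysregulated()].
#' @param delta_min,fdr_max Thresholds on the treated-vs-control contrast
#'   (defaults 0.1 and 0.05, the same as the dysregulation call).
#' @param baseline Label of the affected-vs-control contrast.
#' @return Tibble with one row per flagged event and dose: `event_key`,
#'   `contrast`, `dose`. `unique(out$event_key)` is the flagged set.
#' @export
flag_off_target <- function(matched, calls, delta_min = 0.1, fdr_max = 0.05,
                            baseline = baseline_label(matched)) {
  meta <- matched_contrasts(matched)
  treated <- meta[meta$label != baseline, , drop = FALSE]
  non_dys <- calls$event_key[!calls$is_dysregulated]
  rows <- matched$event_key %in% non_dys
  sub <- matched[rows, ]
  flagged <- purrr::pmap(treated, function(label, dose, type) {
    delta <- sub[[paste0(label, ".delta")]]
    fdr <- sub[[paste0(label, ".fdr")]]
    hit <- !is.na(delta) & !is.na(fdr) &
      abs(delta) >= delta_min & fdr <= fdr_max
    tibble::tibble(event_key = sub$event_key[hit], contrast = label,
                   dose = dose)
  })
  dplyr::bind_rows(flagged) |> dplyr::arrange(.data$event_key, .data$dose)
}
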