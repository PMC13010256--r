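jcec_required_cols <- c(
  "GeneID", "geneSymbol", "chr", "strand", "exonStart_0base", "exonEnd",
  "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
  "IncLevel1", "IncLevel2", "IncLevelDifference", "PValue", "FDR"
)

# "0.5,NA,0.4" -> c(0.5, NA, 0.4); anything unparseable is an error.
parse_inc_levels <- function(x, column) {
  lapply(seq_along(x), function(i) {
    if (is.na(x[i]) || x[i] == "") return(NA_real_)
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(ifelse(parts == "NA", NA, parts)))
    bad <- is.na(vals) & parts != "NA"
    if (any(bad)) {
      stop("format error in ", column, " row ", i, ": cannot parse '",
           x[i], "'", call. = FALSE)
    }
    out_of_range <- !is.na(vals) & (vals < 0 | vals > 1)
    if (any(out_of_range)) {
      stop("validation error in ", column, " row ", i,
           ": inclusion level outside [0, 1]", call. = FALSE)
    }
    vals
  })
}

format_inc_levels <- function(lst) {
  vapply(lst, function(v) {
    paste(ifelse(is.na(v), "NA", sprintf("%.15g", v)), collapse = ",")
  }, character(1))
}

validate_jcec_rows <- function(tab) {
  bad_rows <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop("validation error (", msg, ") at data row(s) ",
           paste(utils::head(idx, 10), collapse = ", "),
           if (length(idx) > 10) " ..." else "",
           call. = FALSE)
    }
  }
  bad_rows(!tab$strand %in% c("+", "-"), "strand must be + or -")
  bad_rows(tab$exonStart_0base >= tab$exonEnd, "exonStart_0base >= exonEnd")
  bad_rows(tab$upstreamES >= tab$upstreamEE, "upstreamES >= upstreamEE")
  bad_rows(tab$downstreamES >= tab$downstreamEE, "downstreamES >= downstreamEE")
  bad_rows(tab$upstreamEE > tab$exonStart_0base, "upstream exon overlaps cassette exon")
  bad_rows(tab$exonEnd > tab$downstreamES, "cassette exon overlaps downstream exon")
  in01 <- function(x) !is.na(x) & (x < 0 | x > 1)
  bad_rows(in01(tab$PValue), "PValue outside [0, 1]")
  bad_rows(in01(tab$FDR), "FDR outside [0, 1]")
  bad_rows(!is.na(tab$IncLevelDifference) &
             abs(tab$IncLevelDifference) > 1,
           "IncLevelDifference outside [-1, 1]")
  invisible(tab)
}

#' Read an rMATS-style JCEC skipped-exon table
#'
#' Parses the tab-separated skipped-exon output dialect of rMATS-turbo
#' (JCEC counting). The required columns are the coordinate, identifier,
#' per-replicate inclusion-level (`IncLevel1`/`IncLevel2`,
#' comma-separated with `NA` for missing replicates), inclusion-level
#' difference, p-value and FDR columns; extra columns are ignored.
#' Every row is validated (coordinate ordering, bounded inclusion levels
#' and probabilities) and failures are reported with row numbers — rows
#' are never silently dropped.
#'
#' @param path Path to the TSV file.
#' @param contrast_label Label to attach to the table (defaults to the file
#'   name without extension).
#' @param dose Optional dose (nM) of the treated arm of the contrast.
#' @param type `"baseline"` or `"treated"`.
#' @param keep_first Deduplicate repeated canonical event keys by keeping
#'   the first row instead of raising an error.
#' @return An event table (tibble) with list columns `IncLevel1` and
#'   `IncLevel2`, carrying `contrast`, `dose` and `type` attributes.
#' @export
read_jcec <- function(path, contrast_label = NULL, dose = NA_real_,
                      type = c("baseline", "treated"), keep_first = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_tsv(
    path, n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  missing_cols <- setdiff(jcec_required_cols, header)
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      GeneID = readr::col_character(),
      geneSymbol = readr::col_character(),
      chr = readr::col_character(),
      strand = readr::col_character(),
      exonStart_0base = readr::col_double(),
      exonEnd = readr::col_double(),
      upstreamES = readr::col_double(),
      upstreamEE = readr::col_double(),
      downstreamES = readr::col_double(),
      downstreamEE = readr::col_double(),
      IncLevel1 = readr::col_character(),
      IncLevel2 = readr::col_character(),
      IncLevelDifference = readr::col_double(),
      PValue = readr::col_double(),
      FDR = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  tab <- raw[, jcec_required_cols]
  tab$IncLevel1 <- parse_inc_levels(raw$IncLevel1, "IncLevel1")
  tab$IncLevel2 <- parse_inc_levels(raw$IncLevel2, "IncLevel2")
  validate_jcec_rows(tab)
  key <- make_event_key(tab)
  dup <- duplicated(key)
  if (any(dup)) {
    if (!keep_first) {
      stop("duplicate event key(s) in ", path, ": ",
           paste(utils::head(unique(key[dup]), 5), collapse = "; "),
           call. = FALSE)
    }
    tab <- tab[!dup, ]
  }
  if (is.null(contrast_label)) {
    contrast_label <- sub("\\.[^.]*$", "", basename(path))
  }
  message(sprintf("read_jcec: %d events from %s", nrow(tab), path))
  new_event_table(tab, contrast = contrast_label, dose = dose, type = type)
}

#' Write an event table as rMATS-style JCEC TSV
#'
#' Inverse of [read_jcec()]: replicate inclusion levels are serialized as
#' comma-separated lists with missing replicates written as `NA`. Writing
#' and re-reading a valid table reproduces it field by field.
#'
#' @param table An event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jcec <- function(table, path) {
  out <- tibble::as_tibble(table[, jcec_required_cols])
  out$IncLevel1 <- format_inc_levels(table$IncLevel1)
  out$IncLevel2 <- format_inc_levels(table$IncLevel2)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_validated_csv <- function(path, col_types, nonneg = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(
    path, n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  required <- names(col_types$cols)
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  tab <- readr::read_csv(path, col_types = col_types, progress = FALSE,
                         show_col_types = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop("validation error: non-numeric or malformed cell(s) in ", path,
         " at row(s) ", paste(utils::head(probs$row, 10), collapse = ", "),
         call. = FALSE)
  }
  for (col in nonneg) {
    bad <- which(!is.na(tab[[col]]) & tab[[col]] < 0)
    if (length(bad) > 0) {
      stop("validation error: negative ", col, " at row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  tab
}

#' Read a capillary-electrophoresis isoform RFU table
#'
#' CSV with columns `event_id`, `sample_id`, `inclusion_rfu`,
#' `exclusion_rfu` (extra columns preserved). Negative RFU values and
#' non-numeric cells are validation errors.
#'
#' @param path Path to the CSV file.
#' @return Validated tibble.
#' @export
read_isoform_table <- function(path) {
  read_validated_csv(
    path,
    readr::cols(
      event_id = readr::col_character(),
      sample_id = readr::col_character(),
      inclusion_rfu = readr::col_double(),
      exclusion_rfu = readr::col_double(),
      .default = readr::col_guess()
    ),
    nonneg = c("inclusion_rfu", "exclusion_rfu")
  )
}

#' Read a normalized gene-expression matrix
#'
#' CSV with a `gene` column followed by one numeric column per sample.
#' Negative expression values are validation errors.
#'
#' @param path Path to the CSV file.
#' @return Tibble (genes in rows, samples in columns).
#' @export
read_expression_matrix <- function(path) {
  tab <- read_validated_csv(
    path, readr::cols(gene = readr::col_character(),
                      .default = readr::col_double())
  )
  sample_cols <- setdiff(names(tab), "gene")
  for (col in sample_cols) {
    bad <- which(!is.na(tab[[col]]) & tab[[col]] < 0)
    if (length(bad) > 0) {
      stop("validation error: negative expression in column '", col,
           "' at row(s) ", paste(utils::head(bad, 10), collapse = ", "),
           call. = FALSE)
    }
  }
  tab
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample_id`, `group`, `target_ct`, `reference_ct`.
#'
#' @param path Path to the CSV file.
#' @return Validated tibble.
#' @export
read_ct_table <- function(path) {
  read_validated_csv(
    path,
    readr::cols(
      sample_id = readr::col_character(),
      group = readr::col_character(),
      target_ct = readr::col_double(),
      reference_ct = readr::col_double(),
      .default = readr::col_guess()
    )
  )
}

#' Read a fluorescence indicator displacement series
#'
#' CSV with columns `concentration_um`, `fluorescence`, `f0`. Negative
#' fluorescence or concentration values are validation errors.
#'
#' @param path Path to the CSV file.
#' @return Validated tibble.
#' @export
read_fid_series <- function(path) {
  read_validated_csv(
    path,
    readr::cols(
      concentration_um = readr::col_double(),
      fluorescence = readr::col_double(),
      f0 = readr::col_double(),
      .default = readr::col_guess()
    ),
    nonneg = c("concentration_um", "fluorescence")
  )
}

#' Write an assay table as CSV
#'
#' Thin wrapper over [readr::write_csv()] so that every assay table
#' round-trips through the matching reader.
#'
#' @param table Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
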