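#' Read genomic intervals from BED, bedGraph or RepeatMasker files
#'
#' All dialects are normalised to the package-wide coordinate convention:
#' 0-based, half-open `[start, end)`.  BED and bedGraph are already 0-based
#' half-open and pass through unchanged; RepeatMasker `.out` coordinates are
#' 1-based inclusive and are shifted exactly once at parse time.
#'
#' @param path Path to the file.
#' @param dialect One of `"bed"` (3+ columns: chrom, start, end, optional
#'   name / score / strand), `"bedgraph"` (chrom, start, end, value) or
#'   `"repeatmasker"` (whitespace-delimited `.out` table; the class part of
#'   the class/family column, before any `/`, becomes `repeat_class`).
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `strand`,
#'   `value`, plus `repeat_class` for the repeatmasker dialect.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrX\t100\t300\tcpg1", bed)
#' read_intervals(bed, "bed")
#' @export
read_intervals <- function(path, dialect = c("bed", "bedgraph", "repeatmasker")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dialect <- tryCatch(match.arg(dialect),
    error = function(e) abort(paste0("unknown dialect: ", dialect[1]))
  )
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), strand = character(), value = double()
    )
    if (dialect == "repeatmasker") out$repeat_class <- character()
    return(out)
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")

  bad_line <- function(i, why) {
    abort(paste0("malformed ", dialect, " line ", idx[i], " in ", path, ": ", why))
  }
  as_coord <- function(x, i, what) {
    v <- suppressWarnings(as.integer(x))
    if (is.na(v)) bad_line(i, paste0("non-integer ", what, " '", x, "'"))
    v
  }

  if (dialect == "repeatmasker") {
    # drop the .out header rows (first field is not a numeric SW score)
    is_data <- vapply(fields, function(f) {
      length(f) >= 11 && !is.na(suppressWarnings(as.numeric(f[1])))
    }, logical(1))
    header_like <- vapply(fields, function(f) {
      is.na(suppressWarnings(as.numeric(f[1])))
    }, logical(1))
    if (any(!is_data & !header_like)) {
      i <- which(!is_data & !header_like)[1]
      bad_line(i, "expected at least 11 whitespace-delimited columns")
    }
    fields <- fields[is_data]
    idx <- idx[is_data]
    rows <- purrr::imap(fields, function(f, i) {
      start1 <- as_coord(f[6], i, "start")
      end1 <- as_coord(f[7], i, "end")
      tibble(
        chrom = f[5],
        start = start1 - 1L, # 1-based inclusive -> 0-based half-open
        end = end1,
        name = f[10],
        strand = if (f[9] == "C") "-" else "+",
        value = suppressWarnings(as.numeric(f[1])),
        repeat_class = strsplit(f[11], "/", fixed = TRUE)[[1]][1]
      )
    })
    out <- bind_rows(rows)
  } else {
    min_cols <- if (dialect == "bedgraph") 4L else 3L
    rows <- purrr::imap(fields, function(f, i) {
      if (length(f) < min_cols) {
        bad_line(i, paste0("expected at least ", min_cols, " columns, got ", length(f)))
      }
      start <- as_coord(f[2], i, "start")
      end <- as_coord(f[3], i, "end")
      if (dialect == "bedgraph") {
        value <- suppressWarnings(as.numeric(f[4]))
        if (is.na(value)) bad_line(i, paste0("non-numeric value '", f[4], "'"))
        name <- NA_character_
        strand <- NA_character_
      } else {
        value <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
        name <- if (length(f) >= 4) f[4] else NA_character_
        strand <- if (length(f) >= 6) f[6] else NA_character_
      }
      tibble(
        chrom = f[1], start = start, end = end,
        name = name, strand = strand, value = value
      )
    })
    out <- bind_rows(rows)
  }

  bad <- which(!(out$start >= 0 & out$start < out$end) | !nzchar(out$chrom))
  if (length(bad) > 0) {
    abort(paste0(
      "malformed ", dialect, " line ", idx[bad[1]], " in ", path,
      ": require 0 <= start < end and non-empty chrom"
    ))
  }
  out
}

#' Read a 450k-style probe table
#'
#' Expects a TSV with columns `probe_id`, `chrom`, `position` (0-based),
#' `island` (annotated CpG island name, may be empty), `promoter`
#' (TRUE/FALSE promoter-associated flag), followed by one beta-value column
#' per sample.  Non-promoter probes are retained but flagged; missing betas
#' stay missing and are excluded from island means downstream, never imputed.
#'
#' @param path Path to the TSV.
#' @param promoter_values Character values of the `promoter` column accepted
#'   as promoter-associated (the annotation vocabulary differs between
#'   manifests, so it is configurable).
#'
#' @return A long tibble with columns `probe_id`, `chrom`, `position`,
#'   `island`, `promoter`, `sample`, `beta`.
#' @export
read_probe_table <- function(path,
                             promoter_values = c("TRUE", "Promoter_Associated")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("probe_id", "chrom", "position", "island", "promoter")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("probe table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  sample_cols <- setdiff(names(tab), need)
  if (length(sample_cols) == 0) abort("probe table has no sample columns")
  if (anyDuplicated(tab$probe_id)) {
    abort(paste0("duplicate probe_id: ", tab$probe_id[duplicated(tab$probe_id)][1]))
  }
  out <- tab |>
    mutate(promoter = as.character(.data$promoter) %in% promoter_values) |>
    tidyr::pivot_longer(all_of(sample_cols), names_to = "sample", values_to = "beta") |>
    mutate(beta = suppressWarnings(as.numeric(.data$beta)))
  bad <- which(!is.na(out$beta) & (out$beta < 0 | out$beta > 1))
  if (length(bad) > 0) {
    abort(paste0(
      "beta value outside [0, 1] for probe ", out$probe_id[bad[1]],
      " sample ", out$sample[bad[1]], ": ", out$beta[bad[1]]
    ))
  }
  out
}

call_table_cols <- c(
  "gene", "species", "dataset", "status", "reason",
  "n_informative", "fraction_escape", "fraction_subject"
)

#' Write and read XCI call tables
#'
#' Call tables are TSVs with the fixed column order `gene`, `species`,
#' `dataset`, `status`, `reason`, `n_informative`, `fraction_escape`,
#' `fraction_subject`.  `read_call_table(write_call_table(x))` is the
#' identity, including `no_call` reasons.  Leading `#` comment lines (used
#' for config-hash headers) are ignored on read.
#'
#' @param calls A call-table tibble (e.g. from [call_genes_allelic()] or
#'   [call_genes_methylation()]).
#' @param path Output (or input) TSV path.
#' @param comment Optional character vector of header comment lines to
#'   prepend, each written prefixed with `"# "`.
#'
#' @return `write_call_table()` returns `path` invisibly;
#'   `read_call_table()` returns the call-table tibble.
#' @export
write_call_table <- function(calls, path, comment = NULL) {
  missing_cols <- setdiff(call_table_cols, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("call table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  calls <- calls[, call_table_cols]
  check_status(calls$status)
  if (!is.null(comment)) {
    writeLines(paste("#", comment), path)
    readr::write_tsv(calls, path, na = "", append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(calls, path, na = "")
  }
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(
    path,
    comment = "#", na = "", show_col_types = FALSE,
    col_types = readr::cols(
      gene = readr::col_character(),
      species = readr::col_character(),
      dataset = readr::col_character(),
      status = readr::col_character(),
      reason = readr::col_character(),
      n_informative = readr::col_integer(),
      fraction_escape = readr::col_double(),
      fraction_subject = readr::col_double()
    )
  )
  missing_cols <- setdiff(call_table_cols, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("call table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check_status(tab$status)
  tab
}

# strict status vocabulary; anything else (including case changes) is an error
check_status <- function(status) {
  bad <- setdiff(unique(status), .xci_statuses)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0) {
    abort(paste0(
      "unknown XCI status: '", bad[1], "' (expected one of ",
      paste(.xci_statuses, collapse = ", "), ")"
    ))
  }
  invisible(status)
}

# overlap join helper: returns indices of `query` rows vs `subject` rows that
# overlap on [start, end), chromosome-aware.  Thin wrapper over IRanges.
overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  stopifnot(length(q_chrom) == length(q_start), length(s_chrom) == length(s_start))
  if (length(q_chrom) == 0 || length(s_chrom) == 0) {
    return(tibble(q = integer(), s = integer()))
  }
  res <- purrr::map(unique(q_chrom), function(ch) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (length(qi) == 0 || length(si) == 0) {
      return(tibble(q = integer(), s = integer()))
    }
    # half-open [start, end) -> closed integer ranges [start, end - 1]
    qr <- IRanges::IRanges(start = q_start[qi], end = q_end[qi] - 1L)
    sr <- IRanges::IRanges(start = s_start[si], end = s_end[si] - 1L)
    hits <- IRanges::findOverlaps(qr, sr)
    tibble(
      q = qi[S4Vectors::queryHits(hits)],
      s = si[S4Vectors::subjectHits(hits)]
    )
  })
  bind_rows(res)
}
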