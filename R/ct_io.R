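#' Read a Ct table
#'
#' Reads raw Ct values exported as plain text, in either layout:
#' \describe{
#'   \item{long}{columns `assay`, `sample`, `ct` and optionally
#'     `replicate`.}
#'   \item{wide}{first column `assay`, one column per sample (single
#'     replicate only).}
#' }
#' Cells that are empty or match one of `nd_tokens` (the instrument
#' software's "Undetermined" marker, by default) are read as non-detected;
#' any other non-numeric Ct is an error. Detected values at or above `lod`
#' are coerced to non-detected.
#'
#' @param path file path. Separator is sniffed from the extension
#'   (`.csv` = comma, anything else = tab) unless `sep` is given.
#' @param format `"long"` or `"wide"`.
#' @param sep field separator; overrides extension sniffing.
#' @param lod detection cutoff in cycles (default 40).
#' @param nd_tokens character vector of tokens meaning non-detected.
#' @return a [ct_matrix].
#' @export
read_ct_table <- function(path, format = c("long", "wide"), sep = NULL,
                          lod = 40,
                          nd_tokens = c("Undetermined", "undetermined",
                                        "ND", "NA", "")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  raw <- readr::read_delim(path, delim = sep, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), trim_ws = TRUE, progress = FALSE,
  show_col_types = FALSE)

  if (format == "long") {
    need <- c("assay", "sample", "ct")
    if (!all(need %in% names(raw))) {
      stop("long Ct table needs columns assay, sample, ct")
    }
    raw$ct <- parse_ct(raw$ct, nd_tokens)
    ct_matrix(raw[intersect(c("assay", "sample", "replicate", "ct"),
                            names(raw))], lod = lod)
  } else {
    if (names(raw)[1] != "assay") {
      stop("wide Ct table must have `assay` as its first column")
    }
    long <- tidyr::pivot_longer(raw, -"assay", names_to = "sample",
                                values_to = "ct")
    long$ct <- parse_ct(long$ct, nd_tokens)
    ct_matrix(long, lod = lod, samples = setdiff(names(raw), "assay"))
  }
}

parse_ct <- function(x, nd_tokens) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  is_nd <- is.na(x) | x %in% nd_tokens
  num <- suppressWarnings(as.numeric(x[!is_nd]))
  if (anyNA(num)) {
    bad <- unique(x[!is_nd][is.na(num)])
    stop("non-numeric Ct value(s) not in the non-detected token set: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out[!is_nd] <- num
  out
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Ct table
#'
#' Inverse of [read_ct_table()]: non-detected wells are written as
#' `nd_token`, detected Ct values at full precision so a write/read
#' round-trip reproduces the matrix cell for cell.
#'
#' @param x a [ct_matrix].
#' @param path output path; separator sniffed from the extension unless
#'   `sep` is given.
#' @param format `"long"` or `"wide"` (wide requires a single replicate).
#' @param sep field separator.
#' @param nd_token token written for non-detected wells.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, format = c("long", "wide"), sep = NULL,
                           nd_token = "Undetermined") {
  stopifnot(inherits(x, "ct_matrix"))
  format <- match.arg(format)
  sep <- sep %||% sniff_sep(path)
  fmt_num <- function(v) ifelse(is.na(v), nd_token, formatC(v, digits = 17,
                                                            format = "g"))
  if (format == "long") {
    out <- x$data
    out$ct <- fmt_num(out$ct)
    readr::write_delim(out, path, delim = sep, progress = FALSE)
  } else {
    if (x$replicates > 1) {
      stop("wide format cannot represent replicated wells; aggregate first")
    }
    wide <- tidyr::pivot_wider(x$data[, c("assay", "sample", "ct")],
                               names_from = "sample", values_from = "ct")
    wide <- wide[match(x$assays, wide$assay),
                 c("assay", x$samples)]
    wide[-1] <- lapply(wide[-1], fmt_num)
    readr::write_delim(wide, path, delim = sep, progress = FALSE)
  }
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with columns `sample_id`, `group` (`endometriosis`/`control`) and
#' `calibrator` (logical; exactly one `TRUE`).
#'
#' @param path file path.
#' @return [read_sample_sheet()]: a [sample_sheet()] tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    calibrator = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
  sample_sheet(raw$sample_id, raw$group, raw$calibrator)
}

#' @param sheet a [sample_sheet()] tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(tibble::as_tibble(sheet), path, progress = FALSE)
  invisible(path)
}

#' Read / write a panel definition
#'
#' JSON object `{"assays": [...], "endogenous_controls": [...],
#' "replicates": n}`.
#'
#' @param path file path.
#' @return [read_panel()]: a [panel_def()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel_def(x$assays, x$endogenous_controls, x$replicates %||% 1L)
}

#' @param panel a [panel_def()].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cross-validate a Ct matrix, sample sheet and panel definition
#'
#' Checks that the three inputs describe the same experiment: every sheet
#' sample has wells in the Ct matrix and vice versa, panel assays are
#' present, replicate counts agree, and at least one endogenous-control
#' assay is measured. A missing endogenous control is a hard error because
#' normalization is impossible without it; all other mismatches are
#' collected as violations.
#'
#' @param ct a [ct_matrix].
#' @param sheet a [sample_sheet()].
#' @param panel a [panel_def()].
#' @return a list with elements `ok` (logical), `violations` (character)
#'   and the three validated inputs.
#' @export
validate_inputs <- function(ct, sheet, panel) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(panel, "panel_def"))
  if (!all(panel$endogenous_controls %in% ct$assays)) {
    miss <- setdiff(panel$endogenous_controls, ct$assays)
    stop("endogenous-control assay(s) absent from the Ct matrix: ",
         paste(miss, collapse = ", "), " — normalization impossible")
  }
  v <- character()
  miss_s <- setdiff(sheet$sample_id, ct$samples)
  if (length(miss_s) > 0) {
    v <- c(v, paste0("sample sheet sample(s) absent from Ct matrix: ",
                     paste(miss_s, collapse = ", ")))
  }
  extra_s <- setdiff(ct$samples, sheet$sample_id)
  if (length(extra_s) > 0) {
    v <- c(v, paste0("Ct matrix sample(s) absent from sample sheet: ",
                     paste(extra_s, collapse = ", ")))
  }
  miss_a <- setdiff(panel$assays, ct$assays)
  if (length(miss_a) > 0) {
    v <- c(v, paste0("panel assay(s) absent from Ct matrix: ",
                     paste(miss_a, collapse = ", ")))
  }
  if (ct$replicates != panel$replicates) {
    v <- c(v, paste0("replicate mismatch: Ct matrix has ", ct$replicates,
                     ", panel declares ", panel$replicates))
  }
  list(ok = length(v) == 0, violations = v, ct = ct, sheet = sheet,
       panel = panel)
}

#' Write / read a screening report
#'
#' Writes the per-assay screening records (group statistics, signed
#' fold-changes, Welch p-value, differential-expression call and
#' confidence tier) as a TSV. With `digits = NULL` numbers are written at
#' full precision and [read_screen_report()] reproduces the records
#' exactly; a small `digits` gives a human-readable table.
#'
#' @param records a screening record tibble from [run_screen()].
#' @param path output path.
#' @param digits decimal places for numeric columns, or `NULL` for full
#'   precision.
#' @return `path` invisibly; [read_screen_report()] returns the tibble.
#' @export
write_screen_report <- function(records, path, digits = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  out <- tibble::as_tibble(records)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) {
      ifelse(is.na(v), NA_character_,
             format(round(v, digits), trim = TRUE, scientific = FALSE))
    })
  } else {
    num <- vapply(out, is.numeric, logical(1)) &
      !vapply(out, is.integer, logical(1))
    out[num] <- lapply(out[num], function(v) {
      ifelse(is.na(v), NA_character_, formatC(v, digits = 17, format = "g"))
    })
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readr::read_tsv(path, col_types = readr::cols(
    assay = readr::col_character(),
    de_call = readr::col_logical(),
    tier = readr::col_character(),
    n_endometriosis = readr::col_integer(),
    n_control = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
}

#' Write a flag report
#'
#' TSV with one row per assay and group: detection counts (`values`,
#' `nd`) and within-sample expression-strength counts (`good`, `normal`,
#' `low`).
#'
#' @param fs flag summary tibble from [flag_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flag_report <- function(fs, path) {
  readr::write_tsv(tibble::as_tibble(fs), path, progress = FALSE)
  invisible(path)
}

#' Write a validation report
#'
#' TSV mirroring a median-RQ validation table: per assay, the group
#' medians with min-max ranges (both numeric and as a formatted
#' `"median (min-max)"` string), the Mann-Whitney U and p-value, and the
#' significance call.
#'
#' @param records validation record tibble from [run_validation()].
#' @param path output path (TSV). A sibling `.json` is written when
#'   `json = TRUE`.
#' @param json also write a machine-readable JSON next to the TSV.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(records, path, json = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  readr::write_tsv(tibble::as_tibble(records), path, progress = FALSE)
  if (json) {
    jpath <- sub("\\.[^.]+$", ".json", path)
    if (identical(jpath, path)) jpath <- paste0(path, ".json")
    jsonlite::write_json(records, jpath, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
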