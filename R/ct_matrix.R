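#' Ct matrix container
#'
#' A `ct_matrix` holds raw cycle-threshold (Ct) values from a low-density
#' qPCR array: one value per (assay, sample, replicate) well, with an
#' explicit non-detected state. Non-detection is represented as `NA`; any
#' finite Ct at or above the detection cutoff `lod` is coerced to
#' non-detected at construction time, so the coercion is idempotent.
#'
#' @param data a data frame with columns `assay`, `sample`, `ct` and
#'   optionally `replicate` (defaults to 1). `ct` may be `NA` for
#'   non-detected wells.
#' @param lod detection cutoff in cycles; detected Ct values must lie below
#'   it. Wells with `ct >= lod` become non-detected. Default 40, the cycle
#'   count of a standard 40-cycle run.
#' @param assays,samples optional character vectors fixing assay/sample
#'   order; defaults to order of first appearance in `data`.
#'
#' @return an object of class `ct_matrix`: a list with elements `data`
#'   (tibble `assay`, `sample`, `replicate`, `ct`), `assays`, `samples`,
#'   `replicates` (max replicate index) and `lod`. The grid is complete:
#'   every assay x sample x replicate combination has exactly one row,
#'   missing combinations are filled in as non-detected.
#' @export
ct_matrix <- function(data, lod = 40, assays = NULL, samples = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("assay", "sample", "ct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("ct data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- tibble::as_tibble(data)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  data$assay <- as.character(data$assay)
  data$sample <- as.character(data$sample)
  data$replicate <- as.integer(data$replicate)
  data$ct <- as.numeric(data$ct)

  dup <- duplicated(data[, c("assay", "sample", "replicate")])
  if (any(dup)) {
    bad <- data[dup, c("assay", "sample", "replicate")][1, ]
    stop("duplicate well: assay=", bad$assay, " sample=", bad$sample,
         " replicate=", bad$replicate)
  }
  det <- !is.na(data$ct)
  if (any(det & (!is.finite(data$ct) | data$ct <= 0))) {
    stop("detected Ct values must be finite and > 0")
  }
  if (!is.numeric(lod) || length(lod) != 1 || lod <= 0) {
    stop("`lod` must be a single positive number")
  }
  data$ct[det & data$ct >= lod] <- NA_real_

  if (is.null(assays)) assays <- unique(data$assay)
  if (is.null(samples)) samples <- unique(data$sample)
  stopifnot(!anyDuplicated(assays), !anyDuplicated(samples))
  if (!all(data$assay %in% assays)) stop("data contains assays not in `assays`")
  if (!all(data$sample %in% samples)) stop("data contains samples not in `samples`")

  replicates <- sort(unique(data$replicate))
  grid <- tidyr::expand_grid(
    assay = assays, sample = samples, replicate = replicates
  )
  data <- dplyr::left_join(grid, data,
                           by = c("assay", "sample", "replicate"))

  structure(
    list(data = data, assays = assays, samples = samples,
         replicates = max(replicates), lod = lod),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  nd <- sum(is.na(x$data$ct))
  cat("<ct_matrix> ", length(x$assays), " assays x ", length(x$samples),
      " samples x ", x$replicates, " replicate(s); ",
      nd, "/", nrow(x$data), " wells non-detected (lod ", x$lod, ")\n",
      sep = "")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) {
  c(length(x$assays), length(x$samples), x$replicates)
}

#' Test two Ct matrices for cell-for-cell equality
#'
#' Compares assay/sample/replicate structure and all Ct values (treating
#' two non-detected cells as equal).
#'
#' @param a,b `ct_matrix` objects.
#' @param tol numeric tolerance on detected Ct values.
#' @return `TRUE` or `FALSE`.
#' @export
ct_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$assays, b$assays)) return(FALSE)
  if (!identical(a$samples, b$samples)) return(FALSE)
  key <- c("assay", "sample", "replicate")
  da <- dplyr::arrange(a$data, .data$assay, .data$sample, .data$replicate)
  db <- dplyr::arrange(b$data, .data$assay, .data$sample, .data$replicate)
  if (nrow(da) != nrow(db)) return(FALSE)
  if (!identical(da[key], db[key])) return(FALSE)
  same_na <- is.na(da$ct) == is.na(db$ct)
  ok <- is.na(da$ct) | is.na(db$ct) | abs(da$ct - db$ct) <= tol
  all(same_na) && all(ok | is.na(ok))
}

#' Sample sheet constructor
#'
#' Describes the samples of a two-group case/control qPCR study: group
#' membership (`endometriosis` vs `control`) and the single calibrator
#' sample that anchors the delta-delta-Ct computation.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector, each `"endometriosis"` or `"control"`.
#' @param calibrator logical vector with exactly one `TRUE`.
#' @return a tibble of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, group, calibrator) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  calibrator <- as.logical(calibrator)
  stopifnot(length(sample_id) == length(group),
            length(sample_id) == length(calibrator))
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  bad <- setdiff(unique(group), c("endometriosis", "control"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'endometriosis' or 'control')")
  }
  if (!all(c("endometriosis", "control") %in% group)) {
    stop("both groups must be non-empty")
  }
  if (anyNA(calibrator) || sum(calibrator) != 1) {
    stop("exactly one sample must be marked as calibrator")
  }
  out <- tibble::tibble(sample_id = sample_id, group = group,
                        calibrator = calibrator)
  class(out) <- c("sample_sheet", class(out))
  out
}

#' Panel definition constructor
#'
#' @param assays character vector of assay ids on the card.
#' @param endogenous_controls character vector of endogenous-control assay
#'   ids (e.g. the MammU6/RNU6B wells); must be a non-empty subset of
#'   `assays`.
#' @param replicates technical replicates per assay (1 for the discovery
#'   cards, 3 for the custom validation card).
#' @return a list of class `panel_def`.
#' @export
panel_def <- function(assays, endogenous_controls, replicates = 1L) {
  assays <- as.character(assays)
  endogenous_controls <- as.character(endogenous_controls)
  replicates <- as.integer(replicates)
  if (anyDuplicated(assays)) stop("panel assay ids must be unique")
  if (length(endogenous_controls) < 1) {
    stop("panel must declare at least one endogenous-control assay")
  }
  if (!all(endogenous_controls %in% assays)) {
    stop("endogenous controls must be a subset of panel assays")
  }
  if (length(replicates) != 1 || is.na(replicates) || replicates < 1) {
    stop("`replicates` must be a single integer >= 1")
  }
  structure(
    list(assays = assays, endogenous_controls = endogenous_controls,
         replicates = replicates),
    class = "panel_def"
  )
}

#' @export
print.panel_def <- function(x, ...) {
  cat("<panel_def> ", length(x$assays), " assays (",
      length(x$endogenous_controls), " endogenous control(s)), ",
      x$replicates, " replicate(s)/assay\n", sep = "")
  invisible(x)
}
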