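#' Aggregate technical replicates
#'
#' Collapses the replicate dimension of a Ct matrix: per (assay, sample)
#' the mean (or median) Ct of the detected replicates; non-detected only
#' if all replicates are non-detected. The identity when the matrix has a
#' single replicate.
#'
#' @param ct a [ct_matrix].
#' @param method `"mean"` (default) or `"median"`.
#' @return a [ct_matrix] with one replicate.
#' @export
aggregate_replicates <- function(ct, method = c("mean", "median")) {
  stopifnot(inherits(ct, "ct_matrix"))
  method <- match.arg(method)
  if (ct$replicates == 1) return(ct)
  fun <- if (method == "mean") mean else stats::median
  agg <- dplyr::summarise(
    dplyr::group_by(ct$data, .data$assay, .data$sample),
    ct = if (all(is.na(.data$ct))) NA_real_ else
      fun(.data$ct[!is.na(.data$ct)]),
    .groups = "drop"
  )
  ct_matrix(agg, lod = ct$lod, assays = ct$assays, samples = ct$samples)
}

#' Delta-Ct normalization against the endogenous control
#'
#' For each sample, subtracts the aggregate (mean by default) Ct of that
#' sample's detected endogenous-control wells from every target assay's
#' Ct: \eqn{\Delta Ct_{ij} = Ct_{ij} - \overline{Ct}^{EC}_{j}}. This
#' removes per-sample loading differences. Endogenous-control assays are
#' consumed by the normalization and do not appear in the output.
#' Replicated matrices are aggregated with [aggregate_replicates()] first.
#'
#' @param ct a [ct_matrix].
#' @param panel a [panel_def()] naming the endogenous-control assays.
#' @param ec_aggregate `"mean"` (default) or `"median"` across detected
#'   endogenous-control wells.
#' @param replicate_aggregate passed to [aggregate_replicates()].
#' @return a tibble `assay`, `sample`, `dct` (`NA` where the raw well was
#'   non-detected), with attribute `ec_ct` (the per-sample EC aggregate).
#' @export
delta_ct <- function(ct, panel, ec_aggregate = c("mean", "median"),
                     replicate_aggregate = c("mean", "median")) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(panel, "panel_def"))
  ec_aggregate <- match.arg(ec_aggregate)
  ct <- aggregate_replicates(ct, match.arg(replicate_aggregate))
  ec_ids <- panel$endogenous_controls
  if (!all(ec_ids %in% ct$assays)) {
    stop("endogenous-control assay(s) missing from the Ct matrix: ",
         paste(setdiff(ec_ids, ct$assays), collapse = ", "))
  }
  fun <- if (ec_aggregate == "mean") mean else stats::median
  ec <- dplyr::summarise(
    dplyr::group_by(ct$data[ct$data$assay %in% ec_ids, ], .data$sample),
    ec_ct = if (all(is.na(.data$ct))) NA_real_ else
      fun(.data$ct[!is.na(.data$ct)]),
    .groups = "drop"
  )
  if (anyNA(ec$ec_ct)) {
    bad <- ec$sample[is.na(ec$ec_ct)]
    stop("no detected endogenous-control well in sample(s): ",
         paste(bad, collapse = ", "))
  }
  targets <- ct$data[!ct$data$assay %in% ec_ids,
                     c("assay", "sample", "ct")]
  out <- dplyr::left_join(targets, ec, by = "sample")
  out$dct <- out$ct - out$ec_ct
  res <- tibble::as_tibble(out[, c("assay", "sample", "dct")])
  attr(res, "ec_ct") <- ec
  res
}

#' Delta-delta-Ct and relative quantities
#'
#' Anchors each assay's delta-Ct at the calibrator sample:
#' \eqn{\Delta\Delta Ct_{ij} = \Delta Ct_{ij} - \Delta Ct_{i,cal}}, and
#' converts to relative quantity \eqn{RQ = 2^{-\Delta\Delta Ct}} assuming
#' perfect doubling per cycle. Under `calibrator = "sample"` (default)
#' the anchor is the sheet's designated calibrator sample; under
#' `"control_mean"` it is the mean delta-Ct of the control group per
#' assay (over detected samples).
#'
#' Assays not detected in the calibrator have no anchor: their rows are
#' dropped and the assay ids are recorded in the `excluded` attribute.
#'
#' @param dct a delta-Ct tibble from [delta_ct()].
#' @param sheet a [sample_sheet()].
#' @param calibrator `"sample"` or `"control_mean"`.
#' @return a tibble `assay`, `sample`, `dct`, `ddct`, `rq` with attribute
#'   `excluded` (assays without a calibrator anchor).
#' @export
delta_delta_ct <- function(dct, sheet, calibrator = c("sample",
                                                      "control_mean")) {
  calibrator <- match.arg(calibrator)
  stopifnot(all(c("assay", "sample", "dct") %in% names(dct)))
  if (calibrator == "sample") {
    cal_id <- sheet$sample_id[sheet$calibrator]
    anchor <- dct[dct$sample == cal_id, c("assay", "dct")]
    names(anchor)[2] <- "cal_dct"
  } else {
    ctrl <- sheet$sample_id[sheet$group == "control"]
    anchor <- dplyr::summarise(
      dplyr::group_by(dct[dct$sample %in% ctrl, ], .data$assay),
      cal_dct = if (all(is.na(.data$dct))) NA_real_ else
        mean(.data$dct[!is.na(.data$dct)]),
      .groups = "drop"
    )
  }
  out <- dplyr::left_join(dct, anchor, by = "assay")
  excluded <- sort(unique(out$assay[is.na(out$cal_dct)]))
  out <- out[!is.na(out$cal_dct), ]
  out$ddct <- out$dct - out$cal_dct
  out$rq <- 2^(-out$ddct)
  res <- tibble::as_tibble(out[, c("assay", "sample", "dct", "ddct", "rq")])
  attr(res, "excluded") <- excluded
  res
}
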