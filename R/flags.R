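#' Classify assays within one sample by expression strength
#'
#' Labels each detected assay of a sample by where its delta-Ct falls
#' among all detected assays of that same sample: `"good"` for the
#' strongest quartile (lowest 25% of delta-Ct, i.e. most abundant),
#' `"low"` for the weakest quartile (highest 25%), `"normal"` in
#' between. Quartiles use linear interpolation between order statistics
#' (type 7) and the boundaries are inclusive. Two guards keep the
#' classification conservative:
#' \itemize{
#'   \item fewer than 4 detected assays: everything is `"normal"` (the
#'     quartiles are meaningless);
#'   \item the 25th and 75th percentiles coincide (massive ties): assays
#'     at that value are `"normal"`, only strictly smaller/larger values
#'     are `"good"`/`"low"`.
#' }
#'
#' @param dct_sample numeric vector of delta-Ct values for one sample
#'   (`NA` = non-detected).
#' @param q quartile fraction (default 0.25).
#' @return character vector of the same length: `"good"`, `"normal"`,
#'   `"low"`, or `NA` where non-detected.
#' @export
classify_sample <- function(dct_sample, q = 0.25) {
  stopifnot(is.numeric(dct_sample), q > 0, q < 0.5)
  out <- rep(NA_character_, length(dct_sample))
  det <- which(!is.na(dct_sample))
  if (length(det) == 0) return(out)
  if (length(det) < 4) {
    out[det] <- "normal"
    return(out)
  }
  v <- dct_sample[det]
  qs <- stats::quantile(v, c(q, 1 - q), type = 7, names = FALSE)
  lab <- rep("normal", length(v))
  if (qs[1] < qs[2]) {
    lab[v <= qs[1]] <- "good"
    lab[v >= qs[2]] <- "low"
  } else {
    lab[v < qs[1]] <- "good"
    lab[v > qs[2]] <- "low"
  }
  out[det] <- lab
  out
}

#' Per-assay, per-group flag summary
#'
#' Aggregates detection state and within-sample strength labels into the
#' five per-assay flag counts, separately for each sample group:
#' \describe{
#'   \item{values}{samples in which the assay was detected}
#'   \item{nd}{samples in which it was not detected}
#'   \item{good}{samples where it fell in the strongest quartile}
#'   \item{normal}{samples where it fell in the middle 50%}
#'   \item{low}{samples where it fell in the weakest quartile}
#' }
#' Invariants: `values + nd = group size`, `good + normal + low = values`.
#'
#' @param dct delta-Ct tibble from [delta_ct()].
#' @param sheet a [sample_sheet()].
#' @param q quartile fraction passed to [classify_sample()].
#' @return a tibble `assay`, `group`, `values`, `nd`, `good`, `normal`,
#'   `low`, sorted by assay then group.
#' @export
flag_summary <- function(dct, sheet, q = 0.25) {
  stopifnot(all(c("assay", "sample", "dct") %in% names(dct)))
  labelled <- dplyr::mutate(
    dplyr::group_by(dct, .data$sample),
    label = classify_sample(.data$dct, q = q)
  )
  labelled <- dplyr::ungroup(labelled)
  labelled <- dplyr::left_join(
    labelled, tibble::as_tibble(sheet)[, c("sample_id", "group")],
    by = c(sample = "sample_id")
  )
  if (anyNA(labelled$group)) {
    stop("sample(s) missing from the sample sheet: ",
         paste(unique(labelled$sample[is.na(labelled$group)]),
               collapse = ", "))
  }
  group_n <- table(sheet$group)
  out <- dplyr::summarise(
    dplyr::group_by(labelled, .data$assay, .data$group),
    values = sum(!is.na(.data$dct)),
    good = sum(.data$label == "good", na.rm = TRUE),
    normal = sum(.data$label == "normal", na.rm = TRUE),
    low = sum(.data$label == "low", na.rm = TRUE),
    .groups = "drop"
  )
  out$nd <- as.integer(group_n[out$group]) - out$values
  out <- out[, c("assay", "group", "values", "nd", "good", "normal",
                 "low")]
  dplyr::arrange(out, .data$assay, .data$group)
}

#' Retention filter on detection counts
#'
#' Keeps only assays detected in at least `min_detected` samples in
#' *both* groups; everything else is excluded from the statistical
#' screen.
#'
#' @param fs flag summary tibble from [flag_summary()].
#' @param min_detected minimum detected samples per group (default 2, the
#'   smallest group size for which an SD exists).
#' @return sorted character vector of retained assay ids.
#' @export
retention_filter <- function(fs, min_detected = 2) {
  stopifnot(all(c("assay", "group", "values") %in% names(fs)))
  keep <- dplyr::summarise(
    dplyr::group_by(fs, .data$assay),
    ok = dplyr::n() == 2 && all(.data$values >= min_detected),
    .groups = "drop"
  )
  sort(keep$assay[keep$ok])
}

#' Confidence tier from the flag profile
#'
#' Triage of a screened assay by its flag counts:
#' \describe{
#'   \item{low}{at least one sample, in either group, fell in the weakest
#'     quartile;}
#'   \item{top}{no `low` flag anywhere and at least one `good` flag in
#'     *both* groups;}
#'   \item{medium}{no `low` flag anywhere and no `good` in either group.}
#' }
#' Assays with `good` flags in exactly one group (a case the two printed
#' definitions leave open) are assigned `medium`, the conservative
#' choice.
#'
#' @param fs flag summary tibble ([flag_summary()]), optionally filtered
#'   to the assays of interest.
#' @return a tibble `assay`, `tier` with tier one of `"top"`,
#'   `"medium"`, `"low"`.
#' @export
confidence_tier <- function(fs) {
  stopifnot(all(c("assay", "group", "good", "low") %in% names(fs)))
  dplyr::summarise(
    dplyr::group_by(fs, .data$assay),
    tier = if (sum(.data$low) > 0) "low"
           else if (all(.data$good >= 1)) "top"
           else "medium",
    .groups = "drop"
  )
}
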