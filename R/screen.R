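#' Screening configuration
#'
#' Thresholds and scale/policy choices for the discovery screen.
#'
#' @param p_threshold Welch p-value threshold of the composite
#'   differential-expression rule (inclusive; default 0.1).
#' @param fc_threshold signed fold-change threshold (inclusive; default 2,
#'   i.e. |fc| >= 2 in either direction).
#' @param quartile quartile fraction of the flag classification.
#' @param min_detected retention rule: minimum detected samples per group.
#' @param scale scale on which the Welch t-test runs: `"rq"` (linear
#'   relative quantities, default — group summaries are always reported on
#'   this scale) or `"ddct"` (log2 scale).
#' @param calibrator calibrator policy, see [delta_delta_ct()].
#' @param ec_aggregate,replicate_aggregate aggregation methods, see
#'   [delta_ct()] and [aggregate_replicates()].
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 0.1, fc_threshold = 2,
                          quartile = 0.25, min_detected = 2,
                          scale = c("rq", "ddct"),
                          calibrator = c("sample", "control_mean"),
                          ec_aggregate = c("mean", "median"),
                          replicate_aggregate = c("mean", "median")) {
  stopifnot(p_threshold > 0, p_threshold <= 1, fc_threshold >= 1,
            quartile > 0, quartile < 0.5, min_detected >= 2)
  structure(
    list(p_threshold = p_threshold, fc_threshold = fc_threshold,
         quartile = quartile, min_detected = min_detected,
         scale = match.arg(scale), calibrator = match.arg(calibrator),
         ec_aggregate = match.arg(ec_aggregate),
         replicate_aggregate = match.arg(replicate_aggregate)),
    class = "screen_config"
  )
}

#' Per-group summary statistics of relative quantities
#'
#' For each assay and group, over the samples where the assay was
#' detected: n, mean, sample SD (n-1 denominator), coefficient of
#' variation (percent, 100*sd/mean), max/min ratio, and median of the
#' relative quantities. Assays with fewer than 2 detected values in
#' either group are dropped (SD undefined) and recorded in the
#' `excluded` attribute.
#'
#' @param rq tibble with columns `assay`, `sample` and the value column
#'   `rq`, e.g. from [delta_delta_ct()].
#' @param sheet a [sample_sheet()].
#' @return a tibble `assay`, `group`, `n`, `mean`, `sd`, `cv`,
#'   `maxmin_r`, `median` with attribute `excluded`.
#' @export
group_stats <- function(rq, sheet) {
  stopifnot(all(c("assay", "sample", "rq") %in% names(rq)))
  x <- dplyr::left_join(
    rq, tibble::as_tibble(sheet)[, c("sample_id", "group")],
    by = c(sample = "sample_id")
  )
  x <- x[!is.na(x$rq), ]
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$assay, .data$group),
    n = dplyr::n(),
    mean = mean(.data$rq),
    sd = stats::sd(.data$rq),
    cv = 100 * stats::sd(.data$rq) / mean(.data$rq),
    maxmin_r = max(.data$rq) / min(.data$rq),
    median = stats::median(.data$rq),
    .groups = "drop"
  )
  ok <- dplyr::summarise(
    dplyr::group_by(out, .data$assay),
    ok = dplyr::n() == 2 && all(.data$n >= 2),
    .groups = "drop"
  )
  excluded <- sort(ok$assay[!ok$ok])
  out <- out[out$assay %in% ok$assay[ok$ok], ]
  out <- dplyr::arrange(out, .data$assay, .data$group)
  attr(out, "excluded") <- excluded
  out
}

#' Signed fold-change
#'
#' Expresses a positive expression ratio in the symmetric signed
#' convention used throughout miRNA array screening: the ratio itself
#' when >= 1 (upregulation), minus its reciprocal when < 1 (so a halving
#' is -2, not 0.5). Vectorized.
#'
#' @param ratio positive ratio(s), e.g. mean RQ in cases over mean RQ in
#'   controls.
#' @return signed fold-change(s), always with absolute value >= 1.
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop("fold-change ratios must be positive and finite")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate inputs follow a documented
#' convention: when both groups have zero variance the test is decided by
#' the means alone (p = 1 if equal, p = 0 otherwise).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs at least 2 values per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Composite differential-expression call
#'
#' An assay is called differentially expressed when *at least one* of
#' the three prerequisites holds: Welch p-value at or below
#' `p_threshold`, or absolute mean fold-change at or above
#' `fc_threshold`, or absolute median fold-change at or above
#' `fc_threshold`. All comparisons inclusive. Vectorized.
#'
#' @param p Welch p-value(s).
#' @param mean_fc,median_fc signed fold-changes.
#' @param p_threshold,fc_threshold thresholds (defaults 0.1 and 2).
#' @return logical vector.
#' @export
de_call <- function(p, mean_fc, median_fc, p_threshold = 0.1,
                    fc_threshold = 2) {
  p <= p_threshold | abs(mean_fc) >= fc_threshold |
    abs(median_fc) >= fc_threshold
}

#' Run the discovery screen
#'
#' The full stage-1 pipeline: replicate aggregation, delta-Ct against the
#' endogenous control, flag classification, retention filtering
#' (>= `min_detected` detected samples per group), delta-delta-Ct /
#' relative quantities against the calibrator, per-group statistics,
#' signed mean/median fold-changes (endometriosis over control), Welch
#' t-test, the composite differential-expression call, and the
#' top/medium/low confidence tier.
#'
#' A Benjamini-Hochberg adjusted p-value column (`q_bh`) is included for
#' reference only; it plays no part in the composite call, which applies
#' no multiple-testing correction.
#'
#' @param ct a [ct_matrix].
#' @param sheet a [sample_sheet()].
#' @param panel a [panel_def()].
#' @param config a [screen_config()].
#' @return a tibble with one row per screened assay — group statistics
#'   (`*_endometriosis`, `*_control`), `mean_ratio`, `median_ratio`,
#'   `mean_fc`, `median_fc`, `t`, `df`, `p_welch`, `q_bh`, `de_call`,
#'   `tier` — sorted by tier (top, medium, low) then p-value. Attributes:
#'   `excluded` (tibble `assay`, `reason`), `flags` (the flag summary)
#'   and `config`.
#' @export
run_screen <- function(ct, sheet, panel, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  chk <- validate_inputs(ct, sheet, panel)
  if (!chk$ok) {
    stop("inconsistent inputs:\n  ",
         paste(chk$violations, collapse = "\n  "))
  }
  dct <- delta_ct(ct, panel, ec_aggregate = config$ec_aggregate,
                  replicate_aggregate = config$replicate_aggregate)
  fs <- flag_summary(dct, sheet, q = config$quartile)
  retained <- retention_filter(fs, min_detected = config$min_detected)
  excluded <- tibble::tibble(
    assay = setdiff(unique(dct$assay), retained),
    reason = paste0("fewer than ", config$min_detected,
                    " detected samples in a group")
  )

  rqm <- delta_delta_ct(dct[dct$assay %in% retained, ], sheet,
                        calibrator = config$calibrator)
  if (length(attr(rqm, "excluded")) > 0) {
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      assay = attr(rqm, "excluded"),
      reason = "not detected in the calibrator sample"
    ))
  }

  gs <- group_stats(rqm, sheet)
  if (length(attr(gs, "excluded")) > 0) {
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      assay = attr(gs, "excluded"),
      reason = "fewer than 2 detected relative quantities in a group"
    ))
  }
  wide <- tidyr::pivot_wider(
    gs, names_from = "group",
    values_from = c("n", "mean", "sd", "cv", "maxmin_r", "median")
  )

  # test scale: linear RQ (default) or log2 (delta-delta-Ct)
  val <- dplyr::left_join(
    rqm, tibble::as_tibble(sheet)[, c("sample_id", "group")],
    by = c(sample = "sample_id")
  )
  val$y <- if (config$scale == "rq") val$rq else val$ddct
  tests <- dplyr::summarise(
    dplyr::group_by(val[val$assay %in% wide$assay, ], .data$assay),
    t = welch_t(.data$y[.data$group == "endometriosis"],
                .data$y[.data$group == "control"])$t,
    df = welch_t(.data$y[.data$group == "endometriosis"],
                 .data$y[.data$group == "control"])$df,
    p_welch = welch_t(.data$y[.data$group == "endometriosis"],
                      .data$y[.data$group == "control"])$p,
    .groups = "drop"
  )

  rec <- dplyr::left_join(wide, tests, by = "assay")
  rec$mean_ratio <- rec$mean_endometriosis / rec$mean_control
  rec$median_ratio <- rec$median_endometriosis / rec$median_control
  rec$mean_fc <- signed_fold_change(rec$mean_ratio)
  rec$median_fc <- signed_fold_change(rec$median_ratio)
  rec$q_bh <- stats::p.adjust(rec$p_welch, method = "BH")
  rec$de_call <- de_call(rec$p_welch, rec$mean_fc, rec$median_fc,
                         p_threshold = config$p_threshold,
                         fc_threshold = config$fc_threshold)
  rec <- dplyr::left_join(rec, confidence_tier(
    fs[fs$assay %in% rec$assay, ]
  ), by = "assay")

  cols <- c("assay",
            "n_endometriosis", "mean_endometriosis", "sd_endometriosis",
            "cv_endometriosis", "maxmin_r_endometriosis",
            "median_endometriosis",
            "n_control", "mean_control", "sd_control", "cv_control",
            "maxmin_r_control", "median_control",
            "mean_ratio", "median_ratio", "mean_fc", "median_fc",
            "t", "df", "p_welch", "q_bh", "de_call", "tier")
  rec <- rec[, cols]
  rec$n_endometriosis <- as.integer(rec$n_endometriosis)
  rec$n_control <- as.integer(rec$n_control)
  tier_rank <- match(rec$tier, c("top", "medium", "low"))
  ord <- order(tier_rank, rec$p_welch, rec$assay)
  rec <- rec[ord, ]
  excluded <- dplyr::arrange(excluded, .data$assay)
  attr(rec, "excluded") <- excluded
  attr(rec, "flags") <- fs
  attr(rec, "config") <- config
  rec
}
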