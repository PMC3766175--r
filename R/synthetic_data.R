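#' Synthetic Ct dataset configuration
#'
#' Parameters of the generative model used to emulate a two-group
#' low-density qPCR array study. Ct values are generated additively in
#' cycle (log2) space, where qPCR technical noise is approximately normal:
#'
#' \deqn{Ct_{ijr} = B_i + L_j - s_i \, [j \in \mathrm{endometriosis}] +
#'   \epsilon_{ijr}}
#'
#' with per-assay baseline \eqn{B_i \sim U(\mathrm{baseline\_ct\_range})},
#' per-sample loading shift \eqn{L_j \sim N(0, \mathrm{loading\_sd})},
#' technical noise \eqn{\epsilon \sim N(0, \mathrm{noise\_sd})} and effect
#' shift \eqn{s_i = \log_2 f_i} for an upregulation fold-change
#' \eqn{f \ge 1} (a downregulation coded as \eqn{f = -2} means halved
#' expression, i.e. a shift of \eqn{+1} cycle). Endogenous-control wells
#' use baseline `ec_ct` and fold-change 1 under the same noise model.
#' Values at or above `lod_ct` are censored to non-detected.
#'
#' Defaults mirror a discovery card design of 667 target miRNAs measured
#' in 10 endometriosis and 10 control samples with 8 endogenous-control
#' wells.
#'
#' @param n_assays number of target miRNA assays.
#' @param n_endo,n_control samples per group.
#' @param n_planted number of truly differential assays.
#' @param planted_fold_changes signed linear fold-changes for the planted
#'   assays, recycled to `n_planted`; each must have absolute value >= 1.
#' @param baseline_ct_range interval for the per-assay baseline Ct.
#' @param loading_sd SD of the per-sample loading shift, in cycles.
#' @param noise_sd SD of per-well technical noise, in cycles.
#' @param ec_ct baseline Ct of the endogenous-control wells.
#' @param lod_ct censoring threshold (limit of detection), in cycles.
#' @param replicates technical replicates per well.
#' @param n_ec_wells number of endogenous-control assay wells.
#' @param ec_label id stem for the endogenous-control assay(s).
#' @param seed integer seed; the generator is deterministic given the
#'   configuration.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_assays = 667, n_endo = 10, n_control = 10,
                         n_planted = 0,
                         planted_fold_changes = numeric(0),
                         baseline_ct_range = c(22, 35),
                         loading_sd = 0.5, noise_sd = 0.4,
                         ec_ct = 20, lod_ct = 40, replicates = 1L,
                         n_ec_wells = 8L, ec_label = "MammU6",
                         seed = 1L) {
  cfg <- list(n_assays = as.integer(n_assays), n_endo = as.integer(n_endo),
              n_control = as.integer(n_control),
              n_planted = as.integer(n_planted),
              planted_fold_changes = as.numeric(planted_fold_changes),
              baseline_ct_range = as.numeric(baseline_ct_range),
              loading_sd = as.numeric(loading_sd),
              noise_sd = as.numeric(noise_sd),
              ec_ct = as.numeric(ec_ct), lod_ct = as.numeric(lod_ct),
              replicates = as.integer(replicates),
              n_ec_wells = as.integer(n_ec_wells),
              ec_label = as.character(ec_label), seed = as.integer(seed))
  if (cfg$n_assays < 1) stop("n_assays must be >= 1")
  if (cfg$n_endo < 1 || cfg$n_control < 1) {
    stop("both groups need at least one sample")
  }
  if (cfg$n_planted > cfg$n_assays) stop("n_planted exceeds n_assays")
  if (cfg$n_planted > 0 && length(cfg$planted_fold_changes) == 0) {
    stop("planted_fold_changes required when n_planted > 0")
  }
  if (any(abs(cfg$planted_fold_changes) < 1)) {
    stop("planted fold-changes must have |f| >= 1 ",
         "(code a halving as -2, not 0.5)")
  }
  if (cfg$loading_sd < 0 || cfg$noise_sd < 0) stop("SDs must be >= 0")
  if (length(cfg$baseline_ct_range) != 2 ||
      diff(cfg$baseline_ct_range) < 0) {
    stop("baseline_ct_range must be an increasing interval")
  }
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  if (cfg$n_ec_wells < 1) stop("need at least one endogenous-control well")
  structure(cfg, class = "synth_config")
}

#' Signed linear fold-change to a log2 shift
#'
#' Maps the signed convention (f >= 1 up, f <= -1 down with -f meaning
#' 1/f-fold expression) to the log2 of the implied expression ratio.
#' @noRd
signed_fc_to_log2 <- function(f) {
  out <- numeric(length(f))
  up <- f >= 1
  out[up] <- log2(f[up])
  out[!up] <- -log2(-f[!up])
  out
}

#' Generate a synthetic discovery dataset
#'
#' Draws a complete Ct dataset from the model described in
#' [synth_config()], together with the matching sample sheet (first
#' control sample designated calibrator), panel definition and a
#' ground-truth table of the planted fold-changes.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements `ct` ([ct_matrix]), `sheet`
#'   ([sample_sheet()]), `panel` ([panel_def()]) and `truth` (tibble
#'   `assay`, `fold_change`; 1.0 for null assays and endogenous
#'   controls).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::local_seed(cfg$seed)

  target_ids <- sprintf("syn-miR-%04d", seq_len(cfg$n_assays))
  ec_ids <- if (cfg$n_ec_wells == 1) cfg$ec_label else
    sprintf("%s-%02d", cfg$ec_label, seq_len(cfg$n_ec_wells))
  assays <- c(target_ids, ec_ids)
  samples <- c(sprintf("endo_%02d", seq_len(cfg$n_endo)),
               sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  is_endo <- c(rep(TRUE, cfg$n_endo), rep(FALSE, cfg$n_control))

  fc <- rep(1, cfg$n_assays)
  if (cfg$n_planted > 0) {
    planted <- sample.int(cfg$n_assays, cfg$n_planted)
    fc[planted] <- rep_len(cfg$planted_fold_changes, cfg$n_planted)
  }
  baseline <- c(
    stats::runif(cfg$n_assays, cfg$baseline_ct_range[1],
                 cfg$baseline_ct_range[2]),
    rep(cfg$ec_ct, cfg$n_ec_wells)
  )
  shift <- c(signed_fc_to_log2(fc), rep(0, cfg$n_ec_wells))
  loading <- stats::rnorm(length(samples), 0, cfg$loading_sd)

  grid <- tidyr::expand_grid(
    assay_i = seq_along(assays),
    sample_j = seq_along(samples),
    replicate = seq_len(cfg$replicates)
  )
  mu <- baseline[grid$assay_i] + loading[grid$sample_j] -
    shift[grid$assay_i] * is_endo[grid$sample_j]
  eps <- stats::rnorm(nrow(grid), 0, cfg$noise_sd)
  data <- tibble::tibble(
    assay = assays[grid$assay_i],
    sample = samples[grid$sample_j],
    replicate = as.integer(grid$replicate),
    ct = mu + eps
  )

  ct <- ct_matrix(data, lod = cfg$lod_ct, assays = assays,
                  samples = samples)
  sheet <- sample_sheet(
    sample_id = samples,
    group = ifelse(is_endo, "endometriosis", "control"),
    calibrator = samples == samples[cfg$n_endo + 1]
  )
  panel <- panel_def(assays, ec_ids, cfg$replicates)
  truth <- tibble::tibble(assay = assays,
                          fold_change = c(fc, rep(1, cfg$n_ec_wells)))
  list(ct = ct, sheet = sheet, panel = panel, truth = truth)
}

#' Generate a synthetic validation dataset
#'
#' Same generative model as [generate_dataset()], with defaults matching
#' a custom validation card design: 15 target assays with 3 technical
#' replicates each, a single RNU6B endogenous control, measured in 21
#' endometriosis and 25 control samples.
#'
#' @param ... overrides passed to [synth_config()] on top of the
#'   validation defaults.
#' @return as [generate_dataset()].
#' @export
generate_validation_dataset <- function(...) {
  defaults <- list(n_assays = 15, n_endo = 21, n_control = 25,
                   replicates = 3L, n_ec_wells = 1L, ec_label = "RNU6B")
  over <- list(...)
  cfg <- do.call(synth_config, utils::modifyList(defaults, over))
  generate_dataset(cfg)
}

#' Write a synthetic dataset to disk in the package's file formats
#'
#' Emits `ct.tsv` (long), `samples.csv`, `panel.json` and `truth.csv`
#' under `dir`.
#'
#' @param ds a dataset list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ct = file.path(dir, "ct.tsv"),
    samples = file.path(dir, "samples.csv"),
    panel = file.path(dir, "panel.json"),
    truth = file.path(dir, "truth.csv")
  )
  write_ct_table(ds$ct, paths["ct"], format = "long")
  write_sample_sheet(ds$sheet, paths["samples"])
  write_panel(ds$panel, paths["panel"])
  readr::write_csv(ds$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
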