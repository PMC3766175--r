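test_that("group statistics match their definitions", {
  rq <- tibble::tibble(
    assay = "a",
    sample = c("E01", "E02", "E03", "C01", "C02"),
    rq = c(1, 2, 3, 4, 4)
  )
  sheet <- two_group_sheet(3, 2)
  gs <- group_stats(rq, sheet)
  e <- gs[gs$group == "endometriosis", ]
  expect_equal(e$n, 3L)
  expect_equal(e$mean, 2)
  expect_equal(e$sd, 1)
  expect_equal(e$cv, 50)
  expect_equal(e$maxmin_r, 3)
  expect_equal(e$median, 2)
  ctrl <- gs[gs$group == "control", ]
  expect_equal(ctrl$sd, 0)
  expect_equal(ctrl$cv, 0)
  expect_equal(ctrl$maxmin_r, 1)
})

test_that("group statistics match an independent two-pass computation", {
  withr::local_seed(44)
  sheet <- two_group_sheet(6, 5)
  rq <- tidyr::expand_grid(assay = paste0("a", 1:4),
                           sample = sheet$sample_id)
  rq$rq <- stats::rlnorm(nrow(rq))
  gs <- group_stats(rq, sheet)
  for (i in seq_len(nrow(gs))) {
    ids <- sheet$sample_id[sheet$group == gs$group[i]]
    v <- rq$rq[rq$assay == gs$assay[i] & rq$sample %in% ids]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(gs$mean[i], m)
    expect_equal(gs$sd[i], s)
    expect_equal(gs$cv[i], 100 * s / m)
    expect_equal(gs$maxmin_r[i], max(v) / min(v))
    expect_equal(gs$median[i], sort(v)[ceiling(length(v) / 2)] / 2 +
                   sort(v)[length(v) + 1 - ceiling(length(v) / 2)] / 2)
  }
})

test_that("assays with a group below two detected values are excluded", {
  sheet <- two_group_sheet(2, 2)
  rq <- tibble::tibble(
    assay = rep(c("ok", "thin"), each = 4),
    sample = rep(sheet$sample_id, 2),
    rq = c(1, 2, 3, 4, 1, NA, 3, 4)
  )
  gs <- group_stats(rq, sheet)
  expect_equal(attr(gs, "excluded"), "thin")
  expect_setequal(unique(gs$assay), "ok")
})

test_that("signed fold-change follows the symmetric convention", {
  expect_equal(round(signed_fold_change(1.29 / 1.16), 2), 1.11)
  expect_equal(round(signed_fold_change(1.04 / 2.39), 2), -2.30)
  expect_equal(signed_fold_change(1), 1)
  expect_equal(signed_fold_change(0.5), -2)
  expect_error(signed_fold_change(0), "positive")
  expect_error(signed_fold_change(-1), "positive")
})

test_that("signed fold-change is antisymmetric in the ratio inverse", {
  withr::local_seed(5)
  r <- stats::rlnorm(200)
  r <- r[abs(r - 1) > 1e-8]
  expect_equal(signed_fold_change(1 / r), -signed_fold_change(r))
  expect_true(all(abs(signed_fold_change(r)) >= 1))
})

test_that("the Welch test matches the closed-form statistic and p-value", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  res <- welch_t(x, y)
  se2 <- stats::var(x) / 4 + stats::var(y) / 4
  t_ref <- (mean(x) - mean(y)) / sqrt(se2)
  df_ref <- se2^2 / ((stats::var(x) / 4)^2 / 3 + (stats::var(y) / 4)^2 / 3)
  p_ref <- 2 * stats::pt(-abs(t_ref), df_ref)
  expect_equal(res$t, t_ref)
  expect_equal(res$df, df_ref)
  expect_equal(res$p, p_ref)

  withr::local_seed(61)
  for (i in 1:10) {
    x <- stats::rnorm(sample(2:9, 1)); y <- stats::rnorm(sample(2:9, 1))
    res <- welch_t(x, y)
    vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
    t_ref <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df_ref <- (vx + vy)^2 /
      (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    expect_equal(res$t, t_ref)
    expect_equal(res$p, 2 * stats::pt(-abs(t_ref), df_ref))
  }
})

test_that("degenerate Welch inputs follow the documented conventions", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t(c(2, 2), c(3, 3))$p, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("the composite DE rule is an inclusive three-way union", {
  expect_true(de_call(p = 0.5, mean_fc = -2.5, median_fc = -1.1))
  expect_true(de_call(p = 0.09, mean_fc = 1.1, median_fc = 1.1))
  expect_false(de_call(p = 0.5, mean_fc = 1.5, median_fc = -1.5))
  expect_true(de_call(p = 0.1, mean_fc = 1, median_fc = 1))    # inclusive
  expect_true(de_call(p = 0.9, mean_fc = 2, median_fc = 1))    # inclusive
  expect_true(de_call(p = 0.9, mean_fc = 1, median_fc = -2))
})

test_that("the DE rule is monotone in p and |fc|", {
  withr::local_seed(71)
  for (i in 1:100) {
    p <- stats::runif(1)
    fc <- signed_fold_change(stats::rlnorm(2))
    base <- de_call(p, fc[1], fc[2])
    stronger <- de_call(p / 2, sign(fc[1]) * (abs(fc[1]) + 1),
                        sign(fc[2]) * (abs(fc[2]) + 1))
    expect_true(!base || stronger)
  }
})

test_that("a noiseless planted two-fold assay is the unique DE call", {
  ds <- generate_dataset(synth_config(
    n_assays = 12, n_endo = 4, n_control = 4, n_planted = 1,
    planted_fold_changes = 2, noise_sd = 0, loading_sd = 0,
    n_ec_wells = 2, seed = 19
  ))
  rec <- run_screen(ds$ct, ds$sheet, ds$panel)
  planted <- ds$truth$assay[ds$truth$fold_change == 2]
  expect_equal(rec$assay[rec$de_call], planted)
  expect_equal(abs(rec$mean_fc[rec$assay == planted]), 2)
  expect_equal(rec$mean_fc[rec$assay != planted], rep(1, nrow(rec) - 1))
})

test_that("swapping group labels negates fold-changes and keeps p", {
  ds <- generate_dataset(synth_config(n_assays = 10, n_endo = 4,
                                      n_control = 4, n_ec_wells = 2,
                                      seed = 29))
  rec <- run_screen(ds$ct, ds$sheet, ds$panel)
  swapped <- sample_sheet(
    ds$sheet$sample_id,
    ifelse(ds$sheet$group == "control", "endometriosis", "control"),
    ds$sheet$calibrator
  )
  rec2 <- run_screen(ds$ct, swapped, ds$panel)
  m <- match(rec$assay, rec2$assay)
  expect_equal(rec2$mean_fc[m], -rec$mean_fc)
  expect_equal(rec2$median_fc[m], -rec$median_fc)
  expect_equal(rec2$p_welch[m], rec$p_welch)
})

test_that("screening records are invariant under sample order", {
  ds <- generate_dataset(synth_config(n_assays = 10, n_endo = 4,
                                      n_control = 4, n_ec_wells = 2,
                                      seed = 37))
  rec <- run_screen(ds$ct, ds$sheet, ds$panel)
  withr::local_seed(1)
  perm <- sample(length(ds$ct$samples))
  ct2 <- ct_matrix(ds$ct$data, lod = ds$ct$lod, assays = ds$ct$assays,
                   samples = ds$ct$samples[perm])
  sheet2 <- sample_sheet(ds$sheet$sample_id[perm], ds$sheet$group[perm],
                         ds$sheet$calibrator[perm])
  rec2 <- run_screen(ct2, sheet2, ds$panel)
  expect_equal(tibble::as_tibble(rec2), tibble::as_tibble(rec),
               ignore_attr = TRUE)
})

test_that("run_screen reports excluded assays with reasons", {
  ds <- generate_dataset(synth_config(
    n_assays = 30, n_endo = 4, n_control = 4,
    baseline_ct_range = c(36, 44), lod_ct = 40, seed = 53
  ))
  rec <- run_screen(ds$ct, ds$sheet, ds$panel)
  ex <- attr(rec, "excluded")
  expect_gt(nrow(ex), 0)
  expect_true(all(nzchar(ex$reason)))
  expect_length(intersect(ex$assay, rec$assay), 0)
})
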