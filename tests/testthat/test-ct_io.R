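test_that("long tables parse, with non-detected tokens and cutoff coercion", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "assay,sample,ct",
    "miR-a,s1,25.1", "miR-a,s2,26.0",
    "miR-b,s1,Undetermined", "miR-b,s2,30.5",
    "miR-c,s1,33.0", "miR-c,s2,41.2"
  ), f)
  ct <- read_ct_table(f, format = "long")
  expect_s3_class(ct, "ct_matrix")
  expect_equal(dim(ct), c(3, 2, 1))
  expect_equal(sum(is.na(ct$data$ct)), 2)  # token + above-cutoff cell
  d <- ct$data
  expect_true(is.na(d$ct[d$assay == "miR-b" & d$sample == "s1"]))
  expect_true(is.na(d$ct[d$assay == "miR-c" & d$sample == "s2"]))
})

test_that("non-detection coercion is idempotent and configurable", {
  m <- matrix(c(39.9, 40.0, 35, 28), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  ct <- ct_from_matrix(m)
  expect_true(is.na(ct$data$ct[ct$data$assay == "b" &
                                 ct$data$sample == "s1"]))
  ct2 <- ct_matrix(ct$data, lod = ct$lod, assays = ct$assays,
                   samples = ct$samples)
  expect_true(ct_equal(ct, ct2))
  ct35 <- ct_from_matrix(m, lod = 35)
  expect_equal(sum(is.na(ct35$data$ct)), 3)
})

test_that("malformed Ct tables are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("assay,sample,ct", "a,s1,25", "a,s1,26"), f)
  expect_error(read_ct_table(f, format = "long"), "duplicate well")
  writeLines(c("assay,sample,ct", "a,s1,twenty"), f)
  expect_error(read_ct_table(f, format = "long"), "non-numeric")
  expect_error(read_ct_table(tempfile(), format = "long"), "not found")
})

test_that("write/read round-trip is the identity in both dialects", {
  ds <- generate_dataset(synth_config(n_assays = 12, n_endo = 3,
                                      n_control = 3, n_ec_wells = 2,
                                      seed = 42))
  long <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ds$ct, long, format = "long")
  expect_true(ct_equal(ds$ct, read_ct_table(long, format = "long")))

  wide <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ds$ct, wide, format = "wide")
  expect_true(ct_equal(ds$ct, read_ct_table(wide, format = "wide")))

  rep3 <- generate_dataset(synth_config(n_assays = 4, n_endo = 2,
                                        n_control = 2, replicates = 3,
                                        n_ec_wells = 1, seed = 5))
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(rep3$ct, f3, format = "long")
  expect_true(ct_equal(rep3$ct, read_ct_table(f3, format = "long")))
  expect_error(write_ct_table(rep3$ct, f3, format = "wide"), "wide")
})

test_that("sample sheets validate and round-trip", {
  sheet <- two_group_sheet(3, 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, f)
  expect_equal(tibble::as_tibble(read_sample_sheet(f)),
               tibble::as_tibble(sheet))
  expect_error(sample_sheet("s1", "endometriosis", TRUE), "non-empty")
  expect_error(sample_sheet(c("s1", "s2"), c("endometriosis", "control"),
                            c(TRUE, TRUE)), "exactly one")
  expect_error(sample_sheet(c("s1", "s2"), c("case", "control"),
                            c(TRUE, FALSE)), "unknown group")
})

test_that("panel definitions validate and round-trip", {
  p <- panel_def(c("a", "b", "EC"), "EC", replicates = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_panel(p, f)
  expect_equal(read_panel(f), p)
  expect_error(panel_def(c("a", "b"), "EC"), "subset")
  expect_error(panel_def(c("a", "b"), character(0)), "at least one")
})

test_that("validate_inputs cross-checks the three inputs", {
  ds <- generate_dataset(synth_config(n_assays = 5, n_endo = 2,
                                      n_control = 2, n_ec_wells = 1,
                                      seed = 1))
  ok <- validate_inputs(ds$ct, ds$sheet, ds$panel)
  expect_true(ok$ok)
  expect_length(ok$violations, 0)

  sheet_extra <- sample_sheet(
    c(ds$sheet$sample_id, "ghost"),
    c(ds$sheet$group, "control"),
    c(ds$sheet$calibrator, FALSE)
  )
  res <- validate_inputs(ds$ct, sheet_extra, ds$panel)
  expect_false(res$ok)
  expect_match(res$violations, "ghost", all = FALSE)

  panel_bad <- panel_def(c(ds$panel$assays, "EC2"), "EC2")
  expect_error(validate_inputs(ds$ct, ds$sheet, panel_bad),
               "normalization impossible")
})

test_that("screening reports render at configurable precision and round-trip", {
  rec <- tibble::tibble(
    assay = "hsa-miR-24",
    mean_endometriosis = 1.29, mean_control = 1.16,
    mean_ratio = 1.29 / 1.16,
    mean_fc = signed_fold_change(1.29 / 1.16)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen_report(rec, f, digits = 2)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_equal(strsplit(lines[2], "\t")[[1]][5], "1.11")

  ds <- generate_dataset(synth_config(n_assays = 8, n_endo = 4,
                                      n_control = 4, n_ec_wells = 2,
                                      seed = 9))
  full <- run_screen(ds$ct, ds$sheet, ds$panel)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_screen_report(full, f2)
  back <- read_screen_report(f2)
  expect_equal(back, tibble::as_tibble(full), ignore_attr = TRUE)
})
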