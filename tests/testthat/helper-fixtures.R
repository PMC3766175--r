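# Small in-code fixtures shared across tests.

# ct_matrix from a numeric matrix (rows = assays, cols = samples, NA = nd)
ct_from_matrix <- function(m, lod = 40) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  long <- tibble::tibble(
    assay = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    ct = as.vector(m)
  )
  ct_matrix(long, lod = lod, assays = rownames(m), samples = colnames(m))
}

# sample sheet with n_endo + n_ctrl samples, first control as calibrator
two_group_sheet <- function(n_endo, n_ctrl, cal_index = n_endo + 1) {
  ids <- c(sprintf("E%02d", seq_len(n_endo)),
           sprintf("C%02d", seq_len(n_ctrl)))
  sample_sheet(
    sample_id = ids,
    group = rep(c("endometriosis", "control"), c(n_endo, n_ctrl)),
    calibrator = seq_along(ids) == cal_index
  )
}

# exact two-sided Mann-Whitney p by brute-force enumeration of all
# C(nx+ny, nx) group labelings of the pooled (tie-free) values
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(length(pooled), nx), 2, u_of)
  p_lo <- mean(all_u <= obs)
  p_hi <- mean(all_u >= obs)
  min(1, 2 * min(p_lo, p_hi))
}
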