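# Shared in-code fixtures for the test suite.

toy_sheet <- function(n_rep = 3L, organ = "shoot") {
  make_design(organ = organ, n_rep = n_rep)
}

# A small spot table with explicit values, optionally already on the
# log2 scale.
toy_table <- function(m, sheet = NULL, log2 = FALSE, normalized = FALSE) {
  if (is.null(sheet)) sheet <- toy_sheet(ncol(m) / 3L)
  if (is.null(rownames(m))) rownames(m) <- sprintf("SSP%03d", seq_len(nrow(m)))
  colnames(m) <- sheet$sample_id
  spot_table(m, sheet, log_transformed = log2, normalized = normalized)
}

# Null spot table: pure noise around a common baseline, no condition
# effect.
null_table <- function(n_spots, sheet, sd = 1, baseline = 10) {
  m <- matrix(rnorm(n_spots * nrow(sheet), baseline, sd), n_spots,
              dimnames = list(sprintf("N%04d", seq_len(n_spots)),
                              sheet$sample_id))
  spot_table(m, sheet, log_transformed = TRUE, normalized = TRUE)
}

expect_setequal_num <- function(a, b, tol = 1e-9) {
  expect_equal(sort(a), sort(b), tolerance = tol)
}
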