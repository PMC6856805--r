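# shared fixture shortcuts; everything is built in code
fx <- pharmera::mpa_fixture()

# small deterministic censored dataset: 5 nondetects (LOQ 1) + detects 2..6
mixed_mecs <- tibble::tibble(
  value_ugL = c(rep(NA_real_, 5), 2, 3, 4, 5, 6),
  loq_ugL = 1
)

expect_tibble <- function(x, cols = NULL) {
  testthat::expect_s3_class(x, "tbl_df")
  if (!is.null(cols)) testthat::expect_true(all(cols %in% names(x)))
}
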