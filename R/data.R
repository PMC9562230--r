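#' Published 18-wine reference quality table
#'
#' Perceived-quality panel means and the five published quality-proxy columns
#' (one per retained `(alpha, n)` combination, computed with k = 1) for the
#' 18 commercial New Zealand Pinot noir wines whose study design the
#' synthetic generator emulates. The underlying chemistry is not public, so
#' this table serves as a printed-value regression reference: for example,
#' the Euclidean distance between the perceived quality column and the
#' `alpha = 0.8, n = 1.0` proxy column is a frozen fixture in the test suite.
#'
#' @return A tibble: `wine_id`, `perceived_quality`, and one proxy column per
#'   published `(alpha, n)` combination.
#' @export
reference_quality_table <- function() {
  path <- system.file("extdata", "nz_pinot_quality_reference.csv",
                      package = "winepi", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
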