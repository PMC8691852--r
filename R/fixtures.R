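#' Bundled worked-example tables
#'
#' A three-quarter toy cohort of adverse-drug-reaction reports (Sex, Age, a
#' multivalued `ADR` code list) plus two published anonymizations of it:
#' `toy_release_ktheta()` satisfies PPMS(3, 1/3)-bounding only (the baseline
#' that is vulnerable to the medication-discontinuation and
#' substantial-symptoms attacks), and `toy_release_ktheta_alpha()` satisfies
#' the full PPMS(3, 1/3, 1/4)-bounding.  All three are shipped as plain CSV
#' under `inst/extdata` and are used throughout the tests and vignette.
#'
#' @param schema Schema used to validate the files; default [toy_schema()].
#' @return A list of three tibbles (quarters 1-3), as read by
#'   [read_quarter()] / [read_release()].
#' @examples
#' raw <- toy_quarters()
#' vapply(raw, nrow, integer(1))
#' @export
toy_quarters <- function(schema = toy_schema()) {
  read_quarters(toy_path(sprintf("toy_raw_q%d.csv", 1:3)), schema)
}

#' @rdname toy_quarters
#' @export
toy_release_ktheta <- function(schema = toy_schema()) {
  read_release_series(toy_path(sprintf("toy_release_ktheta_q%d.csv", 1:3)), schema)
}

#' @rdname toy_quarters
#' @export
toy_release_ktheta_alpha <- function(schema = toy_schema()) {
  read_release_series(toy_path(sprintf("toy_release_ktheta_alpha_q%d.csv", 1:3)),
                      schema)
}

toy_path <- function(files) {
  p <- system.file("extdata", files, package = "ppmsbound")
  if (any(!nzchar(p))) abort("bundled fixture files not found")
  p
}
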