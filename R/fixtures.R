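# Packaged reference tables: benchmark values transcribed from published
# full-transport Monte Carlo comparisons of the analytical shift model (WD
# percentage differences, dDD differences in mm, and the 141/148 MeV
# energy-selection worked example). Read-only; an MD5 checksum guards
# against accidental edits.

.verify_fixture <- function(path, md5, identifier) {
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, md5))
    stop(sprintf("fixture '%s' failed its checksum (%s != %s): file modified?",
                 identifier, sum, md5))
  invisible(path)
}

.fixture_registry <- list(
  table1 = list(file = "table1_wd_percent_diff.csv",
                md5 = "2b72dc1810927bee2d54d45653b8731a"),
  table2 = list(file = "table2_ddd_mm.csv",
                md5 = "8f013d8dd858f37f3769acb548ab7758"),
  worked_example = list(file = "worked_example.json",
                        md5 = "0a3726585bad0cf2419c88dde3d84073")
)

#' Load a packaged reference fixture
#'
#' * `"table1"`: per-energy percentage differences of the lateral shift WD
#'   between the closed-form model (non-relativistic and relativistic
#'   variants) and reference Monte Carlo transport, 100-170 MeV at 3 T.
#' * `"table2"`: depth retraction dDD in mm from reference transport and
#'   from the closed form, 100-170 MeV at 1.5-3 T.
#' * `"worked_example"`: the energy-selection example (WD = 2.0 cm or
#'   dDD = 0.25 cm at 3 T give 141 / 148 MeV).
#'
#' @param identifier One of `"table1"`, `"table2"`, `"worked_example"`.
#' @return A data frame (tables) or list (worked example) with attribute
#'   `fixture_id`.
#' @export
load_fixture <- function(identifier = c("table1", "table2",
                                        "worked_example")) {
  identifier <- match.arg(identifier)
  entry <- .fixture_registry[[identifier]]
  path <- system.file("extdata", entry$file, package = "braggshift",
                      mustWork = TRUE)
  .verify_fixture(path, entry$md5, identifier)
  out <- if (grepl("\\.json$", entry$file)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path)
  }
  attr(out, "fixture_id") <- identifier
  out
}
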