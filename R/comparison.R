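# Simulation-vs-model comparison arithmetic in the style of the packaged
# reference tables.

#' Compare simulated and analytic shift values
#'
#' Aligns two tables of shift values on their `(energy_mev, field_t)` keys
#' and computes, per row, the absolute difference in mm and the percentage
#' difference `100 * |analytic - simulated| / simulated` (the simulated value
#' is the denominator), plus summary statistics.
#'
#' @param simulated Data frame with columns `energy_mev`, `field_t`,
#'   `value_mm` (measured, e.g. from dose grids).
#' @param analytic Data frame with the same columns (closed-form values).
#' @return A list of class `comparison_table`: `rows` (the aligned table
#'   with `abs_diff_mm` and `percent_diff`) and `summary`
#'   (`mean_percent_diff`, `max_abs_diff_mm`).
#' @export
build_comparison <- function(simulated, analytic) {
  need <- c("energy_mev", "field_t", "value_mm")
  if (!all(need %in% names(simulated)) || !all(need %in% names(analytic)))
    stop("inputs need columns energy_mev, field_t, value_mm")
  key <- function(d) paste(d$energy_mev, d$field_t)
  ks <- key(simulated); ka <- key(analytic)
  missing_in_a <- setdiff(ks, ka); missing_in_s <- setdiff(ka, ks)
  if (length(missing_in_a) || length(missing_in_s))
    stop("key mismatch; missing pairs: ",
         paste(c(missing_in_a, missing_in_s), collapse = ", "))
  m <- match(ks, ka)
  rows <- data.frame(
    energy_mev = simulated$energy_mev, field_t = simulated$field_t,
    simulated_mm = simulated$value_mm, analytic_mm = analytic$value_mm[m])
  rows$abs_diff_mm <- abs(rows$analytic_mm - rows$simulated_mm)
  rows$percent_diff <- 100 * rows$abs_diff_mm / rows$simulated_mm
  structure(list(rows = rows,
                 summary = list(mean_percent_diff = mean(rows$percent_diff),
                                max_abs_diff_mm = max(rows$abs_diff_mm))),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  print(x$rows, ...)
  cat(sprintf("mean percent difference: %.2f%%; max |difference|: %.2g mm\n",
              x$summary$mean_percent_diff, x$summary$max_abs_diff_mm))
  invisible(x)
}

#' Summarize a packaged comparison fixture
#'
#' For `"table1"` (which stores per-energy WD percentage differences
#' directly) returns the mean percentage difference of each formula column.
#' For `"table2"` runs [build_comparison()] on the stored simulation and
#' formula dDD columns and returns its summary.
#'
#' @param fixture A fixture from [load_fixture()] (`table1` or `table2`).
#' @return For table1: named vector of mean percentage differences. For
#'   table2: the `comparison_table` object.
#' @export
summarize_fixture <- function(fixture) {
  id <- attr(fixture, "fixture_id")
  if (identical(id, "table1")) {
    c(formula1_mean_pct = mean(fixture$formula1_pct),
      formula2_mean_pct = mean(fixture$formula2_pct))
  } else if (identical(id, "table2")) {
    sim <- data.frame(energy_mev = fixture$energy_mev,
                      field_t = fixture$field_t,
                      value_mm = fixture$simulation_mm)
    ana <- data.frame(energy_mev = fixture$energy_mev,
                      field_t = fixture$field_t,
                      value_mm = fixture$formula_mm)
    build_comparison(sim, ana)
  } else {
    stop("no summary defined for this fixture")
  }
}
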