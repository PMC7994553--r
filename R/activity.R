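#' Daily resident-device counts per cell
#'
#' Counts devices whose inferred residence falls in each cell on each day,
#' completed over the full date range (days with no residents are explicit
#' zeros).
#'
#' @param residences output of [residence_table()].
#' @param dates optional Date vector defining the full span (defaults to the
#'   observed range).
#' @return data.table `col`, `row`, `date`, `U`.
#' @export
activity_counts <- function(residences, dates = NULL) {
  res <- as.data.table(residences)
  if (is.null(dates)) {
    dates <- seq(min(res$date), max(res$date), by = "day")
  }
  counts <- res[, .(U = .N), by = .(col, row, date)]
  cells <- unique(counts[, .(col, row)])
  full <- cells[, .(date = dates), by = .(col, row)]
  out <- counts[full, on = c("col", "row", "date")]
  out[is.na(U), U := 0L]
  setorder(out, col, row, date)
  out[]
}

#' Pre-event baseline activity per cell
#'
#' The baseline U_NA is the arithmetic mean of daily resident counts over
#' the pre-event equilibrium window. Cells whose baseline falls below
#' `min_devices` are flagged excluded: their deviation ratio would be
#' dominated by small-count noise (and a zero baseline is undefined).
#'
#' @param counts output of [activity_counts()].
#' @param baseline_window `c(start, end)` Date pair, inclusive.
#' @param min_devices minimum mean baseline devices for a cell to be kept
#'   (default 10).
#' @return data.table `col`, `row`, `U_NA`, `included`.
#' @export
activity_baseline <- function(counts, baseline_window, min_devices = 10) {
  dt <- as.data.table(counts)
  win <- dt[date >= baseline_window[1] & date <= baseline_window[2]]
  if (nrow(win) == 0L) stop("baseline window contains no data")
  base <- win[, .(U_NA = mean(U)), by = .(col, row)]
  base[, included := U_NA >= min_devices & U_NA > 0]
  base[]
}

#' Daily activity deviation from baseline
#'
#' The dimensionless deviation `D = (U - U_NA) / U_NA`: 0 on a normal day,
#' -1 when a neighborhood empties, positive when activity exceeds baseline.
#' No clipping is applied. Excluded cells yield no series.
#'
#' @param counts output of [activity_counts()].
#' @param baseline output of [activity_baseline()].
#' @return data.table `col`, `row`, `date`, `U`, `D`.
#' @export
activity_deviation <- function(counts, baseline) {
  dt <- as.data.table(counts)
  keep <- baseline[included == TRUE, .(col, row, U_NA)]
  out <- dt[keep, on = c("col", "row")]
  out[, D := (U - U_NA) / U_NA]
  setorder(out, col, row, date)
  out[]
}

#' Smoothed activity trend
#'
#' Centered moving average of the deviation series; the first and last
#' `(window - 1) / 2` days are dropped, so a 61-day deviation series yields
#' a 59-day trend under the default 3-day window.
#'
#' @param deviation output of [activity_deviation()].
#' @param window odd integer moving-average width in days (default 3).
#' @return data.table `col`, `row`, `date`, `trend`.
#' @export
activity_trend <- function(deviation, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  dt <- as.data.table(deviation)
  n_dates <- length(unique(dt$date))
  if (n_dates < window) stop("series shorter than the smoothing window")
  setorder(dt, col, row, date)
  dt[, trend := data.table::frollmean(D, window, align = "center"),
     by = .(col, row)]
  out <- dt[!is.na(trend), .(col, row, date, trend)]
  out[]
}

#' Build per-cell activity series from a residence table
#'
#' Convenience wrapper chaining [activity_counts()], [activity_baseline()],
#' [activity_deviation()] and [activity_trend()].
#'
#' @inheritParams activity_counts
#' @inheritParams activity_baseline
#' @inheritParams activity_trend
#' @return an object of class `activity_series`: list with elements
#'   `counts`, `baseline`, `deviation`, `trend` (long data.tables) plus
#'   `trend_matrix` (cells x dates, rownames `"col_row"`) and `trend_dates`.
#' @export
build_activity_series <- function(residences, baseline_window,
                                  dates = NULL, min_devices = 10,
                                  window = 3) {
  counts <- activity_counts(residences, dates)
  baseline <- activity_baseline(counts, baseline_window, min_devices)
  deviation <- activity_deviation(counts, baseline)
  trend <- activity_trend(deviation, window)
  wide <- data.table::dcast(trend, col + row ~ date, value.var = "trend")
  mat <- as.matrix(wide[, -(1:2)])
  rownames(mat) <- paste(wide$col, wide$row, sep = "_")
  structure(list(counts = counts, baseline = baseline,
                 deviation = deviation, trend = trend,
                 trend_matrix = mat,
                 trend_dates = as.Date(colnames(mat)),
                 cells = wide[, .(col, row)]),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %d cells x %d trend days (%s .. %s)\n",
              nrow(x$trend_matrix), ncol(x$trend_matrix),
              min(x$trend_dates), max(x$trend_dates)))
  invisible(x)
}
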