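#' Infer a device's residence cell for one day
#'
#' The daily residence activity area is the grid cell receiving the
#' plurality (argmax) of a device's qualifying pings that calendar day. On
#' weekdays only night-window pings qualify (local hour >= 20 or < 7, each
#' credited to the calendar day it falls on); on weekends all hours qualify.
#' Ties are broken deterministically by lowest `(col, row)` lexicographic
#' order.
#'
#' @param pings grid-tagged standardized pings for a single device-day.
#' @param is_weekday logical; if `FALSE` all hours qualify.
#' @return `list(col, row, n_pings)` or `NULL` when no ping qualifies.
#' @export
daily_residence <- function(pings, is_weekday = TRUE) {
  dt <- as.data.table(pings)
  if (is_weekday) dt <- dt[local_hour >= 20 | local_hour < 7]
  if (nrow(dt) == 0L) return(NULL)
  counts <- dt[, .N, by = .(col, row)]
  setorder(counts, -N, col, row)
  list(col = counts$col[1], row = counts$row[1], n_pings = counts$N[1])
}

.is_weekend <- function(date) format(date, "%u") %in% c("6", "7")

#' Daily residence table for a ping panel
#'
#' Vectorized [daily_residence()] over every device and day: one record per
#' device per day with at least one qualifying ping; silent days are
#' explicit gaps. Ping input order never affects the result.
#'
#' @param pings grid-tagged standardized pings (`device_id`, `local_date`,
#'   `local_hour`, `col`, `row`).
#' @param period optional `c(start, end)` Date pair restricting the table.
#' @param weekend_all_hours if `TRUE` (default) weekend days count pings
#'   from all hours; weekdays always use the 20:00-07:00 night window.
#' @return data.table `device_id`, `date`, `col`, `row`, `n_pings`.
#' @export
residence_table <- function(pings, period = NULL, weekend_all_hours = TRUE) {
  dt <- as.data.table(pings)
  if (!is.null(period)) {
    dt <- dt[local_date >= period[1] & local_date <= period[2]]
  }
  if (nrow(dt) == 0L) {
    return(data.table(device_id = character(), date = as.Date(character()),
                      col = integer(), row = integer(), n_pings = integer()))
  }
  night <- dt$local_hour >= 20 | dt$local_hour < 7
  if (weekend_all_hours) night <- night | .is_weekend(dt$local_date)
  dt <- dt[night]
  if (nrow(dt) == 0L) {
    return(data.table(device_id = character(), date = as.Date(character()),
                      col = integer(), row = integer(), n_pings = integer()))
  }
  counts <- dt[, .N, by = .(device_id, local_date, col, row)]
  setorder(counts, device_id, local_date, -N, col, row)
  res <- unique(counts, by = c("device_id", "local_date"))
  setnames(res, c("local_date", "N"), c("date", "n_pings"))
  res[]
}
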