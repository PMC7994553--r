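#' Impact magnitude of a response curve
#'
#' The maximum depth or height (peak absolute trend deviation) within the
#' event impact window, together with its date t0 (earliest on ties).
#'
#' @param trend numeric trend series.
#' @param dates Date vector aligned with `trend`.
#' @param impact_window `c(start, end)` Date pair; must intersect `dates`.
#' @return list `impact` (>= 0), `t0` (Date), `value` (signed trend at t0).
#' @export
impact_magnitude <- function(trend, dates, impact_window) {
  idx <- which(dates >= impact_window[1] & dates <= impact_window[2])
  if (length(idx) == 0L) stop("impact window outside trend support")
  w <- trend[idx]
  i <- which.max(abs(w))            # which.max returns the earliest maximum
  list(impact = abs(w[i]), t0 = dates[idx[i]], value = w[i])
}

#' Time from peak impact to post-event equilibrium
#'
#' The post-event equilibrium level is the mean trend over the final
#' `eq_window` days of the series. Recovery is the first date at or after
#' `t0` where the trend stays within `tol` of that level for at least
#' `persist` consecutive days; the statistic is `t2 - t0` in days. Curves
#' that never sustain the band before the series ends are censored
#' ("not recovered within study").
#'
#' @inheritParams impact_magnitude
#' @param t0 peak-impact date (from [impact_magnitude()]).
#' @param eq_window days at the series tail defining the equilibrium level
#'   (default 14).
#' @param tol tolerance band around the equilibrium level (default 0.05).
#' @param persist consecutive in-band days required (default 3).
#' @return list `t2` (Date), `days` (integer, `NA` if censored),
#'   `recovered` (logical), `level` (equilibrium), `span` (days from t0 to
#'   series end, the lower bound when censored).
#' @export
time_to_recovery <- function(trend, dates, t0, eq_window = 14, tol = 0.05,
                             persist = 3) {
  if (!t0 %in% dates) stop("t0 outside trend support")
  post <- which(dates >= t0)
  if (eq_window > length(dates)) {
    stop("equilibrium window longer than the trend support")
  }
  level <- mean(tail(trend, eq_window))
  inband <- abs(trend[post] - level) <= tol
  runlen <- 0L
  t2_idx <- NA_integer_
  for (i in seq_along(inband)) {
    runlen <- if (inband[i]) runlen + 1L else 0L
    if (runlen >= persist) {
      t2_idx <- i - persist + 1L
      break
    }
  }
  ## a band-entry too close to the series end to show `persist` days still
  ## counts if it stays in band through the end
  if (is.na(t2_idx) && runlen > 0L && inband[length(inband)]) {
    t2_idx <- length(inband) - runlen + 1L
  }
  span <- as.integer(dates[post[length(post)]] - t0)
  if (is.na(t2_idx)) {
    list(t2 = dates[post[length(post)]], days = NA_integer_,
         recovered = FALSE, level = level, span = span)
  } else {
    t2 <- dates[post[t2_idx]]
    list(t2 = t2, days = as.integer(t2 - t0), recovered = TRUE,
         level = level, span = span)
  }
}

#' Resilience capacity (signed area under the response curve)
#'
#' Trapezoidal integral of the trend deviation (relative to the pre-event
#' baseline, i.e. equilibrium level 0) between the peak-impact date t0 and
#' the recovery date t2, in day-fraction units: negative for below-baseline
#' excursions (activity loss), positive for above-baseline ones
#' (shelter-in-place gains).
#'
#' @inheritParams impact_magnitude
#' @param t0,t2 integration bounds (Dates in the trend support).
#' @return signed scalar, day-fraction units.
#' @export
resilience_capacity <- function(trend, dates, t0, t2) {
  if (t0 > t2) stop("t0 must not exceed t2")
  idx <- which(dates >= t0 & dates <= t2)
  if (length(idx) == 0L) stop("integration window outside trend support")
  if (length(idx) == 1L) return(0)
  pracma::trapz(as.numeric(dates[idx] - t0), trend[idx])
}

#' Full resilience profile of one response curve
#'
#' @inheritParams time_to_recovery
#' @inheritParams impact_magnitude
#' @return list with `impact`, `t0`, `t2`, `time_to_recovery`, `recovered`,
#'   `censored` (integration truncated at series end), `rc`.
#' @export
resilience_profile <- function(trend, dates, impact_window, eq_window = 14,
                               tol = 0.05, persist = 3) {
  imp <- impact_magnitude(trend, dates, impact_window)
  rec <- time_to_recovery(trend, dates, imp$t0, eq_window, tol, persist)
  rc <- resilience_capacity(trend, dates, imp$t0, rec$t2)
  list(impact = imp$impact, t0 = imp$t0, t2 = rec$t2,
       time_to_recovery = rec$days, recovered = rec$recovered,
       censored = !rec$recovered, rc = rc)
}

#' Per-group resilience profiles
#'
#' Computes each group's profile on its mean trend curve and, alongside,
#' the mean of the per-cell metrics (the source tables could be read either
#' way, so both are reported).
#'
#' @param x trend matrix (cells x days).
#' @param labels integer group label per row.
#' @param dates Date vector aligned with columns.
#' @inheritParams resilience_profile
#' @return data.table: `group`, `n_cells`, `impact`, `t0`,
#'   `time_to_recovery`, `recovered`, `rc` (mean-curve metrics), plus
#'   `mean_cell_impact` and `mean_cell_rc`.
#' @export
group_profiles <- function(x, labels, dates, impact_window, eq_window = 14,
                           tol = 0.05, persist = 3) {
  x <- as.matrix(x)
  out <- lapply(sort(unique(labels)), function(g) {
    rows <- which(labels == g)
    if (length(rows) == 0L) {
      warning("empty group ", g, " skipped")
      return(NULL)
    }
    mean_curve <- colMeans(x[rows, , drop = FALSE])
    p <- resilience_profile(mean_curve, dates, impact_window, eq_window,
                            tol, persist)
    cellp <- lapply(rows, function(r) {
      resilience_profile(x[r, ], dates, impact_window, eq_window, tol,
                         persist)
    })
    data.table(group = g, n_cells = length(rows), impact = p$impact,
               t0 = p$t0, time_to_recovery = p$time_to_recovery,
               recovered = p$recovered, rc = p$rc,
               mean_cell_impact = mean(vapply(cellp, `[[`, numeric(1),
                                              "impact")),
               mean_cell_rc = mean(vapply(cellp, `[[`, numeric(1), "rc")))
  })
  rbindlist(out)
}
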