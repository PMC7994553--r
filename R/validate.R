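#' Apportion zone-level damage counts to grid cells
#'
#' Damage tallies are typically published at a coarse (zipcode-like) zone
#' resolution. Each cell's estimate is the zone's per-household damage rate
#' times the cell's households:
#' `est_damaged = (zone_damage / zone_households) * cell_households`, so
#' cell estimates sum back to the zone count when the cells tile the zone.
#'
#' @param zone_damage data.table `zone`, `damaged` and optionally
#'   `households` (zone totals; derived from the cell table otherwise).
#' @param cells data.table `col`, `row`, `zone`, `households`.
#' @return data.table `col`, `row`, `zone`, `households`, `est_damaged`,
#'   `rate_per_1000` (the zone rate applied). Zones with zero households
#'   but positive damage are flagged with a warning and skipped (`NA`
#'   estimates).
#' @export
apportion_damage <- function(zone_damage, cells) {
  zd <- as.data.table(zone_damage)
  ct <- as.data.table(cells)
  if (anyNA(ct$households)) stop("every cell needs a household count")
  if (!"households" %in% names(zd)) {
    zd <- ct[, .(households = sum(households)), by = zone][
      zd[, .(zone, damaged)], on = "zone"]
  }
  bad <- zd[households <= 0 & damaged > 0]
  if (nrow(bad) > 0L) {
    warning("zones with damage but no households skipped: ",
            paste(bad$zone, collapse = ", "))
  }
  zd[, rate := fifelse(households > 0, damaged / households, NA_real_)]
  out <- zd[, .(zone, rate)][ct, on = "zone"]
  if (anyNA(out$rate) && nrow(bad) == 0L) {
    missing_z <- unique(out[is.na(rate), zone])
    if (length(missing_z) > 0 && !all(missing_z %in% zd$zone)) {
      stop("cells mapped to unknown zones: ",
           paste(head(missing_z, 5), collapse = ", "))
    }
  }
  out[, est_damaged := fifelse(households == 0, 0, rate * households)]
  out[, rate_per_1000 := rate * 1000]
  out[, rate := NULL]
  out[]
}

#' Damage-capacity association
#'
#' Pearson correlation and ordinary least-squares fit of per-cell damage
#' estimates against resilience capacity. A negative correlation indicates
#' neighborhoods with higher resilience capacity experienced less damage.
#'
#' @param damage data.table `col`, `row` and a damage column.
#' @param profiles data.table `col`, `row` and an `rc` column.
#' @param damage_col name of the damage column (default `"est_damaged"`).
#' @return list `r` (Pearson), `slope`, `intercept`, `n`, `sign`.
#' @export
damage_capacity_association <- function(damage, profiles,
                                        damage_col = "est_damaged") {
  d <- as.data.table(damage)[, c("col", "row", damage_col), with = FALSE]
  setnames(d, damage_col, "dmg")
  p <- as.data.table(profiles)[, .(col, row, rc)]
  m <- p[d, on = c("col", "row"), nomatch = NULL]
  m <- m[complete.cases(m)]
  if (nrow(m) < 3L) stop("need at least 3 paired cells")
  if (stats::sd(m$dmg) == 0 || stats::sd(m$rc) == 0) {
    warning("zero-variance input; association undefined")
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = nrow(m), sign = NA_character_))
  }
  r <- cor(m$rc, m$dmg)
  fit <- lm(dmg ~ rc, data = m)
  list(r = r, slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = nrow(m), sign = if (r < 0) "negative" else "non-negative")
}
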