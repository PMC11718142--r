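#' Empty monthly source table
#'
#' The canonical per-block container of monthly N source inputs, all in
#' kg N ha^-1 month^-1.
#'
#' @return A data.frame of class `monthly_sources` with 12 rows (one per
#'   calendar month) and the source columns `urine_n`, `dung_n`,
#'   `effluent_n`, `fert_n`, `residue_ag_n`, `residue_bg_n`,
#'   `cultivation_n`, `erosion_n`, all zero.
#' @export
monthly_sources <- function() {
  out <- data.frame(month = 1:12, urine_n = 0, dung_n = 0, effluent_n = 0,
                    fert_n = 0, residue_ag_n = 0, residue_bg_n = 0,
                    cultivation_n = 0, erosion_n = 0)
  class(out) <- c("monthly_sources", "data.frame")
  out
}

#' @keywords internal
.source_categories <- c("urine_n", "dung_n", "effluent_n", "fert_n",
                        "residue_ag_n", "residue_bg_n", "cultivation_n",
                        "erosion_n")

.check_sources <- function(sources) {
  missing_cols <- setdiff(c("month", .source_categories), names(sources))
  if (length(missing_cols) > 0) {
    stop("source table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  vals <- as.matrix(sources[, .source_categories])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all monthly source inputs must be finite and >= 0")
  }
  invisible(sources)
}

#' Livestock excreta and effluent N
#'
#' Converts monthly head counts into per-hectare urine-N, dung-N and dairy
#' effluent N using a rate table of per-head monthly excretion.
#'
#' @param stock data.frame of monthly stock: columns `month`, `stock_class`,
#'   `age_class`, `region`, `head`. Zero rows means no animals.
#' @param rates excreta rate table: columns `stock_class`, `age_class`,
#'   `region`, `urine_n_kg_head`, `dung_n_kg_head` (kg N head^-1 month^-1).
#' @param area_ha block area, ha.
#' @param effluent list with `milking_class` (stock class whose head count
#'   drives dairy-shed effluent, default `"dairy_milking"`) and
#'   `n_kg_head_month` (effluent N yield per milking cow per month).
#'
#' @return data.frame with columns `month`, `urine_n`, `dung_n`,
#'   `effluent_n` (kg N ha^-1 month^-1) for months 1--12.
#' @export
excreta_n <- function(stock, rates, area_ha,
                      effluent = list(milking_class = "dairy_milking",
                                      n_kg_head_month = 0.9)) {
  if (area_ha <= 0) stop("area_ha must be > 0")
  out <- data.frame(month = 1:12, urine_n = 0, dung_n = 0, effluent_n = 0)
  if (is.null(stock) || nrow(stock) == 0) return(out)
  if (any(stock$head < 0)) stop("head counts must be >= 0")
  key <- function(d) paste(d$stock_class, d$age_class, d$region, sep = "|")
  rk <- key(rates)
  if (anyDuplicated(rk)) {
    stop("excreta rate table has duplicate (stock_class, age_class, region) keys")
  }
  idx <- match(key(stock), rk)
  if (anyNA(idx)) {
    miss <- unique(key(stock)[is.na(idx)])
    stop("no excreta rate for stock key(s): ", paste(miss, collapse = "; "))
  }
  urine <- stock$head * rates$urine_n_kg_head[idx] / area_ha
  dung <- stock$head * rates$dung_n_kg_head[idx] / area_ha
  m <- factor(stock$month, levels = 1:12)
  out$urine_n <- as.numeric(tapply(urine, m, sum, default = 0))
  out$dung_n <- as.numeric(tapply(dung, m, sum, default = 0))
  milking <- stock$stock_class == effluent$milking_class
  if (any(milking)) {
    eff <- stock$head[milking] * effluent$n_kg_head_month / area_ha
    out$effluent_n <- as.numeric(tapply(eff, m[milking], sum, default = 0))
  }
  out
}

#' Fertilizer N by month
#'
#' @param applications data.frame with columns `product_id`,
#'   `mass_kg_ha` and `month`. Zero rows means no fertilizer.
#' @param products product table: columns `product_id`, `n_fraction`
#'   (N mass fraction in \[0, 1\]).
#' @return numeric vector of length 12: kg N ha^-1 in each calendar month.
#' @export
fertilizer_n <- function(applications, products) {
  out <- numeric(12)
  if (is.null(applications) || nrow(applications) == 0) return(out)
  if (any(applications$mass_kg_ha < 0)) stop("fertilizer mass must be >= 0")
  if (any(products$n_fraction < 0 | products$n_fraction > 1)) {
    stop("product n_fraction must lie in [0, 1]")
  }
  idx <- match(applications$product_id, products$product_id)
  if (anyNA(idx)) {
    stop("unknown fertilizer product id(s): ",
         paste(unique(applications$product_id[is.na(idx)]), collapse = ", "))
  }
  n_applied <- applications$mass_kg_ha * products$n_fraction[idx]
  m <- factor(applications$month, levels = 1:12)
  as.numeric(tapply(n_applied, m, sum, default = 0))
}

#' Crop residue N release schedule
#'
#' Residue N is released to the soil over the three months following harvest
#' only when the residue C:N ratio is below 25; otherwise the N is treated as
#' microbially immobilized and poses no loss risk. Belowground release is
#' increased by 40 \% for shallow-rooting crops and decreased by 30 \% for
#' deep-rooting crops (unchanged for intermediate rooting), reflecting N that
#' roots of the previous crop could have captured.
#'
#' @param crop a list or one-row data.frame with `yield_t_ha`,
#'   `residue_fraction` (fraction of aboveground biomass left after harvest),
#'   `n_conc_ag`, `n_conc_bg` (kg N per t yield, above/below ground),
#'   `cn_ratio`, and `rooting` in `"shallow"`, `"intermediate"`, `"deep"`.
#' @param harvest_month calendar month of harvest (1--12).
#' @param cn_threshold C:N ratio above which residue N is immobilized.
#' @return data.frame with columns `month`, `residue_ag_n`, `residue_bg_n`
#'   (kg N ha^-1 month^-1) for months 1--12; release lands in months
#'   harvest+1, harvest+2, harvest+3 (wrapping the calendar), split equally.
#' @export
residue_n <- function(crop, harvest_month, cn_threshold = 25) {
  if (!harvest_month %in% 1:12) stop("harvest_month must be in 1..12")
  crop <- as.list(crop)
  if (crop$yield_t_ha < 0) stop("yield must be >= 0")
  if (crop$cn_ratio <= 0) stop("C:N ratio must be > 0")
  mult <- switch(crop$rooting,
                 shallow = 1.4, deep = 0.7, intermediate = 1.0,
                 stop("unknown rooting class '", crop$rooting, "'"))
  out <- data.frame(month = 1:12, residue_ag_n = 0, residue_bg_n = 0)
  if (crop$cn_ratio >= cn_threshold) return(out) # immobilized
  ag_total <- crop$yield_t_ha * crop$residue_fraction * crop$n_conc_ag
  bg_total <- crop$yield_t_ha * crop$residue_fraction * crop$n_conc_bg * mult
  months <- ((harvest_month + 0:2) %% 12) + 1 # h+1, h+2, h+3
  out$residue_ag_n[months] <- ag_total / 3
  out$residue_bg_n[months] <- bg_total / 3
  out
}

#' Cultivation mineralization N
#'
#' First-order release of a mineralizable-N pool triggered by cultivating
#' pasture. The pool size depends on pasture age (long-term pastures hold
#' more mineralizable N than short, < 3-year pastures) and enterprise.
#' Fallow months stretch the release horizon. The release rate is set so
#' that 99.5 \% of the pool is released within the horizon (the configured
#' pool is conserved to well within 1 \%).
#'
#' @param age_class `"short"` (< 3 years) or `"long"` (long-term pasture).
#' @param enterprise `"dairy"` or `"sheep-and-beef"`.
#' @param cultivation_month calendar month of cultivation (1--12); release
#'   starts in this month.
#' @param fallow_months months of fallow, each adding one month to the
#'   release horizon.
#' @param pools named pool sizes, kg N ha^-1.
#' @param enterprise_factor named multipliers on the pool by enterprise.
#' @param horizon_months base release horizon, months.
#' @param pool_kg_ha optional explicit pool size overriding the lookup (for
#'   example, derived from a measured soil N stock).
#' @return data.frame `month` (1--12, wrapping), `cultivation_n`
#'   (kg N ha^-1 month^-1); months beyond the calendar wrap around, so
#'   12-month totals equal the released fraction of the pool.
#' @export
cultivation_n <- function(age_class = c("long", "short"),
                          enterprise = c("dairy", "sheep-and-beef"),
                          cultivation_month = 10, fallow_months = 0,
                          pools = c(short = 150, long = 300),
                          enterprise_factor = c("dairy" = 1, "sheep-and-beef" = 0.8),
                          horizon_months = 6, pool_kg_ha = NULL) {
  age_class <- match.arg(age_class)
  enterprise <- match.arg(enterprise)
  if (!cultivation_month %in% 1:12) stop("cultivation_month must be in 1..12")
  if (fallow_months < 0) stop("fallow_months must be >= 0")
  pool <- if (!is.null(pool_kg_ha)) pool_kg_ha else {
    pools[[age_class]] * enterprise_factor[[enterprise]]
  }
  H <- horizon_months + fallow_months
  k <- log(200) / H # 99.5 % released over the horizon
  i <- seq_len(H)
  release <- pool * (exp(-k * (i - 1)) - exp(-k * i))
  out <- data.frame(month = 1:12, cultivation_n = 0)
  months <- ((cultivation_month - 1 + i - 1) %% 12) + 1
  for (j in seq_len(H)) {
    out$cultivation_n[months[j]] <- out$cultivation_n[months[j]] + release[j]
  }
  out
}

#' Erosion-borne soil N per season
#'
#' Estimated sediment yield is cover factor x land-use multiplier (t ha^-1),
#' then calibrated against observed yields via the linear correction
#' `max(0, 0.92 x estimated - 15.7)`. Eroded soil carries the soil's total N
#' at its mass fraction; the seasonal N loss is spread equally over the
#' season's three months.
#'
#' @param cover_factor RUSLE-style cover factor (>= 0) for the season.
#' @param multiplier land-use sediment multiplier (dimensionless, the
#'   calibrated range spans roughly 70--800).
#' @param soil_n_fraction soil total N, kg N per kg soil.
#' @param calibration named vector `c(slope = , intercept = )` of the
#'   sediment calibration line (t ha^-1 scale).
#' @return list with `estimated_t_ha`, `calibrated_t_ha`, `erosion_n_kg_ha`
#'   (seasonal total) and `monthly_n_kg_ha` (per month of the season).
#' @export
erosion_n <- function(cover_factor, multiplier, soil_n_fraction,
                      calibration = c(slope = 0.92, intercept = -15.7)) {
  if (cover_factor < 0) stop("cover_factor must be >= 0")
  if (multiplier <= 0) stop("multiplier must be > 0")
  if (soil_n_fraction < 0) stop("soil_n_fraction must be >= 0")
  est <- cover_factor * multiplier
  cal <- max(0, calibration[["slope"]] * est + calibration[["intercept"]])
  n_kg <- cal * 1000 * soil_n_fraction # t sediment -> kg, times N fraction
  list(estimated_t_ha = est, calibrated_t_ha = cal,
       erosion_n_kg_ha = n_kg, monthly_n_kg_ha = n_kg / 3)
}

#' Season to month lookup (southern hemisphere)
#'
#' @param season one of `"summer"`, `"autumn"`, `"winter"`, `"spring"`.
#' @return integer vector of the season's three calendar months.
#' @export
season_months <- function(season) {
  switch(season,
         summer = c(12L, 1L, 2L),
         autumn = 3:5, winter = 6:8, spring = 9:11,
         stop("unknown season '", season, "'"))
}

#' Assemble the monthly source table for one block
#'
#' Runs every source operation over a block management calendar and sums the
#' results into a single [monthly_sources()] table.
#'
#' @param calendar a list describing one block's year of management:
#'   `area_ha`; optional `stock` (see [excreta_n()]), `fertilizer`
#'   (see [fertilizer_n()]), `crops` (data.frame of crop records with a
#'   `harvest_month` column), `cultivation` (data.frame with `age_class`,
#'   `enterprise`, `cultivation_month`, `fallow_months`), `erosion`
#'   (data.frame with `season`, `cover_factor`, `multiplier`); and
#'   `tables`, a list with `excreta_rates` and `fertilizer_products`.
#' @param soil_n_fraction soil total N fraction used for erosion N.
#' @param effluent effluent parameters passed to [excreta_n()].
#' @return a [monthly_sources()] data.frame.
#' @export
assemble_monthly_sources <- function(calendar, soil_n_fraction = 0.003,
                                     effluent = list(milking_class = "dairy_milking",
                                                     n_kg_head_month = 0.9)) {
  out <- monthly_sources()
  if (!is.null(calendar$stock) && nrow(calendar$stock) > 0) {
    ex <- excreta_n(calendar$stock, calendar$tables$excreta_rates,
                    calendar$area_ha, effluent = effluent)
    out$urine_n <- ex$urine_n
    out$dung_n <- ex$dung_n
    out$effluent_n <- ex$effluent_n
  }
  if (!is.null(calendar$fertilizer) && nrow(calendar$fertilizer) > 0) {
    out$fert_n <- fertilizer_n(calendar$fertilizer,
                               calendar$tables$fertilizer_products)
  }
  if (!is.null(calendar$crops) && nrow(calendar$crops) > 0) {
    for (i in seq_len(nrow(calendar$crops))) {
      cr <- calendar$crops[i, ]
      res <- residue_n(cr, cr$harvest_month)
      out$residue_ag_n <- out$residue_ag_n + res$residue_ag_n
      out$residue_bg_n <- out$residue_bg_n + res$residue_bg_n
    }
  }
  if (!is.null(calendar$cultivation) && nrow(calendar$cultivation) > 0) {
    for (i in seq_len(nrow(calendar$cultivation))) {
      cu <- calendar$cultivation[i, ]
      cn <- cultivation_n(age_class = cu$age_class, enterprise = cu$enterprise,
                          cultivation_month = cu$cultivation_month,
                          fallow_months = cu$fallow_months)
      out$cultivation_n <- out$cultivation_n + cn$cultivation_n
    }
  }
  if (!is.null(calendar$erosion) && nrow(calendar$erosion) > 0) {
    for (i in seq_len(nrow(calendar$erosion))) {
      er <- calendar$erosion[i, ]
      en <- erosion_n(er$cover_factor, er$multiplier, soil_n_fraction)
      out$erosion_n[season_months(er$season)] <-
        out$erosion_n[season_months(er$season)] + en$monthly_n_kg_ha
    }
  }
  .check_sources(out)
  out
}
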