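#' Transport protocol configuration
#'
#' Defaults follow the transport-risk protocol: a single conservative tracer
#' application of 450 kg N ha^-1 on the 15th of a month, leaching accounted
#' past 1000 mm depth over the following 730 days and normalized by the
#' applied mass, runoff summed over the 30 days after application and
#' normalized by 200 mm (the 95th-percentile benchmark), capped at 1.
#'
#' @param tracer_mass applied tracer, kg N ha^-1.
#' @param application_day day of month of the application.
#' @param leach_horizon_days accounting horizon for leaching, days.
#' @param leach_depth_mm depth past which drainage counts as leached, mm.
#' @param runoff_window_days accounting window for runoff, days.
#' @param runoff_normalizer_mm runoff normalizer, mm.
#' @param slope_runoff_multiplier named multipliers on the runoff curve
#'   parameter per slope class; the effective parameter is capped at 1.
#' @param irrigation_months calendar months in which irrigation may be
#'   applied (southern-hemisphere season, October--April).
#' @param irrigation_trigger irrigation refills the profile to field capacity
#'   when plant-available storage falls below this fraction of
#'   plant-available capacity.
#'
#' @return A list of class `transport_config`.
#' @export
transport_config <- function(tracer_mass = 450,
                             application_day = 15,
                             leach_horizon_days = 730,
                             leach_depth_mm = 1000,
                             runoff_window_days = 30,
                             runoff_normalizer_mm = 200,
                             slope_runoff_multiplier = c(flat = 1, rolling = 1.2,
                                                         easy = 1.5, steep = 2),
                             irrigation_months = c(10:12, 1:4),
                             irrigation_trigger = 0.5) {
  vals <- c(tracer_mass, application_day, leach_horizon_days, leach_depth_mm,
            runoff_window_days, runoff_normalizer_mm, irrigation_trigger)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all transport protocol parameters must be strictly positive")
  }
  if (!all(.slope_levels %in% names(slope_runoff_multiplier))) {
    stop("slope_runoff_multiplier must name all of: ",
         paste(.slope_levels, collapse = ", "))
  }
  structure(
    list(tracer_mass = tracer_mass,
         application_day = application_day,
         leach_horizon_days = leach_horizon_days,
         leach_depth_mm = leach_depth_mm,
         runoff_window_days = runoff_window_days,
         runoff_normalizer_mm = runoff_normalizer_mm,
         slope_runoff_multiplier = slope_runoff_multiplier,
         irrigation_months = irrigation_months,
         irrigation_trigger = irrigation_trigger),
    class = "transport_config"
  )
}

#' Simulate the daily soil water balance
#'
#' A tipping-bucket cascade. Each day: (i) runoff is partitioned from rain as
#' `rain * min(1, curve * slope multiplier) * wetness`, where wetness is the
#' antecedent relative saturation of the top layer; (ii) the remaining rain
#' infiltrates and cascades down: a fraction `k_drain` of the water each
#' layer holds above field capacity drains to the layer below, and the
#' outflow of the bottom layer is deep drainage; saturation excess backs up
#' the profile and exits as additional surface runoff (water never bypasses
#' a layer that cannot transmit it); (iii) evaporative demand is satisfied
#' top-down from water held above wilting point; (iv) on irrigated profiles,
#' inside the irrigation season,
#' the profile is refilled to field capacity at the end of any day on which
#' plant-available storage has fallen below the trigger fraction.
#'
#' Daily water conservation, rain + irrigation = runoff + deep drainage +
#' evapotranspiration + storage change, holds to machine precision and is
#' reported per day in the `balance_error` column.
#'
#' @param soil a [soil_profile()].
#' @param climate a [climate_series()]; at least `leach_horizon_days + 30`
#'   days when the balance feeds risk estimation.
#' @param irrigated logical.
#' @param slope slope class label (affects only the runoff partition).
#' @param config a [transport_config()].
#' @param initial_fraction initial storage as a fraction of the field-capacity
#'   to wilting-point range (1 = start at field capacity).
#'
#' @return A list of class `water_balance`: `daily`, a data.frame with
#'   columns `date`, `rain_mm`, `irrigation_mm`, `runoff_mm`, `et_mm`,
#'   `drainage_mm` (deep drainage below the profile), `storage_mm` and
#'   `balance_error`; `flux_out`, an (n days x n layers) matrix of water
#'   leaving each layer downward; `w_mix`, the layer storages at mixing time
#'   (after inflow, before outflow) used for tracer transport; and the layer
#'   index `leach_layer` whose outflow crosses the accounting depth.
#' @export
simulate_water_balance <- function(soil, climate, irrigated = FALSE,
                                   slope = "flat",
                                   config = transport_config(),
                                   initial_fraction = 1) {
  stopifnot(inherits(soil, "soil_profile"))
  if (!inherits(climate, "climate_series")) {
    climate <- climate_series(climate$date, climate$rain_mm, climate$pet_mm)
  }
  .check_slope(slope)
  if (soil$profile_depth_mm < config$leach_depth_mm) {
    stop("soil profile (", soil$profile_depth_mm, " mm) does not reach the ",
         "leaching accounting depth of ", config$leach_depth_mm, " mm")
  }
  mm <- .layer_mm(soil)
  L <- length(mm$sat)
  leach_layer <- which(mm$bottom_depth >= config$leach_depth_mm)[1]

  n <- nrow(climate)
  rain <- climate$rain_mm
  pet <- climate$pet_mm
  month <- as.integer(format(climate$date, "%m"))

  c_eff <- min(1, soil$runoff_curve * config$slope_runoff_multiplier[[slope]])
  paw_cap <- sum(mm$fc - mm$wp)
  trigger_mm <- config$irrigation_trigger * paw_cap
  irrigable <- irrigated & (month %in% config$irrigation_months)

  W <- mm$wp + initial_fraction * (mm$fc - mm$wp)
  runoff <- et <- drain_bot <- irr <- storage <- balerr <- numeric(n)
  flux_out <- matrix(0, n, L)
  w_mix <- matrix(0, n, L)

  sat <- mm$sat; fc <- mm$fc; wp <- mm$wp; k <- mm$k
  for (t in seq_len(n)) {
    w0 <- sum(W)
    r <- rain[t]
    ro <- 0
    if (r > 0) {
      wet <- (W[1] - wp[1]) / (sat[1] - wp[1])
      wet <- min(1, max(0, wet))
      ro <- r * c_eff * wet
    }
    inflow <- r - ro
    for (l in 1:L) {
      Wl <- W[l] + inflow
      w_mix[t, l] <- Wl
      dr <- if (Wl > fc[l]) k[l] * (Wl - fc[l]) else 0
      W[l] <- Wl - dr
      inflow <- dr
      flux_out[t, l] <- dr
    }
    drain_bot[t] <- inflow
    # saturation excess backs up the profile and exits as surface runoff:
    # water that a layer cannot hold never bypasses it downward
    if (any(W > sat)) {
      if (L > 1) {
        for (l in L:2) {
          ex <- W[l] - sat[l]
          if (ex > 0) {
            W[l] <- sat[l]
            W[l - 1] <- W[l - 1] + ex
          }
        }
      }
      ex <- W[1] - sat[1]
      if (ex > 0) {
        W[1] <- sat[1]
        ro <- ro + ex
      }
    }
    # evaporative demand, top-down, limited by water above wilting point
    demand <- pet[t]
    taken <- 0
    if (demand > 0) {
      for (l in 1:L) {
        avail <- W[l] - wp[l]
        if (avail <= 0) next
        take <- min(demand, avail)
        W[l] <- W[l] - take
        taken <- taken + take
        demand <- demand - take
        if (demand <= 0) break
      }
    }
    et[t] <- taken
    if (irrigable[t]) {
      if (sum(pmax(W - wp, 0)) < trigger_mm) {
        add <- pmax(fc - W, 0)
        W <- W + add
        irr[t] <- sum(add)
      }
    }
    runoff[t] <- ro
    storage[t] <- sum(W)
    balerr[t] <- (r + irr[t]) - (ro + drain_bot[t] + et[t] + (storage[t] - w0))
  }

  structure(
    list(
      daily = data.frame(date = climate$date, rain_mm = rain,
                         irrigation_mm = irr, runoff_mm = runoff, et_mm = et,
                         drainage_mm = drain_bot, storage_mm = storage,
                         balance_error = balerr),
      flux_out = flux_out,
      w_mix = w_mix,
      leach_layer = leach_layer,
      slope = slope,
      irrigated = irrigated,
      config = config
    ),
    class = "water_balance"
  )
}

# Days on which the tracer is applied for a given calendar month: the
# application_day of that month in every simulated year for which the full
# leaching horizon fits inside the climate record.
.application_days <- function(dates, month, config) {
  n <- length(dates)
  idx <- which(as.integer(format(dates, "%m")) == month &
               as.integer(format(dates, "%d")) == config$application_day)
  idx[idx + config$leach_horizon_days - 1 <= n]
}

# Propagate conservative tracers through stored water fluxes.
# apps: vector of application day indices (one tracer each). Complete mixing
# within each layer: the fraction of a layer's tracer leaving on a day equals
# the fraction of its mixing-time storage that leaves downward.
# Returns leached mass (past leach_layer within the horizon) per application.
.tracer_leached <- function(wb, apps, config) {
  flux <- wb$flux_out
  wmix <- wb$w_mix
  L <- ncol(flux)
  iL <- wb$leach_layer
  K <- length(apps)
  if (K == 0) return(numeric(0))
  m <- matrix(0, L, K) # tracer mass per layer per application
  leached <- numeric(K)
  t0 <- min(apps)
  tend <- max(apps) + config$leach_horizon_days - 1
  tend <- min(tend, nrow(flux))
  frac <- ifelse(wmix > 0, flux / wmix, 0)
  for (t in t0:tend) {
    started <- apps == t
    if (any(started)) m[1, started] <- m[1, started] + config$tracer_mass
    active <- t >= apps & t <= apps + config$leach_horizon_days - 1
    if (!any(active)) next
    inflow <- numeric(K)
    for (l in 1:L) {
      ml <- m[l, ] + inflow
      out <- ml * frac[t, l]
      m[l, ] <- ml - out
      if (l == iL) leached <- leached + ifelse(active, out, 0)
      inflow <- out
    }
  }
  leached
}

#' Monthly transport risk for one soil x climate x slope x irrigation setting
#'
#' Applies the configured tracer mass on the application day of the given
#' calendar month in every simulated year whose leaching horizon fits in the
#' climate record, and returns the across-year mean of (i) the fraction of
#' tracer drained past the accounting depth within the horizon and (ii) the
#' capped, normalized runoff sum in the runoff window.
#'
#' @inheritParams simulate_water_balance
#' @param month calendar month 1--12. May be a vector; the default computes
#'   all 12 months in one pass (the water balance is simulated once).
#' @param wb optionally, a precomputed [simulate_water_balance()] result for
#'   the same inputs, to avoid re-simulation.
#'
#' @return A data.frame with columns `month`, `leach_risk`, `runoff_risk`,
#'   `n_years` (application years averaged). Both risks lie in \[0, 1\].
#' @export
monthly_transport_risk <- function(soil, climate, slope = "flat",
                                   irrigated = FALSE, month = 1:12,
                                   config = transport_config(), wb = NULL) {
  if (any(!month %in% 1:12)) stop("month must be in 1..12")
  if (!inherits(climate, "climate_series")) {
    climate <- climate_series(climate$date, climate$rain_mm, climate$pet_mm)
  }
  if (nrow(climate) < config$leach_horizon_days + config$runoff_window_days) {
    stop("climate record too short: need at least ",
         config$leach_horizon_days + config$runoff_window_days, " days")
  }
  if (is.null(wb)) {
    wb <- simulate_water_balance(soil, climate, irrigated = irrigated,
                                 slope = slope, config = config)
  }
  runoff <- wb$daily$runoff_mm
  n <- length(runoff)
  app_list <- lapply(month, function(m) .application_days(climate$date, m, config))
  empty <- lengths(app_list) == 0
  if (any(empty)) {
    stop("no application of month ", paste(month[empty], collapse = ", "),
         " fits the leaching horizon; supply a longer climate record")
  }
  apps <- unlist(app_list)
  # one tracer per application, all months propagated in a single pass
  leached <- .tracer_leached(wb, apps, config)
  grp <- rep(seq_along(month), lengths(app_list))
  lr <- tapply(leached, grp, mean) / config$tracer_mass
  rr_app <- vapply(apps, function(a) {
    w <- a:min(a + config$runoff_window_days - 1, n)
    min(1, sum(runoff[w]) / config$runoff_normalizer_mm)
  }, numeric(1))
  data.frame(month = month,
             leach_risk = pmin(1, pmax(0, as.numeric(lr))),
             runoff_risk = as.numeric(tapply(rr_app, grp, mean)),
             n_years = as.integer(lengths(app_list)))
}

#' Build a transport risk table for a set of locations
#'
#' @param locations a list of location specifications, each a list with
#'   elements `location_id`, `soil` (a [soil_profile()]), `climate` (a
#'   [climate_series()]), `slope` (class label), `irrigated` (logical), and
#'   optionally `lon`/`lat`.
#' @param config a [transport_config()].
#'
#' @return A data.frame of class `transport_table` with one row per location
#'   and calendar month: `location_id`, `soil_id`, `slope`, `irrigated`,
#'   `month`, `leach_risk`, `runoff_risk` (plus `lon`/`lat` when supplied).
#' @export
build_transport_table <- function(locations, config = transport_config()) {
  if (length(locations) == 0) stop("locations must be non-empty")
  ids <- vapply(locations, function(x) as.character(x$location_id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate location ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(locations, function(loc) {
    risks <- monthly_transport_risk(loc$soil, loc$climate, slope = loc$slope,
                                    irrigated = isTRUE(loc$irrigated),
                                    config = config)
    out <- data.frame(
      location_id = as.character(loc$location_id),
      soil_id = if (!is.null(loc$soil$id)) loc$soil$id else NA_character_,
      slope = loc$slope,
      irrigated = isTRUE(loc$irrigated),
      month = risks$month,
      leach_risk = risks$leach_risk,
      runoff_risk = risks$runoff_risk
    )
    if (!is.null(loc$lon) && !is.null(loc$lat)) {
      out$lon <- loc$lon
      out$lat <- loc$lat
    }
    out
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  class(tbl) <- c("transport_table", "data.frame")
  tbl
}
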