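#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator: the seed (which fixes all outputs),
#' farm size and land-use mix, the climate regime of the two-state Markov
#' weather generator, the observation noise model, and the vegetable
#' attenuation used to exercise the scale-factor diagnosis.
#'
#' @param seed integer; fixes all generated outputs.
#' @param n_blocks number of blocks on the fixture farm.
#' @param land_use_mix named probability weights over land uses.
#' @param annual_rain_mm expected annual rainfall.
#' @param seasonality amplitude in \[0, 1\] of the sinusoidal seasonal cycle
#'   on wet-day probability (winter-wet) and PET (summer-peaked).
#' @param storm_frequency baseline probability that a dry day is followed by
#'   a wet day; 0 gives a permanently dry (storm-free) climate.
#' @param wet_persistence probability that a wet day is followed by a wet
#'   day.
#' @param n_years years of daily weather to generate.
#' @param obs_noise_sdlog lognormal (sdlog) multiplicative noise on the
#'   risk-to-loss link; 0 gives a noiseless monotone link.
#' @param obs_link named vector `c(intercept = , slope = )` of the affine
#'   risk-to-loss link (kg N ha^-1 yr^-1 per unit risk), slope > 0.
#' @param vegetable_attenuation factor by which the index under-scores
#'   vegetable blocks (the generated losses respond to `risk x factor`).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 42L, n_blocks = 12,
                            land_use_mix = c(dairy = 0.35, `sheep-and-beef` = 0.3,
                                             cropping = 0.2, vegetables = 0.15),
                            annual_rain_mm = 1200, seasonality = 0.4,
                            storm_frequency = 0.3, wet_persistence = 0.55,
                            n_years = 3,
                            obs_noise_sdlog = 0.4,
                            obs_link = c(intercept = 2, slope = 1.5),
                            vegetable_attenuation = 6) {
  stopifnot(annual_rain_mm >= 0, storm_frequency >= 0, storm_frequency <= 1,
            wet_persistence >= 0, wet_persistence < 1,
            seasonality >= 0, seasonality <= 1,
            obs_noise_sdlog >= 0, obs_link[["slope"]] > 0,
            vegetable_attenuation > 0, n_blocks >= 1, n_years >= 3)
  structure(as.list(environment()), class = "scenario_config")
}

#' Soil archetypes
#'
#' Three contrasting profiles: a stony, shallow, freely draining soil; a
#' deep, fine-textured, water-retentive soil; and an intermediate profile.
#' The stony-shallow archetype stores little water and drains fast, so it
#' leaches readily; the deep-fine archetype holds water and sheds more rain
#' as runoff.
#'
#' @param type `"stony_shallow"`, `"deep_fine"` or `"intermediate"`.
#' @return a [soil_profile()].
#' @export
soil_archetype <- function(type = c("stony_shallow", "deep_fine",
                                    "intermediate")) {
  type <- match.arg(type)
  switch(type,
    stony_shallow = soil_profile(
      data.frame(thickness_mm = c(350, 350, 350),
                 theta_sat = 0.40, theta_fc = 0.16, theta_wp = 0.07,
                 k_drain = 0.9),
      runoff_curve = 0.2, total_n_fraction = 0.002, bulk_density = 1.5,
      id = "stony_shallow"),
    deep_fine = soil_profile(
      data.frame(thickness_mm = c(300, 400, 400, 400),
                 theta_sat = 0.52, theta_fc = 0.40, theta_wp = 0.22,
                 k_drain = 0.12),
      runoff_curve = 0.5, total_n_fraction = 0.004, bulk_density = 1.1,
      id = "deep_fine"),
    intermediate = soil_profile(
      data.frame(thickness_mm = c(300, 400, 500),
                 theta_sat = 0.46, theta_fc = 0.28, theta_wp = 0.14,
                 k_drain = 0.4),
      runoff_curve = 0.35, total_n_fraction = 0.003, bulk_density = 1.3,
      id = "intermediate"))
}

#' Generate a daily climate series
#'
#' Two-state (wet/dry) Markov chain with gamma-distributed wet-day depths
#' and sinusoidal seasonality: wet-day probability peaks in winter (July),
#' PET peaks in mid-January (southern hemisphere). The gamma mean is
#' calibrated so that the expected annual total matches `annual_rain_mm`.
#' Reproducible under the active RNG state; call inside
#' [generate_fixture_farm()] or after `set.seed()` for determinism.
#'
#' @param config a [scenario_config()].
#' @param n_years years of daily weather (default from `config`).
#' @param start first day of the series.
#' @return a [climate_series()].
#' @export
generate_climate <- function(config, n_years = config$n_years,
                             start = as.Date("2001-01-01")) {
  dates <- seq(start, by = "day", length.out = round(365.25 * n_years))
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  season <- cos(2 * pi * (doy - 196) / 365.25) # peaks at doy 196 (mid-July)
  p_wd <- pmin(1, pmax(0, config$storm_frequency * (1 + config$seasonality * season)))
  p_ww <- pmin(0.95, pmax(0, config$wet_persistence * (1 + 0.5 * config$seasonality * season)))
  wet <- logical(n)
  u <- stats::runif(n)
  state <- FALSE
  for (t in seq_len(n)) {
    p <- if (state) p_ww[t] else p_wd[t]
    state <- u[t] < p
    wet[t] <- state
  }
  # stationary wet fraction at mean transition rates calibrates the depth
  pw <- mean(p_wd) / (1 + mean(p_wd) - mean(p_ww))
  mean_depth <- if (pw > 0) config$annual_rain_mm / (365.25 * pw) else 0
  shape <- 0.8
  rain <- numeric(n)
  if (any(wet) && mean_depth > 0) {
    rain[wet] <- stats::rgamma(sum(wet), shape = shape,
                               scale = mean_depth / shape)
  }
  pet_season <- cos(2 * pi * (doy - 15) / 365.25) # peaks mid-January
  pet <- pmax(0, 3 * (1 + config$seasonality * pet_season))
  climate_series(dates, rain, pet)
}

.land_uses <- c("cropping", "dairy", "deer", "sheep-and-beef", "forestry",
                "horticulture", "vegetables")

#' Generate a complete fixture farm
#'
#' Deterministic under the configured seed. The farm always contains at
#' least one block on the stony-shallow and one on the deep-fine soil
#' archetype, and the calendars collectively exercise every source
#' category: pastoral blocks carry stock and fertilizer, cropping and
#' vegetable blocks carry crops, cultivation events and erosion contexts.
#'
#' @param config a [scenario_config()].
#' @return list of class `scenario`: `blocks` (data.frame), `soils` (named
#'   list of profiles), `climates` (named list of climate series),
#'   `calendars` (named list, one calendar per block, see
#'   [assemble_monthly_sources()]), `tables` (rate tables), and `config`.
#' @export
generate_fixture_farm <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  soils <- list(stony_shallow = soil_archetype("stony_shallow"),
                deep_fine = soil_archetype("deep_fine"),
                intermediate = soil_archetype("intermediate"))
  climates <- list(cell_1 = generate_climate(config))
  tables <- default_rate_tables()
  n <- config$n_blocks
  mix <- config$land_use_mix / sum(config$land_use_mix)
  land_use <- sample(names(mix), n, replace = TRUE, prob = mix)
  soil_id <- sample(names(soils), n, replace = TRUE)
  # guarantee the archetype contrast is present
  soil_id[1] <- "stony_shallow"
  if (n >= 2) soil_id[2] <- "deep_fine"
  blocks <- data.frame(
    block_id = sprintf("B%02d", seq_len(n)),
    area_ha = round(stats::runif(n, 5, 60), 1),
    land_use = land_use,
    soil_id = soil_id,
    slope = sample(.slope_levels, n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)),
    climate_id = "cell_1",
    irrigated = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
  blocks$location_id <- paste(blocks$climate_id, blocks$soil_id, blocks$slope,
                              ifelse(blocks$irrigated, "irr", "dry"),
                              sep = "_")
  calendars <- lapply(seq_len(n), function(i) {
    .block_calendar(blocks[i, ], tables)
  })
  names(calendars) <- blocks$block_id
  structure(list(blocks = blocks, soils = soils, climates = climates,
                 calendars = calendars, tables = tables, config = config),
            class = "scenario")
}

# One year of management for a block, by land use.
.block_calendar <- function(block, tables) {
  lu <- block$land_use
  area <- block$area_ha
  cal <- list(area_ha = area, land_use = lu, tables = tables)
  if (lu %in% c("dairy", "sheep-and-beef", "deer")) {
    cls <- switch(lu, dairy = "dairy_milking", `sheep-and-beef` = "sheep_ewe",
                  deer = "deer_hind")
    head <- switch(lu, dairy = round(2.6 * area), `sheep-and-beef` = round(10 * area),
                   deer = round(7 * area))
    cal$stock <- data.frame(month = 1:12, stock_class = cls,
                            age_class = "adult", region = "default",
                            head = head)
    cal$fertilizer <- data.frame(product_id = "urea",
                                 mass_kg_ha = c(60, 40),
                                 month = c(9, 3))
  }
  if (lu %in% c("cropping", "vegetables")) {
    crop_id <- if (lu == "vegetables") "onions" else "wheat"
    cr <- tables$crops[tables$crops$crop_id == crop_id, ]
    cr$harvest_month <- if (lu == "vegetables") 2L else 1L
    cal$crops <- cr
    cal$cultivation <- data.frame(age_class = "short",
                                  enterprise = "sheep-and-beef",
                                  cultivation_month = 9L, fallow_months = 1L)
    cal$fertilizer <- data.frame(product_id = c("urea", "dap"),
                                 mass_kg_ha = c(100, 150),
                                 month = c(10, 9))
    cal$erosion <- data.frame(season = c("winter", "spring"),
                              cover_factor = c(0.05, 0.03),
                              multiplier = 500)
  }
  if (lu %in% c("horticulture", "forestry")) {
    cal$fertilizer <- data.frame(product_id = "urea", mass_kg_ha = 30,
                                 month = 10)
  }
  if (lu %in% c("sheep-and-beef", "deer") && block$slope %in% c("easy", "steep")) {
    cal$erosion <- data.frame(season = "winter", cover_factor = 0.02,
                              multiplier = 800)
  }
  cal
}

#' Generate an observation set with known risk-loss structure
#'
#' Observed annual N losses are generated as a monotone, affine-in-risk
#' link with multiplicative lognormal noise:
#' `loss = (a + b x risk_effective) x exp(noise)`. For vegetable blocks the
#' effective risk is the reported risk times the configured attenuation
#' factor, emulating an index that consistently under-scores that land use
#' and enabling [scale_factor()] recovery. Losses are always >= 0.
#'
#' @param config a [scenario_config()].
#' @param risks data.frame with columns `block_id`, `land_use`, `risk`
#'   (typically the per-block annual `total` from [aggregate_risk()]) and
#'   optionally `flow_path`.
#' @return data.frame of observation records: `id`, `block_id`, `land_use`,
#'   `flow_path`, `measured`, `n_form`, `risk`, `loss` (kg N ha^-1 yr^-1),
#'   `confidence`.
#' @export
generate_observation_set <- function(config, risks) {
  stopifnot(inherits(config, "scenario_config"),
            all(c("block_id", "land_use", "risk") %in% names(risks)))
  set.seed(config$seed + 1L)
  n <- nrow(risks)
  a <- config$obs_link[["intercept"]]
  b <- config$obs_link[["slope"]]
  eff <- risks$risk * ifelse(risks$land_use == "vegetables",
                             config$vegetable_attenuation, 1)
  noise <- if (config$obs_noise_sdlog > 0) {
    exp(stats::rnorm(n, 0, config$obs_noise_sdlog))
  } else rep(1, n)
  loss <- (a + b * eff) * noise
  data.frame(
    id = sprintf("obs_%03d", seq_len(n)),
    block_id = risks$block_id,
    land_use = risks$land_use,
    flow_path = if ("flow_path" %in% names(risks)) risks$flow_path else
      sample(c("leaching", "runoff"), n, replace = TRUE, prob = c(0.7, 0.3)),
    measured = stats::runif(n) < 0.75,
    n_form = sample(c("nitrate-N", "total N"), n, replace = TRUE,
                    prob = c(0.8, 0.2)),
    risk = risks$risk,
    loss = loss,
    confidence = sample(c("high", "low"), n, replace = TRUE, prob = c(0.85, 0.15)),
    stringsAsFactors = FALSE
  )
}
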