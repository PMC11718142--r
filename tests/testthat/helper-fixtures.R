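# shared fixture builders (all data generated in code)

# single-layer 1000 mm profile: sat 500 / fc 300 / wp 100 mm
toy_soil <- function(k_drain = 0.5, runoff_curve = 0.4, thickness = 1000,
                     theta_sat = 0.5, theta_fc = 0.3, theta_wp = 0.1,
                     n_fraction = 0.003) {
  soil_profile(
    data.frame(thickness_mm = thickness, theta_sat = theta_sat,
               theta_fc = theta_fc, theta_wp = theta_wp, k_drain = k_drain),
    runoff_curve = runoff_curve, total_n_fraction = n_fraction
  )
}

const_climate <- function(n_days, rain = 0, pet = 0,
                          start = as.Date("2001-01-01")) {
  climate_series(seq(start, by = "day", length.out = n_days),
                 rep_len(rain, n_days), rep_len(pet, n_days))
}

# random but always-valid layered profile (uses the active RNG stream)
random_soil <- function() {
  nl <- sample(2:4, 1)
  thick <- runif(nl, 250, 600)
  thick <- thick * max(1, 1050 / sum(thick)) # ensure >= 1000 mm depth
  wp <- runif(nl, 0.05, 0.2)
  fc <- wp + runif(nl, 0.05, 0.25)
  sat <- fc + runif(nl, 0.05, 0.2)
  soil_profile(
    data.frame(thickness_mm = thick, theta_sat = sat, theta_fc = fc,
               theta_wp = wp, k_drain = runif(nl, 0.05, 1)),
    runoff_curve = runif(1, 0.1, 1)
  )
}

random_climate <- function(n_days = 800) {
  wet <- runif(n_days) < runif(1, 0.2, 0.5)
  rain <- ifelse(wet, rgamma(n_days, shape = 0.8, scale = runif(1, 4, 15)), 0)
  pet <- pmax(0, 3 + 1.5 * cos(2 * pi * (seq_len(n_days) - 15) / 365.25))
  const_climate(n_days)$date |>
    climate_series(rain, pet)
}

# one-row monthly source table helper for index tests
src_row <- function(urine = 0, dung = 0, effluent = 0, fert = 0, ag = 0,
                    bg = 0, cult = 0, erosion = 0, month = 1) {
  data.frame(month = month, urine_n = urine, dung_n = dung,
             effluent_n = effluent, fert_n = fert, residue_ag_n = ag,
             residue_bg_n = bg, cultivation_n = cult, erosion_n = erosion)
}
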