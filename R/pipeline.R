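#' Score a whole scenario
#'
#' Convenience pipeline: builds the transport risk table for the scenario's
#' distinct (climate, soil, slope, irrigation) combinations, assembles each
#' block's monthly source table from its management calendar, and computes
#' the baseline monthly risk scores.
#'
#' @param scenario a scenario from [generate_fixture_farm()] or
#'   [load_scenario()].
#' @param config a [transport_config()].
#' @param literal_eq2 passed to [risk_scores()].
#' @return list: `scores` (a [risk_scores()] data.frame), `transport` (the
#'   transport table), `sources` (named list of per-block
#'   [monthly_sources()] tables).
#' @export
score_scenario <- function(scenario, config = transport_config(),
                           literal_eq2 = FALSE) {
  blocks <- scenario$blocks
  locs <- unique(blocks[, c("location_id", "climate_id", "soil_id", "slope",
                            "irrigated")])
  location_list <- lapply(seq_len(nrow(locs)), function(i) {
    list(location_id = locs$location_id[i],
         soil = scenario$soils[[locs$soil_id[i]]],
         climate = scenario$climates[[locs$climate_id[i]]],
         slope = locs$slope[i],
         irrigated = locs$irrigated[i])
  })
  transport <- build_transport_table(location_list, config = config)
  sources <- lapply(blocks$block_id, function(b) {
    soil <- scenario$soils[[blocks$soil_id[blocks$block_id == b]]]
    assemble_monthly_sources(scenario$calendars[[b]],
                             soil_n_fraction = soil$total_n_fraction)
  })
  names(sources) <- blocks$block_id
  scores <- risk_scores(blocks, sources, transport, literal_eq2 = literal_eq2)
  list(scores = scores, transport = transport, sources = sources)
}
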