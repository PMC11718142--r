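#' Default rate tables shipped with the package
#'
#' Illustrative, fully configurable lookup tables: per-head monthly excreta
#' N rates, fertilizer product N fractions, crop residue parameters, and
#' land-use x slope erosion multipliers. These are synthetic placeholder
#' values documented for the package's fixtures; operational use should
#' substitute locally authoritative tables via the same CSV schemas.
#'
#' @return list with data.frames `excreta_rates`, `fertilizer_products`,
#'   `crops`, `erosion_multipliers`.
#' @export
default_rate_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "nriskindex",
                                  mustWork = TRUE)
  list(
    excreta_rates = utils::read.csv(path("excreta_rates.csv"),
                                    stringsAsFactors = FALSE),
    fertilizer_products = utils::read.csv(path("fertilizer_products.csv"),
                                          stringsAsFactors = FALSE),
    crops = utils::read.csv(path("crops.csv"), stringsAsFactors = FALSE),
    erosion_multipliers = utils::read.csv(path("erosion_multipliers.csv"),
                                          stringsAsFactors = FALSE)
  )
}

#' Read and write daily climate CSV (date, rain_mm, pet_mm)
#'
#' @param path file path.
#' @return [read_climate_csv()] returns a [climate_series()].
#' @export
read_climate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(d, c("date", "rain_mm", "pet_mm"), basename(path))
  climate_series(as.Date(d$date), d$rain_mm, d$pet_mm)
}

#' @rdname read_climate_csv
#' @param climate a [climate_series()].
#' @export
write_climate_csv <- function(climate, path) {
  utils::write.csv(as.data.frame(climate), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write soil profiles in long CSV form
#'
#' One row per layer: `soil_id`, `layer`, `thickness_mm`, `theta_sat`,
#' `theta_fc`, `theta_wp`, `k_drain`, plus the per-profile columns
#' `runoff_curve`, `total_n_fraction`, `bulk_density` (repeated per layer).
#'
#' @param path file path.
#' @return [read_soil_profiles_csv()] returns a named list of
#'   [soil_profile()] objects.
#' @export
read_soil_profiles_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(d, c("soil_id", "layer", "thickness_mm", "theta_sat",
                     "theta_fc", "theta_wp", "k_drain", "runoff_curve",
                     "total_n_fraction", "bulk_density"), basename(path))
  out <- lapply(split(d, d$soil_id), function(s) {
    s <- s[order(s$layer), ]
    soil_profile(s[, c("thickness_mm", "theta_sat", "theta_fc", "theta_wp",
                       "k_drain")],
                 runoff_curve = s$runoff_curve[1],
                 total_n_fraction = s$total_n_fraction[1],
                 bulk_density = s$bulk_density[1],
                 id = s$soil_id[1])
  })
  out[unique(d$soil_id)]
}

#' @rdname read_soil_profiles_csv
#' @param soils named list of [soil_profile()] objects.
#' @export
write_soil_profiles_csv <- function(soils, path) {
  rows <- lapply(soils, function(s) {
    cbind(data.frame(soil_id = s$id, layer = seq_len(nrow(s$layers))),
          s$layers,
          data.frame(runoff_curve = s$runoff_curve,
                     total_n_fraction = s$total_n_fraction,
                     bulk_density = s$bulk_density))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

.require_cols <- function(d, cols, where) {
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0) {
    stop("file '", where, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(d)
}

#' Write a scenario to a directory of CSV files
#'
#' Emits the complete file layout consumed by [load_scenario()]:
#' `blocks.csv`, `soils.csv`, one `climate_<id>.csv` per climate cell, the
#' management calendars (`stock_calendar.csv`, `fertilizer_calendar.csv`,
#' `crop_calendar.csv`, `cultivation_calendar.csv`, `erosion_context.csv`),
#' and the rate tables. Re-writing an identical scenario reproduces
#' identical bytes.
#'
#' @param scenario a [generate_fixture_farm()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE, quote = FALSE)
  w(scenario$blocks, "blocks.csv")
  write_soil_profiles_csv(scenario$soils, file.path(dir, "soils.csv"))
  for (id in names(scenario$climates)) {
    write_climate_csv(scenario$climates[[id]],
                      file.path(dir, paste0("climate_", id, ".csv")))
  }
  gather <- function(el) {
    rows <- lapply(names(scenario$calendars), function(b) {
      x <- scenario$calendars[[b]][[el]]
      if (is.null(x) || nrow(x) == 0) return(NULL)
      cbind(data.frame(block_id = b), x)
    })
    do.call(rbind, rows)
  }
  for (spec in list(c("stock", "stock_calendar.csv"),
                    c("fertilizer", "fertilizer_calendar.csv"),
                    c("crops", "crop_calendar.csv"),
                    c("cultivation", "cultivation_calendar.csv"),
                    c("erosion", "erosion_context.csv"))) {
    d <- gather(spec[1])
    if (is.null(d)) d <- data.frame(block_id = character(0))
    w(d, spec[2])
  }
  w(scenario$tables$excreta_rates, "excreta_rates.csv")
  w(scenario$tables$fertilizer_products, "fertilizer_products.csv")
  invisible(dir)
}

#' Load and validate a scenario directory
#'
#' Reads the file layout written by [write_scenario()], validates column
#' schemas and cross-references (soil ids, climate ids, fertilizer product
#' ids, excreta rate keys), and reports all problems together in a single
#' error naming each file and key.
#'
#' @param dir scenario directory.
#' @return a `scenario` list as produced by [generate_fixture_farm()]
#'   (without the `config` element).
#' @export
load_scenario <- function(dir) {
  errs <- character(0)
  note <- function(msg) errs[[length(errs) + 1]] <<- msg
  rd <- function(f, cols = NULL) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      note(paste0("missing file: ", f))
      return(NULL)
    }
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (!is.null(cols) && nrow(d) > 0) {
      miss <- setdiff(cols, names(d))
      if (length(miss) > 0) {
        note(paste0(f, ": missing column(s) ", paste(miss, collapse = ", ")))
        return(NULL)
      }
    }
    d
  }
  blocks <- rd("blocks.csv", c("block_id", "area_ha", "land_use", "soil_id",
                               "slope", "climate_id", "irrigated",
                               "location_id"))
  soils <- tryCatch(read_soil_profiles_csv(file.path(dir, "soils.csv")),
                    error = function(e) {
                      note(paste0("soils.csv: ", conditionMessage(e)))
                      NULL
                    })
  stock <- rd("stock_calendar.csv")
  fert <- rd("fertilizer_calendar.csv")
  crops <- rd("crop_calendar.csv")
  cult <- rd("cultivation_calendar.csv")
  eros <- rd("erosion_context.csv")
  rates <- rd("excreta_rates.csv", c("stock_class", "age_class", "region",
                                     "urine_n_kg_head", "dung_n_kg_head"))
  products <- rd("fertilizer_products.csv", c("product_id", "n_fraction"))

  climates <- list()
  if (!is.null(blocks)) {
    for (id in unique(blocks$climate_id)) {
      cl <- tryCatch(read_climate_csv(file.path(dir, paste0("climate_", id, ".csv"))),
                     error = function(e) {
                       note(paste0("climate_", id, ".csv: ", conditionMessage(e)))
                       NULL
                     })
      if (!is.null(cl)) climates[[id]] <- cl
    }
    if (!is.null(soils)) {
      bad <- setdiff(blocks$soil_id, names(soils))
      if (length(bad) > 0) {
        note(paste0("blocks.csv: unknown soil id(s) ",
                    paste(bad, collapse = ", ")))
      }
    }
    if (!all(blocks$slope %in% .slope_levels)) {
      note("blocks.csv: invalid slope class(es)")
    }
    if (any(blocks$area_ha <= 0)) note("blocks.csv: non-positive areas")
  }
  if (!is.null(fert) && nrow(fert) > 0 && !is.null(products)) {
    bad <- setdiff(fert$product_id, products$product_id)
    if (length(bad) > 0) {
      note(paste0("fertilizer_calendar.csv: unknown product id(s) ",
                  paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(stock) && nrow(stock) > 0 && !is.null(rates)) {
    key <- function(d) paste(d$stock_class, d$age_class, d$region, sep = "|")
    bad <- setdiff(key(stock), key(rates))
    if (length(bad) > 0) {
      note(paste0("stock_calendar.csv: unresolvable stock key(s) ",
                  paste(bad, collapse = "; ")))
    }
  }
  if (length(errs) > 0) {
    stop("scenario validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  }
  tables <- list(excreta_rates = rates, fertilizer_products = products)
  calendars <- lapply(blocks$block_id, function(b) {
    pick <- function(d) {
      if (is.null(d) || nrow(d) == 0 || !"block_id" %in% names(d)) return(NULL)
      x <- d[d$block_id == b, setdiff(names(d), "block_id"), drop = FALSE]
      if (nrow(x) == 0) NULL else x
    }
    i <- which(blocks$block_id == b)
    list(area_ha = blocks$area_ha[i], land_use = blocks$land_use[i],
         tables = tables, stock = pick(stock), fertilizer = pick(fert),
         crops = pick(crops), cultivation = pick(cult), erosion = pick(eros))
  })
  names(calendars) <- blocks$block_id
  structure(list(blocks = blocks, soils = soils, climates = climates,
                 calendars = calendars, tables = tables),
            class = "scenario")
}

#' Serialize blocks and their annual scores as GeoJSON
#'
#' Emits a `FeatureCollection` of block polygons with the risk scores as
#' feature properties. When the blocks table lacks geometry, each block is
#' drawn as a synthetic unit square laid out on a grid (row-major by block
#' order) purely for visualisation.
#'
#' @param blocks blocks data.frame.
#' @param scores optional per-block annual scores (data.frame with
#'   `block_id`, `leach_index`, `runoff_index`, `total`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks_geojson <- function(blocks, scores = NULL, path) {
  n <- nrow(blocks)
  ncol_grid <- ceiling(sqrt(n))
  features <- lapply(seq_len(n), function(i) {
    x0 <- (i - 1) %% ncol_grid
    y0 <- (i - 1) %/% ncol_grid
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    props <- as.list(blocks[i, setdiff(names(blocks), c("lon", "lat"))])
    if (!is.null(scores)) {
      j <- which(scores$block_id == blocks$block_id[i])
      if (length(j) == 1) {
        props$leach_index <- scores$leach_index[j]
        props$runoff_index <- scores$runoff_index[j]
        props$total <- scores$total[j]
      }
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the risk report files
#'
#' Writes `risk_scores.csv` (block-month rows), a `summary.txt` with annual
#' totals and the pathway-share line, and optionally a modifier audit trail
#' CSV, a rank-validation plot (PNG) and a block GeoJSON. Re-running on
#' identical inputs reproduces identical CSV bytes.
#'
#' @param scores a [risk_scores()] data.frame.
#' @param outdir output directory (created if absent).
#' @param blocks optional blocks table (enables the GeoJSON and the farm
#'   aggregate).
#' @param audit optional audit-trail data.frame from [apply_modifiers()].
#' @param validation optional [rank_regression()] object.
#' @return character vector of the files written, invisibly.
#' @export
write_risk_report <- function(scores, outdir, blocks = NULL, audit = NULL,
                              validation = NULL) {
  if (nrow(scores) == 0) stop("scores must be non-empty")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(outdir, "risk_scores.csv")
  utils::write.csv(as.data.frame(scores), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  annual <- aggregate_risk(scores, "annual")
  f <- file.path(outdir, "annual_scores.csv")
  utils::write.csv(annual, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  shares <- aggregate_risk(scores, "pathway_shares")
  f <- file.path(outdir, "summary.txt")
  lines <- c(
    sprintf("blocks scored: %d", length(unique(scores$block_id))),
    sprintf("total risk: %.3f (leaching %.3f, runoff %.3f)",
            sum(scores$total), sum(scores$leach_index),
            sum(scores$runoff_index)),
    sprintf("pathway shares: leaching %.1f%%, runoff %.1f%%",
            100 * shares$leach_share, 100 * shares$runoff_share)
  )
  writeLines(lines, f)
  files <- c(files, f)

  if (!is.null(audit)) {
    f <- file.path(outdir, "mitigation_audit.csv")
    utils::write.csv(audit, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(validation) && !validation$degenerate) {
    f <- file.path(outdir, "rank_validation.png")
    grDevices::png(f, width = 800, height = 600)
    plot(validation)
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(blocks)) {
    f <- file.path(outdir, "blocks.geojson")
    write_blocks_geojson(blocks, annual, f)
    files <- c(files, f)
  }
  invisible(files)
}
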