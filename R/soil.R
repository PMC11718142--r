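#' Construct a layered soil profile
#'
#' A soil profile is an ordered stack of layers, each with a thickness and
#' volumetric water contents at saturation, field capacity and wilting point,
#' plus a first-order saturated drainage coefficient. The profile carries the
#' surface runoff partition parameter, the soil total N mass fraction (used
#' for erosion-borne N), and bulk density.
#'
#' @param layers data.frame with one row per layer, top first, and columns
#'   `thickness_mm`, `theta_sat`, `theta_fc`, `theta_wp` (volumetric
#'   fractions) and `k_drain` (fraction of water above field capacity that
#'   drains per day, in \[0, 1\]).
#' @param runoff_curve dimensionless runoff partition parameter in (0, 1];
#'   the fraction of rain shed as runoff on a fully wet soil (before the
#'   slope multiplier).
#' @param total_n_fraction soil total N as kg N per kg soil (e.g. 0.003 for
#'   0.3 \% N).
#' @param bulk_density t m^-3.
#' @param id optional identifier used when profiles are assembled into
#'   transport tables.
#'
#' @details The profile must reach at least 1000 mm depth: tracer leaching is
#'   accounted past that depth, so the accounting plane has to lie within the
#'   profile.
#'
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(layers, runoff_curve, total_n_fraction = 0.003,
                         bulk_density = 1.3, id = NULL) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1)
  req <- c("thickness_mm", "theta_sat", "theta_fc", "theta_wp", "k_drain")
  missing_cols <- setdiff(req, names(layers))
  if (length(missing_cols) > 0) {
    stop("soil layers are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  layers <- layers[, req]
  if (any(layers$thickness_mm <= 0)) {
    stop("layer thicknesses must be > 0")
  }
  bad <- !(layers$theta_wp < layers$theta_fc & layers$theta_fc < layers$theta_sat)
  if (any(bad)) {
    stop("every layer needs wilting < field capacity < saturation; violated in layer(s) ",
         paste(which(bad), collapse = ", "))
  }
  if (any(layers$k_drain < 0 | layers$k_drain > 1)) {
    stop("k_drain must lie in [0, 1]")
  }
  if (!is.numeric(runoff_curve) || length(runoff_curve) != 1 ||
      runoff_curve <= 0 || runoff_curve > 1) {
    stop("runoff_curve must be a single value in (0, 1]")
  }
  if (total_n_fraction < 0) stop("total_n_fraction must be >= 0")
  depth <- sum(layers$thickness_mm)
  if (depth < 1000) {
    stop("profile depth (", depth, " mm) is shallower than the 1000 mm ",
         "leaching accounting depth; add layers")
  }
  structure(
    list(
      layers = layers,
      profile_depth_mm = depth,
      runoff_curve = runoff_curve,
      total_n_fraction = total_n_fraction,
      bulk_density = bulk_density,
      id = id
    ),
    class = "soil_profile"
  )
}

#' @export
print.soil_profile <- function(x, ...) {
  cat("Soil profile", if (!is.null(x$id)) paste0("'", x$id, "'"), "\n")
  cat("  depth:", x$profile_depth_mm, "mm in", nrow(x$layers), "layer(s)\n")
  cat("  plant-available water:",
      round(sum((x$layers$theta_fc - x$layers$theta_wp) * x$layers$thickness_mm), 1),
      "mm\n")
  cat("  runoff curve parameter:", x$runoff_curve,
      " total N:", x$total_n_fraction * 100, "%\n")
  invisible(x)
}

# per-layer storages in mm at the three reference points
.layer_mm <- function(soil) {
  l <- soil$layers
  list(
    sat = l$theta_sat * l$thickness_mm,
    fc  = l$theta_fc * l$thickness_mm,
    wp  = l$theta_wp * l$thickness_mm,
    k   = l$k_drain,
    bottom_depth = cumsum(l$thickness_mm)
  )
}
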