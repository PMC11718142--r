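#' Construct a daily climate series
#'
#' @param date a `Date` vector, contiguous daily steps.
#' @param rain_mm daily rainfall, mm.
#' @param pet_mm daily potential evapotranspiration, mm.
#'
#' @return A data.frame of class `climate_series` with columns `date`,
#'   `rain_mm`, `pet_mm`.
#' @export
climate_series <- function(date, rain_mm, pet_mm) {
  date <- as.Date(date)
  n <- length(date)
  if (length(rain_mm) != n || length(pet_mm) != n) {
    stop("date, rain_mm and pet_mm must have the same length")
  }
  if (n > 1 && any(diff(as.integer(date)) != 1L)) {
    stop("climate dates must be contiguous daily steps")
  }
  if (any(!is.finite(rain_mm)) || any(rain_mm < 0)) {
    stop("rain_mm must be finite and >= 0")
  }
  if (any(!is.finite(pet_mm)) || any(pet_mm < 0)) {
    stop("pet_mm must be finite and >= 0")
  }
  structure(
    data.frame(date = date, rain_mm = rain_mm, pet_mm = pet_mm),
    class = c("climate_series", "data.frame")
  )
}

#' Classify a slope in degrees into the four slope classes
#'
#' Classes are flat (0--7 degrees), rolling (7.1--15), easy (15.1--25) and
#' steep (> 25). The classification is total: 7.0 is flat, 7.1 is rolling.
#'
#' @param degrees numeric vector of slope angles in degrees.
#' @return character vector of class labels.
#' @export
#' @examples
#' slope_class(c(0, 7, 7.1, 15, 15.1, 25, 25.1))
slope_class <- function(degrees) {
  if (any(!is.finite(degrees)) || any(degrees < 0)) {
    stop("slope degrees must be finite and >= 0")
  }
  cut(degrees,
      breaks = c(-Inf, 7, 15, 25, Inf),
      labels = c("flat", "rolling", "easy", "steep"),
      right = TRUE) |> as.character()
}

#' @keywords internal
.slope_levels <- c("flat", "rolling", "easy", "steep")

.check_slope <- function(slope) {
  if (!slope %in% .slope_levels) {
    stop("unknown slope class '", slope, "'; expected one of ",
         paste(.slope_levels, collapse = ", "))
  }
  slope
}
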