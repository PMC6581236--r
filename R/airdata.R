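# Wind-triangle decomposition and humid air density.
#
# Conventions: wind direction is meteorological (the bearing the wind blows
# FROM, degrees clockwise from north); headings are the bearing of travel.
# Gas constants: R_d = 287.05, R_v = 461.495 J kg^-1 K^-1.

R_DRY <- 287.05
R_VAP <- 461.495

#' Saturation vapour pressure (Arden Buck equation)
#'
#' Saturation vapour pressure of water over liquid, from the Arden Buck
#' fit \eqn{P_{sat} = 0.61121 \exp((18.678 - T_C/234.5)(T_C/(257.14 + T_C)))}
#' with \eqn{T_C} in degrees Celsius. The leading constant is kPa-valued
#' (611.21 Pa at 0 degrees C); the result is returned in pascals.
#'
#' @param temp_c air temperature, degrees Celsius; valid range (-40, 50).
#' @return saturation vapour pressure in Pa.
#' @examples
#' buck_psat(0)    # 611.21 Pa
#' buck_psat(20)   # about 2338 Pa
#' @export
buck_psat <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  if (any(!is.finite(temp_c)) || any(temp_c <= -40 | temp_c >= 50)) {
    stop("temp_c must be finite and within (-40, 50) degrees C")
  }
  1000 * 0.61121 * exp((18.678 - temp_c / 234.5) * (temp_c / (257.14 + temp_c)))
}

#' Create a weather record
#'
#' Bundles one station observation: wind speed and meteorological wind
#' direction (blowing from), air temperature, relative humidity and
#' barometric pressure.
#'
#' @param wind_speed_ms wind speed, m/s (>= 0).
#' @param wind_dir_deg direction the wind blows from, degrees [0, 360).
#' @param temp_c air temperature, degrees Celsius.
#' @param humidity_pct relative humidity, percent in [0, 100].
#' @param pressure_hpa barometric pressure, hPa (> 0).
#' @return a list of class `weather_record`.
#' @export
weather_record <- function(wind_speed_ms = 0, wind_dir_deg = 0, temp_c = 15,
                           humidity_pct = 0, pressure_hpa = 1013.25) {
  stopifnot(wind_speed_ms >= 0, humidity_pct >= 0, humidity_pct <= 100,
            pressure_hpa > 0)
  structure(list(wind_speed_ms = wind_speed_ms,
                 wind_dir_deg = wind_dir_deg %% 360,
                 temp_c = temp_c,
                 humidity_pct = humidity_pct,
                 pressure_hpa = pressure_hpa),
            class = "weather_record")
}

#' Humid air density from the ideal gas law
#'
#' Density of moist air, \eqn{\rho = P_d/(R_d T) + P_v/(R_v T)}, with the
#' vapour pressure \eqn{P_v = \phi P_{sat}} from relative humidity
#' (entered as percent, used as a fraction) and [buck_psat()], and the
#' dry-air partial pressure \eqn{P_d = P - P_v}.
#'
#' @param weather a [weather_record()], or anything with fields
#'   `temp_c`, `humidity_pct`, `pressure_hpa`.
#' @return air density in kg/m^3.
#' @examples
#' humid_air_density(weather_record(temp_c = 15, humidity_pct = 0))  # 1.225
#' @export
humid_air_density <- function(weather) {
  t_k <- weather$temp_c + 273.15
  p_pa <- weather$pressure_hpa * 100
  p_v <- (weather$humidity_pct / 100) * buck_psat(weather$temp_c)
  if (p_v > p_pa) stop("vapour pressure exceeds total pressure")
  p_d <- p_pa - p_v
  p_d / (R_DRY * t_k) + p_v / (R_VAP * t_k)
}

#' Wind support, crosswind and airspeed from the wind triangle
#'
#' Decomposes ground velocity into air and wind components. The wind
#' vector points in the direction the air moves toward (meteorological
#' direction + 180 degrees). Air velocity = ground velocity - wind
#' vector. Wind support is the signed projection of the wind vector on
#' the direction of travel (positive = tailwind), crosswind the
#' magnitude of the perpendicular component, airspeed the magnitude of
#' the air velocity.
#'
#' @param ground_speed_ms ground speed, m/s (>= 0); vectorised.
#' @param heading_deg track direction of travel, degrees clockwise from
#'   north; vectorised.
#' @param weather a [weather_record()] (or list with `wind_speed_ms`,
#'   `wind_dir_deg`).
#' @return data.frame with columns `wind_support_ms`, `crosswind_ms`,
#'   `airspeed_ms`.
#' @examples
#' w <- weather_record(wind_speed_ms = 5, wind_dir_deg = 270)  # westerly
#' wind_triangle(20, 90, w)  # pure tailwind when flying east
#' @export
wind_triangle <- function(ground_speed_ms, heading_deg, weather) {
  if (any(ground_speed_ms < 0) || weather$wind_speed_ms < 0) {
    stop("speeds must be non-negative")
  }
  h <- heading_deg * pi / 180
  # ground velocity in (east, north) components
  ge <- ground_speed_ms * sin(h)
  gn <- ground_speed_ms * cos(h)
  wdir_to <- (weather$wind_dir_deg + 180) * pi / 180
  we <- weather$wind_speed_ms * sin(wdir_to)
  wn <- weather$wind_speed_ms * cos(wdir_to)
  ae <- ge - we
  an <- gn - wn
  support <- we * sin(h) + wn * cos(h)
  cross <- abs(we * cos(h) - wn * sin(h))
  data.frame(wind_support_ms = support,
             crosswind_ms = cross,
             airspeed_ms = sqrt(ae^2 + an^2))
}
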