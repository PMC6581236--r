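# Classical aerodynamic power partition and the ratio arithmetic linking
# airspeed, wingbeat frequency, work per beat, and cost of transport.
#
# The partition follows the fixed-wing convention for bird flight:
#   parasite power  P_par = rho U^3 S_b C_Db / 2     (body drag, ~U^3)
#   induced power   P_ind = k (m g)^2 / (2 rho U A)  (lift, ~U^-1)
#   profile power   P_pro = constant                 (wing drag)
# with A = pi b^2 / 4 the wing disk area.

G_ACCEL <- 9.80665

#' Parameters of the classical power curve
#'
#' @param mass_kg body mass, kg.
#' @param rho air density, kg/m^3.
#' @param span_m wing span b, m (default 0.67).
#' @param aspect_ratio wing aspect ratio (default 6.9).
#' @param Sb body frontal area, m^2; default the allometric
#'   `0.00813 * mass_kg^0.666`.
#' @param CDb body drag coefficient (default 0.1).
#' @param k_ind induced power factor (default 1.2).
#' @param profile_const profile power in watts, held constant across
#'   speeds. Default `NULL` computes `(8.4 / aspect_ratio)` times the
#'   absolute minimum of the parasite+induced curve, the usual
#'   profile-power-ratio convention.
#' @return list of class `power_params`.
#' @export
power_params <- function(mass_kg, rho = 1.225, span_m = 0.67,
                         aspect_ratio = 6.9, Sb = NULL, CDb = 0.1,
                         k_ind = 1.2, profile_const = NULL) {
  if (is.null(Sb)) Sb <- 0.00813 * mass_kg^0.666
  stopifnot(mass_kg > 0, rho > 0, span_m > 0, aspect_ratio > 0,
            Sb > 0, CDb > 0, k_ind > 0)
  p <- list(mass_kg = mass_kg, rho = rho, span_m = span_m,
            aspect_ratio = aspect_ratio, Sb = Sb, CDb = CDb,
            k_ind = k_ind, profile_const = profile_const)
  if (is.null(profile_const)) {
    # minimum of alpha U^3 + beta / U at Vmp = (beta / (3 alpha))^(1/4)
    a <- rho * Sb * CDb / 2
    b <- k_ind * (mass_kg * G_ACCEL)^2 / (2 * rho * pi * span_m^2 / 4)
    vmp <- (b / (3 * a))^0.25
    p$profile_const <- (8.4 / aspect_ratio) * (a * vmp^3 + b / vmp)
  }
  structure(p, class = "power_params")
}

#' Classical three-component aerodynamic power
#'
#' @param U airspeed, m/s (> 4, a stall proxy); vectorised.
#' @param params a [power_params()].
#' @return data.frame with columns `U`, `parasite_w`, `induced_w`,
#'   `profile_w`, `total_w`.
#' @export
classical_power <- function(U, params) {
  if (any(U <= 4)) stop("airspeed must exceed 4 m/s (stall proxy)")
  disk <- pi * params$span_m^2 / 4
  p_par <- params$rho * U^3 * params$Sb * params$CDb / 2
  p_ind <- params$k_ind * (params$mass_kg * G_ACCEL)^2 /
    (2 * params$rho * U * disk)
  data.frame(U = U, parasite_w = p_par, induced_w = p_ind,
             profile_w = params$profile_const,
             total_w = p_par + p_ind + params$profile_const)
}

#' Minimum-power speed of the classical curve
#'
#' Analytic stationary point of parasite + induced power (profile power
#' is constant and does not shift it): \eqn{V_{mp} = (\beta/3\alpha)^{1/4}}.
#'
#' @param params a [power_params()].
#' @return speed in m/s.
#' @export
min_power_speed <- function(params) {
  a <- params$rho * params$Sb * params$CDb / 2
  b <- params$k_ind * (params$mass_kg * G_ACCEL)^2 /
    (2 * params$rho * pi * params$span_m^2 / 4)
  (b / (3 * a))^0.25
}

#' Percent change in parasite power from an airspeed ratio
#'
#' Parasite power scales as U^3, so a speed ratio r implies a
#' (r^3 - 1) * 100 percent change.
#'
#' @param speed_ratio paired/solo airspeed ratio (> 0).
#' @return percent change.
#' @examples
#' parasite_power_change(1.033)  # 10.2
#' @export
parasite_power_change <- function(speed_ratio) {
  stopifnot(speed_ratio > 0)
  (speed_ratio^3 - 1) * 100
}

#' Percent change in mechanical work per wingbeat
#'
#' Work per beat is power over frequency, so ratios combine as
#' (power_ratio / freq_ratio - 1) * 100.
#'
#' @param power_ratio total-power ratio (> 0).
#' @param freq_ratio wingbeat-frequency ratio (> 0).
#' @return percent change.
#' @examples
#' work_per_beat_change(1.022, 1.182)  # -13.5
#' @export
work_per_beat_change <- function(power_ratio, freq_ratio) {
  stopifnot(power_ratio > 0, freq_ratio > 0)
  (power_ratio / freq_ratio - 1) * 100
}

#' Percent change in cost of transport
#'
#' Cost of transport is power over speed (energy per unit distance), so
#' ratios combine as (power_ratio / speed_ratio - 1) * 100.
#'
#' @param power_ratio total-power ratio (> 0).
#' @param speed_ratio airspeed ratio (> 0).
#' @return percent change.
#' @examples
#' cost_of_transport_change(1.029, 1.033)  # -0.4
#' @export
cost_of_transport_change <- function(power_ratio, speed_ratio) {
  stopifnot(power_ratio > 0, speed_ratio > 0)
  (power_ratio / speed_ratio - 1) * 100
}

#' Total wingbeats implied by distance, route accuracy, airspeed, frequency
#'
#' Path length = straight-line distance / route accuracy; flight time =
#' path length / airspeed; wingbeats = time * frequency. Used for the
#' solo-versus-paired wingbeat budget.
#'
#' @param straight_dist_m beeline distance, m (> 0).
#' @param accuracy route accuracy in (0, 1].
#' @param airspeed_ms airspeed, m/s (> 0).
#' @param freq_hz wingbeat frequency, Hz (> 0).
#' @return total number of wingbeats (not rounded).
#' @examples
#' wingbeat_budget(6660, 1, 18, 5.48)  # about 2028 beats
#' @export
wingbeat_budget <- function(straight_dist_m, accuracy, airspeed_ms, freq_hz) {
  if (accuracy <= 0 || accuracy > 1) stop("accuracy must be in (0, 1]")
  stopifnot(straight_dist_m > 0, airspeed_ms > 0, freq_hz > 0)
  (straight_dist_m / accuracy) / airspeed_ms * freq_hz
}
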