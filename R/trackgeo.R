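# Great-circle trajectory geometry on a spherical Earth (R = 6371 km):
# distances, bearings, route accuracy, trimming, pair spacing/leadership.

EARTH_RADIUS_M <- 6371000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) || any(abs(lat) > 90)) {
    stop("invalid coordinates: latitudes must be finite and within [-90, 90]")
  }
  invisible(TRUE)
}

#' Great-circle (haversine) distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS-84
#'   treated as spherical, R = 6,371,000 m); vectorised.
#' @return distance in metres.
#' @examples
#' haversine_m(0, 0, 0, 1)  # one degree of longitude at the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  check_latlon(c(lat1, lat2), c(lon1, lon2))
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing (forward azimuth)
#'
#' @inheritParams haversine_m
#' @return bearing in degrees [0, 360), 0 = north, clockwise.
#' @export
forward_azimuth <- function(lat1, lon1, lat2, lon2) {
  check_latlon(c(lat1, lat2), c(lon1, lon2))
  if (any(lat1 == lat2 & lon1 == lon2)) {
    stop("forward azimuth undefined for coincident points")
  }
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  rad2deg(atan2(y, x)) %% 360
}

#' Destination point along a great circle
#'
#' Point reached from (`lat`, `lon`) after travelling `dist_m` metres on
#' initial bearing `bearing_deg`.
#'
#' @param lat,lon start coordinates, degrees.
#' @param bearing_deg initial bearing, degrees.
#' @param dist_m distance, metres.
#' @return list with `lat`, `lon` in degrees.
#' @export
destination_point <- function(lat, lon, bearing_deg, dist_m) {
  check_latlon(lat, lon)
  delta <- dist_m / EARTH_RADIUS_M
  theta <- deg2rad(bearing_deg)
  phi1 <- deg2rad(lat); lam1 <- deg2rad(lon)
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(sin(theta) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  list(lat = rad2deg(phi2), lon = ((rad2deg(lam2) + 540) %% 360) - 180)
}

#' Construct a GPS track
#'
#' @param t_s time since release, seconds, strictly increasing.
#' @param lat_deg,lon_deg coordinates, decimal degrees.
#' @param flight_id,bird_id optional identifiers carried as attributes.
#' @return data.frame of class `gps_track`.
#' @export
gps_track <- function(t_s, lat_deg, lon_deg, flight_id = NA, bird_id = NA) {
  if (any(diff(t_s) <= 0)) stop("t_s must be strictly increasing")
  check_latlon(lat_deg, lon_deg)
  structure(data.frame(t_s = t_s, lat_deg = lat_deg, lon_deg = lon_deg),
            flight_id = flight_id, bird_id = bird_id,
            class = c("gps_track", "data.frame"))
}

#' Per-step geometry of a track
#'
#' For each consecutive pair of fixes: step distance (haversine), forward
#' azimuth, and ground speed. One row per step (n - 1 rows).
#'
#' @param track a [gps_track()] (or data.frame with `t_s`, `lat_deg`,
#'   `lon_deg`).
#' @return data.frame with `t_s` (step start), `step_dist_m`,
#'   `heading_deg`, `ground_speed_ms`.
#' @export
track_steps <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("track needs at least 2 fixes")
  i <- seq_len(n - 1)
  d <- haversine_m(track$lat_deg[i], track$lon_deg[i],
                   track$lat_deg[i + 1], track$lon_deg[i + 1])
  dt <- diff(track$t_s)
  moved <- d > 0
  hd <- rep(NA_real_, n - 1)
  if (any(moved)) {
    hd[moved] <- forward_azimuth(track$lat_deg[i][moved],
                                 track$lon_deg[i][moved],
                                 track$lat_deg[i + 1][moved],
                                 track$lon_deg[i + 1][moved])
  }
  data.frame(t_s = track$t_s[i], step_dist_m = d, heading_deg = hd,
             ground_speed_ms = d / dt)
}

#' Route accuracy: distance-weighted mean cosine of the heading error
#'
#' For each step the angle theta between the step's forward azimuth and
#' the current bearing to the goal is taken as the smallest angular
#' difference (0 to 180 degrees); the statistic is
#' \eqn{\frac{1}{D}\sum_i d_i \cos\theta_i} with \eqn{D = \sum_i d_i}.
#' 1 means a beeline to the goal, -1 a straight line directly away.
#' Computable on any sub-track, so sections of a flight can be scored.
#'
#' @param track a [gps_track()].
#' @param goal list or vector with `lat`, `lon` of the destination,
#'   degrees.
#' @return route accuracy in [-1, 1].
#' @export
route_accuracy <- function(track, goal) {
  goal <- as.list(goal)
  steps <- track_steps(track)
  keep <- steps$step_dist_m > 0
  steps <- steps[keep, , drop = FALSE]
  if (nrow(steps) == 0 || sum(steps$step_dist_m) <= 0) {
    stop("zero-length track: route accuracy undefined")
  }
  i <- which(keep)
  goal_bearing <- forward_azimuth(track$lat_deg[i], track$lon_deg[i],
                                  goal$lat, goal$lon)
  theta <- abs(((steps$heading_deg - goal_bearing + 180) %% 360) - 180)
  sum(steps$step_dist_m * cos(deg2rad(theta))) / sum(steps$step_dist_m)
}

#' Trim fixes within a radius of given sites
#'
#' Removes fixes lying within `radius_m` of any site (typically the
#' release point and the loft, to drop take-off and landing). Order of
#' the remaining fixes is preserved.
#'
#' @param track a [gps_track()].
#' @param sites list of lists/vectors with `lat`, `lon`.
#' @param radius_m trim radius, metres (>= 0; 0 is the identity).
#' @return the trimmed track (same class); warns if empty.
#' @export
trim_radius <- function(track, sites, radius_m = 200) {
  if (radius_m < 0) stop("radius_m must be >= 0")
  drop <- rep(FALSE, nrow(track))
  for (s in sites) {
    s <- as.list(s)
    drop <- drop | haversine_m(track$lat_deg, track$lon_deg,
                               s$lat, s$lon) < radius_m
  }
  out <- track[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all fixes trimmed; returning empty track")
  out
}

#' Pair spacing, inclusion mask and leadership
#'
#' Matches fixes of two simultaneously flying birds by nearest timestamp
#' (within `tol_s`), computes the horizontal great-circle spacing per
#' match, and derives: an inclusion mask (spacing below `max_spacing_m`),
#' the front bird per match (positive projection of the B-to-A
#' displacement onto the mean pair heading), the majority front bird and
#' its share of fixes, and a consistent-leader flag (front share above
#' `leader_frac`). Matches where the non-majority bird is in front are
#' excluded from the mask, mirroring the exclusion of position-swapped
#' sections from paired summaries.
#'
#' @param track_a,track_b [gps_track()] objects with overlapping times.
#' @param tol_s timestamp matching tolerance, seconds (default 0.2).
#' @param max_spacing_m spacing cut-off, metres (default 50).
#' @param leader_frac front share defining a consistent leader
#'   (default 0.9).
#' @return list with `matches` (data.frame: `t_s`, `spacing_m`,
#'   `front` = "A"/"B", `within_range`, `included`), `front_bird`
#'   ("A"/"B"), `front_fraction`, `consistent_leader`,
#'   `median_spacing_m` (over within-range matches).
#' @export
pair_spacing <- function(track_a, track_b, tol_s = 0.2,
                         max_spacing_m = 50, leader_frac = 0.9) {
  ib <- findInterval(track_a$t_s, track_b$t_s, all.inside = TRUE)
  cand <- cbind(ib, pmin(ib + 1, nrow(track_b)))
  dt <- abs(matrix(track_b$t_s[cand], ncol = 2) - track_a$t_s)
  j <- cand[cbind(seq_len(nrow(cand)), max.col(-dt))]
  ok <- abs(track_b$t_s[j] - track_a$t_s) <= tol_s
  if (!any(ok)) stop("no fixes matched within the timestamp tolerance")
  ia <- which(ok); jb <- j[ok]

  spacing <- haversine_m(track_a$lat_deg[ia], track_a$lon_deg[ia],
                         track_b$lat_deg[jb], track_b$lon_deg[jb])

  # headings of each bird at the matched fixes (step-based, last step
  # carried forward for the final fix)
  step_heading <- function(track) {
    h <- track_steps(track)$heading_deg
    c(h, h[length(h)])
  }
  ha <- deg2rad(step_heading(track_a)[ia])
  hb <- deg2rad(step_heading(track_b)[jb])
  # circular mean pair heading per match
  me <- (sin(ha) + sin(hb)) / 2
  mn <- (cos(ha) + cos(hb)) / 2
  # displacement B -> A in local east/north metres (equirectangular)
  latm <- deg2rad((track_a$lat_deg[ia] + track_b$lat_deg[jb]) / 2)
  de <- deg2rad(track_a$lon_deg[ia] - track_b$lon_deg[jb]) *
    cos(latm) * EARTH_RADIUS_M
  dn <- deg2rad(track_a$lat_deg[ia] - track_b$lat_deg[jb]) * EARTH_RADIUS_M
  proj <- de * me + dn * mn
  front <- ifelse(proj >= 0, "A", "B")

  within <- spacing < max_spacing_m
  fa <- mean(front == "A")
  front_bird <- if (fa >= 0.5) "A" else "B"
  front_fraction <- max(fa, 1 - fa)
  included <- within & front == front_bird

  list(matches = data.frame(t_s = track_a$t_s[ia], spacing_m = spacing,
                            front = front, within_range = within,
                            included = included),
       front_bird = front_bird,
       front_fraction = front_fraction,
       consistent_leader = front_fraction > leader_frac,
       median_spacing_m = if (any(within)) {
         stats::median(spacing[within])
       } else NA_real_)
}
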