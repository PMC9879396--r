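# Site geometry: turbines, rotor-swept zones, camera coverage, and the
# kinematic primitives (signed distance, closing speed, time to collision)
# that the curtailment prescription consumes.
#
# All coordinates are local planar metres (east/north/up); site extents are
# far below the scale where geodesy matters.

#' Turbine specification
#'
#' Describes one turbine in a local planar frame. Defaults match a GE SLE
#' 1.5 MW machine: 65 m hub height, 77 m rotor diameter, 103.5 m maximum
#' blade-tip height.
#'
#' @param turbine_id Character scalar identifier.
#' @param x,y Base position, metres (local projected frame).
#' @param hub_height Hub height above base, metres.
#' @param rotor_diameter Rotor diameter, metres.
#' @param tip_height Maximum blade-tip height, metres. Must equal
#'   `hub_height + rotor_diameter / 2` to within 1e-6 m.
#' @return An object of class `turbine_spec`.
#' @examples
#' t1 <- turbine_spec("T01", 0, 0)
#' rsz_radius(t1)  # 38.5
#' @export
turbine_spec <- function(turbine_id, x, y, hub_height = 65,
                         rotor_diameter = 77,
                         tip_height = hub_height + rotor_diameter / 2) {
  stopifnot(is.character(turbine_id), length(turbine_id) == 1L)
  if (!is.finite(x) || !is.finite(y)) {
    stop("turbine base position must be finite")
  }
  if (hub_height <= 0) stop("hub_height must be positive")
  if (rotor_diameter <= 0) stop("rotor_diameter must be positive")
  if (abs(tip_height - (hub_height + rotor_diameter / 2)) > 1e-6) {
    stop("tip_height must equal hub_height + rotor_diameter/2")
  }
  if (rotor_diameter / 2 >= hub_height) {
    stop("rotor must not reach the ground (rotor_diameter/2 < hub_height)")
  }
  structure(
    list(turbine_id = turbine_id, x = as.numeric(x), y = as.numeric(y),
         hub_height = as.numeric(hub_height),
         rotor_diameter = as.numeric(rotor_diameter),
         tip_height = as.numeric(tip_height)),
    class = "turbine_spec"
  )
}

#' @export
print.turbine_spec <- function(x, ...) {
  cat(sprintf("<turbine %s at (%.1f, %.1f): hub %.1f m, rotor %.1f m>\n",
              x$turbine_id, x$x, x$y, x$hub_height, x$rotor_diameter))
  invisible(x)
}

#' Rotor-swept zone centre and radius
#'
#' The rotor-swept zone (RSZ) is modelled as a sphere of rotor radius centred
#' at hub height. Turbine yaw is unobserved, so a yaw-agnostic volume is
#' used; the true swept disc is a subset of this sphere, which makes
#' distance binning conservative.
#'
#' @param turbine A [turbine_spec()].
#' @return `rsz_center()`: numeric length-3 (x, y, hub height).
#'   `rsz_radius()`: numeric scalar, metres.
#' @export
rsz_center <- function(turbine) {
  c(turbine$x, turbine$y, turbine$hub_height)
}

#' @rdname rsz_center
#' @export
rsz_radius <- function(turbine) {
  turbine$rotor_diameter / 2
}

#' Camera tower
#'
#' @param tower_id Character scalar identifier.
#' @param x,y Tower position, metres.
#' @param detection_range Detection range, metres (default 1000: the system
#'   tracks avian targets up to 1 km from a camera).
#' @return An object of class `camera_tower`.
#' @export
camera_tower <- function(tower_id, x, y, detection_range = 1000) {
  stopifnot(is.character(tower_id), length(tower_id) == 1L)
  if (!is.finite(x) || !is.finite(y)) stop("camera position must be finite")
  if (detection_range <= 0) stop("detection_range must be positive")
  structure(
    list(tower_id = tower_id, x = as.numeric(x), y = as.numeric(y),
         detection_range = as.numeric(detection_range)),
    class = "camera_tower"
  )
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns (x, y, z)")
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 coordinates")
    matrix(p, nrow = 1L)
  }
}

#' Signed distance from a point to a rotor-swept zone
#'
#' Returns the Euclidean distance from `p` to the RSZ centre minus the RSZ
#' radius. Values at or below zero mean the point is inside the zone.
#'
#' @param p Numeric length-3 point, or an n x 3 matrix of points (metres).
#' @param turbine A [turbine_spec()].
#' @return Numeric vector of signed distances, metres.
#' @examples
#' tb <- turbine_spec("T01", 0, 0)
#' distance_to_rsz(c(0, 0, 65), tb)      # -38.5: sphere centre
#' distance_to_rsz(c(138.5, 0, 65), tb)  # 100
#' @export
distance_to_rsz <- function(p, turbine) {
  p <- as_point_matrix(p)
  if (!all(is.finite(p))) stop("non-finite coordinates")
  ctr <- rsz_center(turbine)
  d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2)
  d - rsz_radius(turbine)
}

#' Time to collision with a rotor-swept zone
#'
#' Projects the current closing speed -- the component of velocity along the
#' unit vector from the target toward the RSZ centre -- onto the signed
#' distance. A target already inside the zone has time zero; a target whose
#' closing speed is zero or negative (receding or tangential) never arrives
#' and gets `Inf`.
#'
#' @param p Numeric length-3 point or n x 3 matrix, metres.
#' @param v Numeric length-3 velocity or n x 3 matrix, m/s. Rows with any
#'   `NA` velocity (e.g. a single-record track) yield `Inf`.
#' @param turbine A [turbine_spec()].
#' @return Numeric vector of seconds; `Inf` means "never".
#' @examples
#' tb <- turbine_spec("T01", 0, 0)
#' time_to_collision(c(238.5, 0, 65), c(-10, 0, 0), tb)  # 20 s
#' @export
time_to_collision <- function(p, v, turbine) {
  p <- as_point_matrix(p)
  v <- as_point_matrix(v)
  if (nrow(v) == 1L && nrow(p) > 1L) v <- v[rep(1L, nrow(p)), , drop = FALSE]
  stopifnot(nrow(p) == nrow(v))
  if (!all(is.finite(p))) stop("non-finite coordinates")
  ctr <- rsz_center(turbine)
  dx <- ctr[1] - p[, 1]; dy <- ctr[2] - p[, 2]; dz <- ctr[3] - p[, 3]
  dist_c <- sqrt(dx^2 + dy^2 + dz^2)
  signed <- dist_c - rsz_radius(turbine)
  # closing speed: projection of v on the unit vector toward the centre;
  # a point exactly at the centre (dist_c == 0) counts as inside
  s <- ifelse(dist_c > 0, (v[, 1] * dx + v[, 2] * dy + v[, 3] * dz) / dist_c, 0)
  ttc <- rep(Inf, nrow(p))
  ttc[signed <= 0] <- 0
  open_ <- signed > 0 & !is.na(s) & s > 0
  ttc[open_] <- signed[open_] / s[open_]
  ttc
}

#' Cylinder membership test
#'
#' True when the point lies within `radius` of the turbine base in the
#' horizontal plane and between ground level and `height_cap` vertically.
#' Both boundaries are inclusive.
#'
#' @param p Numeric length-3 point or n x 3 matrix, metres; the z coordinate
#'   is altitude above the turbine base plane.
#' @param turbine A [turbine_spec()].
#' @param radius Cylinder radius, metres.
#' @param height_cap Cylinder height, metres.
#' @return Logical vector.
#' @export
in_cylinder <- function(p, turbine, radius, height_cap) {
  stopifnot(radius > 0, height_cap > 0)
  p <- as_point_matrix(p)
  h <- sqrt((p[, 1] - turbine$x)^2 + (p[, 2] - turbine$y)^2)
  # inclusive boundaries, robust to float round-off at exactly r / cap
  tol <- 1e-9
  h <= radius + tol & p[, 3] >= -tol & p[, 3] <= height_cap + tol
}

#' Classify turbine coverage by a camera network
#'
#' A turbine is *fully* covered when the whole disc of `buffer` metres around
#' its base lies inside the union of the cameras' detection discs;
#' *partially* covered when it is not full but the base itself is within
#' detection range of at least one camera; *none* otherwise.
#'
#' Union containment is decided by sampling the buffer-disc boundary at
#' `n_boundary` points (default 3600, i.e. 0.1 degree steps) plus the base
#' point; exact circle-union algebra is not warranted at this precision.
#'
#' @param turbine A [turbine_spec()].
#' @param cameras A non-empty list of [camera_tower()] objects.
#' @param buffer Buffer radius around the turbine base, metres (default 600).
#' @param n_boundary Number of boundary sample points.
#' @return One of `"full"`, `"partial"`, `"none"`.
#' @export
classify_coverage <- function(turbine, cameras, buffer = 600,
                              n_boundary = 3600) {
  if (length(cameras) == 0L) stop("at least one camera is required")
  cx <- vapply(cameras, `[[`, numeric(1), "x")
  cy <- vapply(cameras, `[[`, numeric(1), "y")
  cr <- vapply(cameras, `[[`, numeric(1), "detection_range")
  covered <- function(px, py) {
    # each sample point must fall inside at least one detection disc
    ok <- rep(FALSE, length(px))
    for (i in seq_along(cx)) {
      ok <- ok | (px - cx[i])^2 + (py - cy[i])^2 <= cr[i]^2 + 1e-9
    }
    all(ok)
  }
  base_ok <- any((turbine$x - cx)^2 + (turbine$y - cy)^2 <= cr^2 + 1e-9)
  th <- seq(0, 2 * pi, length.out = n_boundary + 1L)[-(n_boundary + 1L)]
  full <- base_ok && covered(turbine$x + buffer * cos(th),
                             turbine$y + buffer * sin(th))
  if (full) "full" else if (base_ok) "partial" else "none"
}

#' Read a turbine layout table
#'
#' Expects a UTF-8 CSV with header
#' `turbine_id,x_m,y_m,hub_height_m,rotor_diameter_m`.
#'
#' @param path File path.
#' @return A list of [turbine_spec()] objects, named by turbine id.
#' @export
read_turbines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("turbine_id", "x_m", "y_m", "hub_height_m", "rotor_diameter_m")
  if (!all(need %in% names(df))) {
    stop("turbines file must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    turbine_spec(as.character(df$turbine_id[i]), df$x_m[i], df$y_m[i],
                 df$hub_height_m[i], df$rotor_diameter_m[i])
  })
  names(out) <- as.character(df$turbine_id)
  out
}

#' Read a camera layout table
#'
#' Expects a UTF-8 CSV with header `tower_id,x_m,y_m,range_m`.
#'
#' @param path File path.
#' @return A list of [camera_tower()] objects, named by tower id.
#' @export
read_cameras <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tower_id", "x_m", "y_m", "range_m")
  if (!all(need %in% names(df))) {
    stop("cameras file must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    camera_tower(as.character(df$tower_id[i]), df$x_m[i], df$y_m[i],
                 df$range_m[i])
  })
  names(out) <- as.character(df$tower_id)
  out
}

#' Write turbine / camera layout tables
#'
#' @param turbines List of [turbine_spec()].
#' @param cameras List of [camera_tower()].
#' @param dir Output directory.
#' @return Invisibly, the two file paths written.
#' @export
write_layout <- function(turbines, cameras, dir) {
  tdf <- data.frame(
    turbine_id = vapply(turbines, `[[`, character(1), "turbine_id"),
    x_m = vapply(turbines, `[[`, numeric(1), "x"),
    y_m = vapply(turbines, `[[`, numeric(1), "y"),
    hub_height_m = vapply(turbines, `[[`, numeric(1), "hub_height"),
    rotor_diameter_m = vapply(turbines, `[[`, numeric(1), "rotor_diameter")
  )
  cdf <- data.frame(
    tower_id = vapply(cameras, `[[`, character(1), "tower_id"),
    x_m = vapply(cameras, `[[`, numeric(1), "x"),
    y_m = vapply(cameras, `[[`, numeric(1), "y"),
    range_m = vapply(cameras, `[[`, numeric(1), "detection_range")
  )
  tp <- file.path(dir, "turbines.csv")
  cp <- file.path(dir, "cameras.csv")
  utils::write.csv(tdf, tp, row.names = FALSE, quote = FALSE)
  utils::write.csv(cdf, cp, row.names = FALSE, quote = FALSE)
  invisible(c(tp, cp))
}
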