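# Ellipsoid surface geometry used for scalp/skull placement.
#
# All shells of the head phantom are concentric axis-aligned ellipsoids
# centered on the world origin (RAS, mm). Points "on" a surface satisfy
# sum((p/ax)^2) == 1 for the semi-axis vector ax.

#' Project a point radially onto an ellipsoid surface
#'
#' Scales `p` along the ray from the ellipsoid center so that it lands on the
#' surface with semi-axes `ax`.
#'
#' @param p numeric length-3 point (mm, relative to ellipsoid center).
#' @param ax numeric length-3 semi-axes (mm).
#' @return a length-3 point on the surface.
#' @keywords internal
ell_project <- function(p, ax) {
  s <- sqrt(sum((p / ax)^2))
  if (s == 0) stop("cannot project the ellipsoid center onto the surface")
  p / s
}

#' Outward unit normal of an ellipsoid at a surface point
#' @inheritParams ell_project
#' @keywords internal
ell_normal <- function(p, ax) {
  n <- p / ax^2
  n / sqrt(sum(n^2))
}

#' Distance from an interior point to an ellipsoid surface along a ray
#'
#' Solves |(p + t d) / ax|^2 = 1 for the positive root t.
#'
#' @param p ray origin (mm), `d` unit direction.
#' @param d ray direction (need not be normalized).
#' @param ax semi-axes (mm).
#' @return positive ray parameter t, or `NA` if the ray misses the surface.
#' @keywords internal
ell_ray <- function(p, d, ax) {
  a <- sum((d / ax)^2)
  b <- 2 * sum(p * d / ax^2)
  cc <- sum((p / ax)^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  t1 <- (-b + sqrt(disc)) / (2 * a)
  if (t1 < 0) NA_real_ else t1
}

# Tangent-plane component of a vector at surface point p (unit length).
tangentize <- function(v, p, ax) {
  n <- ell_normal(p, ax)
  t <- v - sum(v * n) * n
  len <- sqrt(sum(t^2))
  if (len < 1e-9) return(NULL)
  t / len
}

#' Walk a geodesic-like path along an ellipsoid surface
#'
#' Steps along the surface from `p` in tangent direction `dir` for arc length
#' `dist`, re-projecting onto the surface after each small step and parallel-
#' transporting the direction (re-tangentizing after each step). For the head
#' curvatures used here the path length error is well below a millimetre.
#'
#' @param p start point on the surface.
#' @param dir initial direction (projected to the tangent plane).
#' @param dist arc length to travel (mm); may be negative (reversed direction).
#' @param ax ellipsoid semi-axes.
#' @param step integration step (mm).
#' @return list with `point` (end point) and `dir` (transported unit tangent).
#' @keywords internal
surface_walk <- function(p, dir, dist, ax, step = 0.5) {
  if (dist < 0) { dir <- -dir; dist <- -dist }
  p <- ell_project(p, ax)
  d <- tangentize(dir, p, ax)
  if (is.null(d)) stop("walk direction is normal to the surface")
  remaining <- dist
  while (remaining > 1e-9) {
    s <- min(step, remaining)
    p_new <- ell_project(p + s * d, ax)
    d_new <- tangentize(d, p_new, ax)
    if (is.null(d_new)) d_new <- d  # at a degenerate point keep heading
    p <- p_new
    d <- d_new
    remaining <- remaining - s
  }
  list(point = p, dir = d)
}

#' Approximate geodesic distance between two points on an ellipsoid
#'
#' Measures the arc length of the curve obtained by spherically interpolating
#' the two radial directions and projecting onto the surface. Exact on a
#' sphere; within a percent of the true geodesic for head-like eccentricities.
#'
#' @param p,q surface points.
#' @param ax semi-axes.
#' @param n number of segments.
#' @keywords internal
surface_distance <- function(p, q, ax, n = 400) {
  p <- ell_project(p, ax); q <- ell_project(q, ax)
  u <- p / sqrt(sum(p^2)); v <- q / sqrt(sum(q^2))
  cosw <- max(-1, min(1, sum(u * v)))
  w <- acos(cosw)
  if (w < 1e-12) return(0)
  ts <- seq(0, 1, length.out = n + 1)
  pts <- vapply(ts, function(t) {
    s <- (sin((1 - t) * w) * u + sin(t * w) * v) / sin(w)
    ell_project(s, ax)
  }, numeric(3))
  sum(sqrt(rowSums(diff(t(pts))^2)))
}

#' Point on the circumferential ring of an ellipsoid
#'
#' The ring is the intersection of the surface with the horizontal plane
#' z = `z_mm`. Azimuth 0 deg points anterior (+y) and increases toward the
#' right (+x).
#'
#' @param ax semi-axes of the surface.
#' @param azimuth_deg azimuth in degrees.
#' @param z_mm height of the ring plane above the center.
#' @keywords internal
ring_point <- function(ax, azimuth_deg, z_mm) {
  if (abs(z_mm) >= ax[3])
    stop("ring plane lies outside the ellipsoid")
  s <- sqrt(1 - (z_mm / ax[3])^2)
  a <- ax[1] * s; b <- ax[2] * s
  th <- azimuth_deg * pi / 180
  dx <- sin(th); dy <- cos(th)
  r <- 1 / sqrt((dx / a)^2 + (dy / b)^2)
  c(r * dx, r * dy, z_mm)
}

#' Local tangent frame at an ellipsoid surface point
#'
#' Returns `e1` pointing in the azimuthal (circumferential) direction and
#' `e2` in the meridional direction toward the superior pole, both unit
#' tangents, plus the outward normal. `angle_deg` rotates the frame in-plane
#' about the normal (right-handed).
#'
#' @keywords internal
tangent_frame <- function(p, ax, angle_deg = 0) {
  n <- ell_normal(p, ax)
  e2 <- tangentize(c(0, 0, 1), p, ax)
  if (is.null(e2)) {  # at/near a pole: meridian direction degenerate
    e2 <- tangentize(c(0, 1, 0), p, ax)
    if (is.null(e2)) stop("cannot build a tangent frame at this point")
  }
  e1 <- cross3(e2, n)
  e1 <- e1 / sqrt(sum(e1^2))
  if (angle_deg != 0) {
    th <- angle_deg * pi / 180
    e1r <- cos(th) * e1 + sin(th) * e2
    e2r <- -sin(th) * e1 + cos(th) * e2
    e1 <- e1r; e2 <- e2r
  }
  list(e1 = e1, e2 = e2, normal = n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
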