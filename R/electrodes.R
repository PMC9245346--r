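# Transducer arrays on the scalp and the three layout families.
#
# One array is a 3 x 3 grid of ceramic discs (20 mm diameter, 1 mm height)
# with center-to-center pitch 45 mm along the array's long axis and 22 mm
# along its short axis. Two opposed arrays form a driven pair carrying a
# fixed total current. Disc centers are laid out by geodesic walks on the
# scalp ellipsoid so the pitches are preserved as surface distances.

ARRAY_LONG_PITCH_MM <- 45
ARRAY_SHORT_PITCH_MM <- 22
DISC_DIAMETER_MM <- 20
DISC_HEIGHT_MM <- 1

#' Construct one 3 x 3 transducer array on the scalp
#'
#' The array is laid out in the local tangent frame at `surface_point` (long
#' axis along `e1`, short axis along `e2`, optionally rotated in-plane by
#' `in_plane_angle`) and wrapped onto the scalp surface by geodesic walks, so
#' nearest-neighbor disc spacing is 45 mm x 22 mm measured along the surface.
#'
#' @param geom a [head_geometry()] providing the scalp surface.
#' @param surface_point world point on (or near) the scalp surface; projected
#'   onto it.
#' @param in_plane_angle rotation of the array about the surface normal, in
#'   degrees (0 and 360 give identical arrays).
#' @param polarity `"source"` or `"sink"`.
#' @return object of class `transducer_array` with fields `centers` (9 x 3
#'   world mm), `normals` (9 x 3 outward unit normals), `center`, `frame`,
#'   `polarity`, `disc_diameter_mm`, `disc_height_mm`.
#' @export
make_array <- function(geom, surface_point, in_plane_angle = 0,
                       polarity = c("source", "sink")) {
  stopifnot(inherits(geom, "head_geometry"))
  polarity <- match.arg(polarity)
  ax <- geom$semiaxes$scalp
  ctr <- ell_project(as.numeric(surface_point), ax)
  fr <- tangent_frame(ctr, ax, in_plane_angle %% 360)

  centers <- matrix(0, 9, 3)
  normals <- matrix(0, 9, 3)
  k <- 0
  for (i in -1:1) {
    # walk along the long axis, then transport the short axis
    leg1 <- if (i == 0) list(point = ctr, dir = fr$e1)
            else surface_walk(ctr, i * fr$e1, abs(i) * ARRAY_LONG_PITCH_MM, ax)
    e2t <- tangentize(fr$e2, leg1$point, ax)
    for (j in -1:1) {
      k <- k + 1
      p <- if (j == 0) leg1$point
           else surface_walk(leg1$point, j * e2t, abs(j) * ARRAY_SHORT_PITCH_MM, ax)$point
      centers[k, ] <- p
      normals[k, ] <- ell_normal(p, ax)
    }
  }
  # all disc centers must stay on the head (z above the lower apex region is
  # implied by projection; reject wrapping past the inferior boundary)
  if (any(!is.finite(centers)))
    stop("array wraps past the surface boundary")
  structure(list(centers = centers, normals = normals, center = ctr,
                 frame = fr, polarity = polarity,
                 disc_diameter_mm = DISC_DIAMETER_MM,
                 disc_height_mm = DISC_HEIGHT_MM),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat("3x3 transducer array (", x$polarity, ") centered at [",
      paste(sprintf("%.1f", x$center), collapse = ", "), "] mm\n", sep = "")
  invisible(x)
}

check_pair_angle <- function(angle_deg) {
  if (!is.numeric(angle_deg) || length(angle_deg) != 1 || !is.finite(angle_deg))
    stop("angle must be a single number")
  if (abs(angle_deg - round(angle_deg / 15) * 15) > 1e-9)
    stop("angle must be a multiple of 15 degrees")
  angle_deg %% 360
}

#' Circumferential array-pair layout
#'
#' Places the two arrays of a pair at diametrically opposite azimuths on the
#' ring `ring_z_mm` above the central horizontal plane and sweeps the pair
#' around the craniocaudal axis in 15-degree steps. Azimuth 0 is the
#' anterior-posterior configuration; at 60 degrees the ipsilateral array sits
#' over the default lesion (and over the `over_tumor` burr-hole quincunx).
#'
#' @param geom a [head_geometry()].
#' @param angle_deg multiple of 15 degrees; the canonical sweep is 0-165
#'   (the pair has 180-degree symmetry), larger multiples are accepted and
#'   wrap onto the same field problems with polarity exchanged.
#' @param ring_z_mm height of the rotation plane (default 50 mm).
#' @return list of two [make_array()] objects `(ipsi, contra)` with
#'   polarities source and sink, plus attributes recording the layout.
#' @export
layout_circumferential <- function(geom, angle_deg, ring_z_mm = 50) {
  angle_deg <- check_pair_angle(angle_deg)
  ax <- geom$semiaxes$scalp
  p_ipsi <- ring_point(ax, angle_deg, ring_z_mm)
  p_contra <- ring_point(ax, angle_deg + 180, ring_z_mm)
  pair <- list(ipsi = make_array(geom, p_ipsi, polarity = "source"),
               contra = make_array(geom, p_contra, polarity = "sink"))
  attr(pair, "layout") <- list(family = "circumferential",
                               parameter = angle_deg, ring_z_mm = ring_z_mm)
  pair
}

#' Normal-axis rotation layout
#'
#' Starts from the 60-degree circumferential layout (ipsilateral array over
#' the lesion) and rotates the ipsilateral array about the axis normal to the
#' scalp at its fixed center; the contralateral array is identical across all
#' angles.
#'
#' @inheritParams layout_circumferential
#' @param base_angle_deg circumferential angle of the reference configuration
#'   (default 60).
#' @return list `(ipsi, contra)` as in [layout_circumferential()].
#' @export
layout_normal_rotation <- function(geom, angle_deg, base_angle_deg = 60,
                                   ring_z_mm = 50) {
  angle_deg <- check_pair_angle(angle_deg)
  ax <- geom$semiaxes$scalp
  p_ipsi <- ring_point(ax, base_angle_deg, ring_z_mm)
  p_contra <- ring_point(ax, base_angle_deg + 180, ring_z_mm)
  pair <- list(ipsi = make_array(geom, p_ipsi, in_plane_angle = angle_deg,
                                 polarity = "source"),
               contra = make_array(geom, p_contra, polarity = "sink"))
  attr(pair, "layout") <- list(family = "normal_rotation",
                               parameter = angle_deg,
                               base_angle_deg = base_angle_deg,
                               ring_z_mm = ring_z_mm)
  pair
}

#' Vertex-translation layout
#'
#' Starting 30 mm inferior to the 60-degree circumferential positions, both
#' arrays travel symmetrically along their scalp meridians toward the vertex
#' in 10 mm steps. Near the maximum travel the two arrays meet at the top of
#' the head: each array's center stops `stop_mm` short of the pole, so at
#' large travels the footprints overlap/abut and the pair shunts through the
#' scalp.
#'
#' @inheritParams layout_normal_rotation
#' @param travel_mm surface travel toward the vertex, in \[20, 150\] mm.
#' @param stop_mm clearance at which an array center stops short of the pole
#'   (default 12 mm).
#' @return list `(ipsi, contra)` as in [layout_circumferential()].
#' @export
layout_vertex_translation <- function(geom, travel_mm, base_angle_deg = 60,
                                      ring_z_mm = 50, stop_mm = 12) {
  if (!is.numeric(travel_mm) || length(travel_mm) != 1 ||
      travel_mm < 20 || travel_mm > 150)
    stop("travel_mm must lie in [20, 150] mm")
  ax <- geom$semiaxes$scalp
  pole <- c(0, 0, ax[3])
  place <- function(azimuth) {
    p0 <- ring_point(ax, azimuth, ring_z_mm)
    p0 <- walk_dir(p0, ax, "inferior", 30)   # starting position
    arc_to_pole <- surface_distance(p0, pole, ax)
    eff <- min(travel_mm, max(arc_to_pole - stop_mm, 0))
    walk_dir(p0, ax, "superior", eff)
  }
  p_ipsi <- place(base_angle_deg)
  p_contra <- place(base_angle_deg + 180)
  pair <- list(ipsi = make_array(geom, p_ipsi, polarity = "source"),
               contra = make_array(geom, p_contra, polarity = "sink"))
  attr(pair, "layout") <- list(family = "vertex_translation",
                               parameter = travel_mm,
                               base_angle_deg = base_angle_deg,
                               ring_z_mm = ring_z_mm, stop_mm = stop_mm)
  pair
}

#' Serialize an array pair to a plain list (for JSON export)
#'
#' @param pair a layout from one of the `layout_*` functions.
#' @return a nested list of disc centers, normals and polarities.
#' @export
pair_to_list <- function(pair) {
  lapply(pair, function(a) list(
    polarity = a$polarity,
    centers = unname(apply(a$centers, 1, function(r) as.numeric(r), simplify = FALSE)),
    normals = unname(apply(a$normals, 1, function(r) as.numeric(r), simplify = FALSE)),
    disc_diameter_mm = a$disc_diameter_mm,
    disc_height_mm = a$disc_height_mm))
}
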