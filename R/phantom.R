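# Synthetic head phantom: nested-ellipsoid anatomy, tumor pathology and
# skull-remodeling burr holes, represented as an integer label volume.

#' Tissue label codes used by the phantom
#'
#' Named integer vector mapping tissue names to the label ids stored in a
#' [label_volume()]. Background is 0; pathology and surgery labels are only
#' present after [insert_pathology()] / [apply_sr_surgery()].
#'
#' @export
TISSUE_LABELS <- c(
  background      = 0L,
  scalp           = 1L,
  skull           = 2L,
  csf             = 3L,
  gm              = 4L,
  wm              = 5L,
  resection_cavity = 6L,
  funnel          = 7L,
  residual_tumor  = 8L,
  burr_hole       = 9L
)

#' Head phantom geometry
#'
#' Describes the layered head as nested concentric ellipsoids: an outer scalp
#' ellipsoid and uniform shell thicknesses for scalp, skull and CSF, a
#' cortical gray-matter shell, and white matter filling the remainder.
#'
#' Defaults approximate an adult head (outer semi-axes 85 x 105 x 95 mm;
#' scalp 6 mm, skull 7 mm, CSF 3 mm, GM 4 mm).
#'
#' @param outer_semiaxes_mm length-3 semi-axes of the scalp surface (x = left-
#'   right, y = anterior-posterior, z = inferior-superior), in mm.
#' @param scalp_mm,skull_mm,csf_mm,gm_mm shell thicknesses in mm; the interior
#'   of the GM shell is white matter.
#' @return an object of class `head_geometry`.
#' @export
#' @examples
#' geom <- head_geometry()
#' geom$semiaxes$wm  # innermost (white matter) ellipsoid
head_geometry <- function(outer_semiaxes_mm = c(85, 105, 95),
                          scalp_mm = 6, skull_mm = 7, csf_mm = 3, gm_mm = 4) {
  outer_semiaxes_mm <- as.numeric(outer_semiaxes_mm)
  th <- c(scalp = scalp_mm, skull = skull_mm, csf = csf_mm, gm = gm_mm)
  if (length(outer_semiaxes_mm) != 3 || any(!is.finite(outer_semiaxes_mm)) ||
      any(outer_semiaxes_mm <= 0))
    stop("outer_semiaxes_mm must be three positive numbers")
  if (any(!is.finite(th)) || any(th <= 0))
    stop("all shell thicknesses must be positive")
  if (sum(th) >= min(outer_semiaxes_mm))
    stop("shell thicknesses leave no room for white matter")
  cum <- cumsum(th)
  semiaxes <- list(
    scalp = outer_semiaxes_mm,
    skull = outer_semiaxes_mm - cum[1],
    csf   = outer_semiaxes_mm - cum[2],
    gm    = outer_semiaxes_mm - cum[3],
    wm    = outer_semiaxes_mm - cum[4]
  )
  structure(list(outer_semiaxes_mm = outer_semiaxes_mm,
                 thickness_mm = th, semiaxes = semiaxes),
            class = "head_geometry")
}

#' @export
print.head_geometry <- function(x, ...) {
  cat("Head phantom geometry (nested ellipsoids, mm)\n")
  cat("  outer semi-axes:", paste(x$outer_semiaxes_mm, collapse = " x "), "\n")
  cat("  shells: scalp", x$thickness_mm["scalp"], "| skull",
      x$thickness_mm["skull"], "| CSF", x$thickness_mm["csf"],
      "| GM", x$thickness_mm["gm"], "| WM remainder\n")
  invisible(x)
}

#' Construct a label volume
#'
#' Container for a 3-D integer tissue-label grid with its voxel size and
#' voxel-to-world (RAS, mm) affine. Most users obtain one from
#' [build_head_phantom()] or [read_label_volume()].
#'
#' @param labels 3-D integer array of label ids.
#' @param voxel_mm length-3 voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param label_names named integer vector mapping tissue names to ids.
#' @param geom optional [head_geometry()] the volume was built from.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_mm, affine, label_names = TISSUE_LABELS,
                         geom = NULL) {
  if (length(dim(labels)) != 3) stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  present <- unique(as.vector(labels))
  unknown <- setdiff(present, unname(label_names))
  if (length(unknown) > 0)
    stop("labels contain ids not in label_names: ",
         paste(unknown, collapse = ", "))
  structure(list(labels = labels, voxel_mm = voxel_mm, affine = affine,
                 label_names = label_names, geom = geom),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume:", paste(dim(x$labels), collapse = " x "), "voxels @",
      paste(x$voxel_mm, collapse = " x "), "mm\n")
  tab <- table(factor(x$labels, levels = unname(x$label_names),
                      labels = names(x$label_names)))
  tab <- tab[tab > 0]
  for (nm in names(tab)) cat(sprintf("  %-16s %8d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

# World coordinates of voxel centers along each axis (assumes the affine is
# diagonal, which holds for all volumes the package itself generates).
voxel_axes <- function(vol) {
  d <- dim(vol$labels)
  A <- vol$affine
  list(x = A[1, 4] + A[1, 1] * (seq_len(d[1]) - 1),
       y = A[2, 4] + A[2, 2] * (seq_len(d[2]) - 1),
       z = A[3, 4] + A[3, 3] * (seq_len(d[3]) - 1))
}

# Full 3-D world-coordinate arrays (X, Y, Z), each with the grid dimensions.
voxel_coords <- function(vol) {
  ax <- voxel_axes(vol)
  d <- dim(vol$labels)
  list(X = array(rep(ax$x, times = d[2] * d[3]), dim = d),
       Y = array(rep(rep(ax$y, each = d[1]), times = d[3]), dim = d),
       Z = array(rep(ax$z, each = d[1] * d[2]), dim = d))
}

#' Rasterize the layered head phantom
#'
#' Labels a regular voxel grid with the nested-ellipsoid anatomy of a
#' [head_geometry()]: scalp, skull, CSF, gray matter and white matter from the
#' outside in, with background outside the head. Voxels are classified by
#' their center point. The grid is symmetric about the head center (world
#' origin) with at least one voxel of background margin, so no anatomy is
#' clipped.
#'
#' @param geom a [head_geometry()].
#' @param voxel_mm voxel size in mm; a scalar (isotropic) or length-3 vector.
#'   Each component must lie in \[1, 4\] mm and must not exceed the thinnest
#'   shell (a shell thinner than one voxel could vanish from the grid).
#' @return a [label_volume()] carrying `geom`.
#' @export
#' @examples
#' vol <- build_head_phantom(head_geometry(), voxel_mm = 4)  # coarse demo
build_head_phantom <- function(geom, voxel_mm = 2) {
  stopifnot(inherits(geom, "head_geometry"))
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (length(voxel_mm) != 3 || any(!is.finite(voxel_mm)))
    stop("voxel_mm must be a scalar or length-3 vector")
  if (any(voxel_mm < 1) || any(voxel_mm > 4))
    stop("voxel_mm components must lie in [1, 4] mm")
  if (min(geom$thickness_mm) < max(voxel_mm))
    stop(sprintf(
      "voxel size %.1f mm cannot resolve the thinnest shell (%.1f mm)",
      max(voxel_mm), min(geom$thickness_mm)))

  half_n <- floor((geom$outer_semiaxes_mm + 2 * voxel_mm) / voxel_mm)
  d <- 2L * as.integer(half_n) + 1L
  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- -half_n * voxel_mm

  vol0 <- list(labels = array(0L, dim = d), affine = affine)
  co <- voxel_coords(vol0)

  labels <- array(TISSUE_LABELS[["background"]], dim = d)
  shells <- c("scalp", "skull", "csf", "gm", "wm")
  for (sh in shells) {
    ax <- geom$semiaxes[[sh]]
    inside <- (co$X / ax[1])^2 + (co$Y / ax[2])^2 + (co$Z / ax[3])^2 <= 1
    labels[inside] <- TISSUE_LABELS[[sh]]
  }
  label_volume(labels, voxel_mm, affine, geom = geom)
}

# --- Pathology -------------------------------------------------------------

#' Specify the tumor pathology (resection cavity, funnel track, residual tumor)
#'
#' The default placement emulates a superficial parieto-temporal lesion: the
#' cavity center sits along the radial ray through the circumferential ring
#' point at `azimuth_deg` (see [ring_point()]) at height `ring_z_mm`, buried
#' `depth_margin_mm` below the brain surface; the residual tumor sphere is
#' tangent to the cavity directly beneath it (deeper along the funnel axis),
#' and the funnel track runs radially from the cavity to the inner skull
#' table.
#'
#' @param geom a [head_geometry()].
#' @param cavity_diameter_mm,tumor_diameter_mm sphere diameters (default 25).
#' @param funnel_diameter_mm surgical-corridor diameter (default 8).
#' @param azimuth_deg,ring_z_mm placement of the radial axis (defaults 60 deg,
#'   50 mm, so the lesion lies under the 60-degree circumferential array).
#' @param depth_margin_mm clearance between the cavity sphere and the brain
#'   surface along the radial ray.
#' @return object of class `pathology_spec` with world-space centers (mm) and
#'   the funnel axis (unit vector pointing from the cavity toward the skull).
#' @export
pathology_spec <- function(geom, cavity_diameter_mm = 25,
                           tumor_diameter_mm = 25, funnel_diameter_mm = 8,
                           azimuth_deg = 60, ring_z_mm = 50,
                           depth_margin_mm = 2) {
  stopifnot(inherits(geom, "head_geometry"))
  if (cavity_diameter_mm <= 0 || tumor_diameter_mm <= 0)
    stop("cavity and tumor diameters must be positive")
  if (funnel_diameter_mm <= 0)
    stop("the funnel track must have a positive diameter")
  p_ring <- ring_point(geom$semiaxes$scalp, azimuth_deg, ring_z_mm)
  u <- p_ring / sqrt(sum(p_ring^2))
  r_brain <- ell_ray(c(0, 0, 0), u, geom$semiaxes$gm)
  r_cav <- cavity_diameter_mm / 2
  r_tum <- tumor_diameter_mm / 2
  cavity_center <- (r_brain - r_cav - depth_margin_mm) * u
  tumor_center <- cavity_center - (r_cav + r_tum) * u
  structure(list(cavity_center = cavity_center,
                 cavity_diameter_mm = cavity_diameter_mm,
                 tumor_center = tumor_center,
                 tumor_diameter_mm = tumor_diameter_mm,
                 funnel_diameter_mm = funnel_diameter_mm,
                 funnel_axis = u),
            class = "pathology_spec")
}

# TRUE when the sphere (center, r) lies inside the ellipsoid with semi-axes
# ax, checked on a dense sample of surface directions (conservative in the
# limit of the sample; ample for the clearances used here).
sphere_in_ellipsoid <- function(center, r, ax, n = 200) {
  set_pts <- fibonacci_sphere(n)
  pts <- sweep(r * set_pts, 2, center, "+")
  all(rowSums(sweep(pts, 2, ax, "/")^2) <= 1)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Carve the tumor pathology into a head phantom
#'
#' Replaces brain voxels inside the cavity sphere with `resection_cavity`,
#' voxels inside the tumor sphere with `residual_tumor`, and CSF/GM/WM voxels
#' inside the funnel cylinder (from the cavity center to the inner skull
#' table) with `funnel`. All other voxels are untouched.
#'
#' @param vol a [label_volume()] from [build_head_phantom()].
#' @param spec a [pathology_spec()]; defaults to `pathology_spec(vol$geom)`.
#' @return a new [label_volume()] with pathology labels.
#' @export
insert_pathology <- function(vol, spec = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(spec)) {
    if (is.null(vol$geom)) stop("spec is required when the volume has no geometry")
    spec <- pathology_spec(vol$geom)
  }
  stopifnot(inherits(spec, "pathology_spec"))
  geom <- vol$geom
  if (is.null(geom)) stop("insert_pathology needs a phantom built by build_head_phantom")

  r_cav <- spec$cavity_diameter_mm / 2
  r_tum <- spec$tumor_diameter_mm / 2
  if (!sphere_in_ellipsoid(spec$cavity_center, r_cav, geom$semiaxes$gm))
    stop("resection cavity protrudes outside the brain")
  if (!sphere_in_ellipsoid(spec$tumor_center, r_tum, geom$semiaxes$gm))
    stop("residual tumor protrudes outside the brain")
  gap <- sqrt(sum((spec$cavity_center - spec$tumor_center)^2))
  if (gap < r_cav + r_tum - 1e-6)
    stop("cavity and tumor spheres overlap")
  depth <- sum((spec$tumor_center - spec$cavity_center) * spec$funnel_axis)
  if (depth >= 0)
    stop("residual tumor must lie deeper than the cavity along the funnel axis")
  t_skull <- ell_ray(spec$cavity_center, spec$funnel_axis, geom$semiaxes$csf)
  if (!is.finite(t_skull))
    stop("funnel axis does not reach the inner skull table")

  co <- voxel_coords(vol)
  labels <- vol$labels
  brain <- labels %in% TISSUE_LABELS[c("gm", "wm")]
  dim(brain) <- dim(labels)

  dxc <- co$X - spec$cavity_center[1]
  dyc <- co$Y - spec$cavity_center[2]
  dzc <- co$Z - spec$cavity_center[3]
  in_cavity <- (dxc^2 + dyc^2 + dzc^2 <= r_cav^2) & brain
  labels[in_cavity] <- TISSUE_LABELS[["resection_cavity"]]

  dxt <- co$X - spec$tumor_center[1]
  dyt <- co$Y - spec$tumor_center[2]
  dzt <- co$Z - spec$tumor_center[3]
  in_tumor <- (dxt^2 + dyt^2 + dzt^2 <= r_tum^2) & brain
  labels[in_tumor] <- TISSUE_LABELS[["residual_tumor"]]

  ax_u <- spec$funnel_axis
  tpar <- dxc * ax_u[1] + dyc * ax_u[2] + dzc * ax_u[3]
  perp2 <- (dxc^2 + dyc^2 + dzc^2) - tpar^2
  carvable <- array(vol$labels %in% TISSUE_LABELS[c("csf", "gm", "wm")],
                    dim = dim(labels))
  in_funnel <- carvable & perp2 <= (spec$funnel_diameter_mm / 2)^2 &
    tpar > 0 & tpar <= t_skull
  labels[in_funnel] <- TISSUE_LABELS[["funnel"]]

  out <- vol
  out$labels <- labels
  out$pathology <- spec
  out
}

# --- Skull-remodeling surgery ----------------------------------------------

#' Specify a burr-hole quincunx
#'
#' Five skull perforations: one central hole plus four at the corners of a
#' square of side `span_mm`, all of diameter `hole_diameter_mm`, centered on a
#' point of the outer skull surface with axes along the local surface normal.
#'
#' @param center world-space point on (or near) the outer skull surface (mm);
#'   it is projected onto the surface.
#' @param hole_diameter_mm hole diameter (default 15).
#' @param span_mm side of the square holding the four outer holes (default 45).
#' @param orientation_deg in-plane rotation of the square (default 0: square
#'   sides along the azimuthal/meridional directions).
#' @param variant optional tag recording how the placement was chosen.
#' @return object of class `quincunx_spec`.
#' @export
quincunx_spec <- function(center, hole_diameter_mm = 15, span_mm = 45,
                          orientation_deg = 0, variant = "custom") {
  if (hole_diameter_mm <= 0 || span_mm <= 0)
    stop("hole diameter and span must be positive")
  if (span_mm / sqrt(2) < hole_diameter_mm)
    stop("holes would overlap: span too small for the hole diameter")
  structure(list(center = as.numeric(center),
                 hole_diameter_mm = hole_diameter_mm, span_mm = span_mm,
                 orientation_deg = orientation_deg, variant = variant),
            class = "quincunx_spec")
}

#' Place the burr-hole quincunx for a named surgical variant
#'
#' `over_tumor` centers the quincunx at the skull point radially above the
#' cavity/tumor centroid; `sup3`, `post3` and `sup3post3` translate that
#' center 30 mm along the skull surface superiorly, posteriorly, or both;
#' `far` walks 110 mm posteriorly and 20 mm inferiorly into the ipsilateral
#' occipito-parietal region (well over 80 mm of surface distance from the
#' lesion); `none` is the no-hole control and returns `NULL`.
#'
#' @param vol a [label_volume()] containing pathology labels (needed to locate
#'   the lesion centroid), built on a phantom geometry.
#' @param variant one of `"over_tumor"`, `"sup3"`, `"post3"`, `"sup3post3"`,
#'   `"far"`, `"none"`.
#' @return a [quincunx_spec()], or `NULL` for `variant = "none"`.
#' @export
place_quincunx <- function(vol, variant = "over_tumor") {
  stopifnot(inherits(vol, "label_volume"))
  variants <- c("over_tumor", "sup3", "post3", "sup3post3", "far", "none")
  if (!variant %in% variants)
    stop("unknown SR-surgery variant: ", variant)
  if (variant == "none") return(NULL)
  geom <- vol$geom
  if (is.null(geom)) stop("place_quincunx needs a phantom with geometry")
  ax <- geom$semiaxes$skull  # outer skull surface

  centroid <- pathology_centroid(vol)
  u <- centroid / sqrt(sum(centroid^2))
  base <- ell_project(u, ax)

  center <- switch(variant,
    over_tumor = base,
    sup3 = walk_dir(base, ax, "superior", 30),
    post3 = walk_dir(base, ax, "posterior", 30),
    sup3post3 = walk_dir(walk_dir(base, ax, "superior", 30), ax, "posterior", 30),
    far = walk_dir(walk_dir(base, ax, "posterior", 110), ax, "inferior", 20)
  )
  quincunx_spec(center, variant = variant)
}

walk_dir <- function(p, ax, direction, dist) {
  fr <- tangent_frame(p, ax)
  d <- switch(direction,
    superior = fr$e2,
    inferior = -fr$e2,
    posterior = if (sum(fr$e1 * c(0, -1, 0)) >= 0) fr$e1 else -fr$e1,
    anterior = if (sum(fr$e1 * c(0, 1, 0)) >= 0) fr$e1 else -fr$e1
  )
  surface_walk(p, d, dist, ax)$point
}

# Centroid (world mm) of the cavity + residual tumor labels.
pathology_centroid <- function(vol) {
  mask <- vol$labels %in% TISSUE_LABELS[c("resection_cavity", "residual_tumor")]
  if (!any(mask)) stop("volume has no pathology labels; run insert_pathology first")
  co <- voxel_coords(vol)
  c(mean(co$X[mask]), mean(co$Y[mask]), mean(co$Z[mask]))
}

# World-space centers of the five holes (central + four square corners),
# laid out by geodesic walks on the outer skull surface.
quincunx_hole_centers <- function(spec, ax) {
  ctr <- ell_project(spec$center, ax)
  fr <- tangent_frame(ctr, ax, spec$orientation_deg)
  half <- spec$span_mm / 2
  corners <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(s) {
    w1 <- surface_walk(ctr, s[1] * fr$e1, half, ax)
    # transport e2 along the first leg: re-tangentize at the new point
    e2t <- tangentize(fr$e2, w1$point, ax)
    surface_walk(w1$point, s[2] * e2t, half, ax)$point
  })
  do.call(rbind, c(list(ctr), corners))
}

#' Drill burr holes into the skull of a phantom
#'
#' Within each of the five hole cylinders (axis along the local skull-surface
#' normal), voxels labeled `skull` become `burr_hole`; no other label is ever
#' modified. Downstream, `burr_hole` maps to CSF conductivity.
#'
#' @param vol a [label_volume()] (typically with pathology already inserted).
#' @param spec a [quincunx_spec()], e.g. from [place_quincunx()]; `NULL` is
#'   the no-hole control and returns `vol` unchanged.
#' @return a new [label_volume()] with `burr_hole` labels.
#' @export
apply_sr_surgery <- function(vol, spec) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(spec)) return(vol)
  stopifnot(inherits(spec, "quincunx_spec"))
  geom <- vol$geom
  if (is.null(geom)) stop("apply_sr_surgery needs a phantom with geometry")
  ax <- geom$semiaxes$skull

  centers <- quincunx_hole_centers(spec, ax)
  r_hole <- spec$hole_diameter_mm / 2
  dmin <- min(stats::dist(centers))
  if (dmin < spec$hole_diameter_mm)
    stop("burr holes overlap each other")

  co <- voxel_coords(vol)
  labels <- vol$labels
  skull_mask <- labels == TISSUE_LABELS[["skull"]]
  reach <- geom$thickness_mm[["skull"]] + 2 * max(vol$voxel_mm)
  n_before <- sum(skull_mask)
  for (i in seq_len(nrow(centers))) {
    cc <- centers[i, ]
    nrm <- ell_normal(cc, ax)
    dx <- co$X - cc[1]; dy <- co$Y - cc[2]; dz <- co$Z - cc[3]
    tpar <- dx * nrm[1] + dy * nrm[2] + dz * nrm[3]
    perp2 <- (dx^2 + dy^2 + dz^2) - tpar^2
    in_hole <- skull_mask & perp2 <= r_hole^2 & abs(tpar) <= reach
    if (!any(in_hole))
      stop(sprintf("burr hole %d does not intersect the skull", i))
    labels[in_hole] <- TISSUE_LABELS[["burr_hole"]]
  }
  # each hole must fully pierce the skull: the ray along the hole axis from
  # outside the head to the center must cross no remaining skull voxel
  for (i in seq_len(nrow(centers))) {
    cc <- centers[i, ]
    nrm <- ell_normal(cc, ax)
    ts <- seq(-geom$thickness_mm[["skull"]] - 1, 1, by = min(vol$voxel_mm) / 2)
    pts <- t(vapply(ts, function(t) cc + t * nrm, numeric(3)))
    ids <- world_to_voxel(vol, pts)
    hit <- labels[ids]
    if (any(hit == TISSUE_LABELS[["skull"]]))
      stop(sprintf("burr hole %d does not pierce the full skull thickness", i))
  }
  out <- vol
  out$labels <- labels
  out$quincunx <- spec
  out$quincunx_centers <- centers
  out
}

# Linear voxel indices of world points (nearest voxel center); points outside
# the grid are clamped to its boundary.
world_to_voxel <- function(vol, pts) {
  ax <- voxel_axes(vol)
  d <- dim(vol$labels)
  ix <- pmin(pmax(round((pts[, 1] - ax$x[1]) / vol$voxel_mm[1]) + 1, 1), d[1])
  iy <- pmin(pmax(round((pts[, 2] - ax$y[1]) / vol$voxel_mm[2]) + 1, 1), d[2])
  iz <- pmin(pmax(round((pts[, 3] - ax$z[1]) / vol$voxel_mm[3]) + 1, 1), d[3])
  as.integer(ix + d[1] * (iy - 1) + d[1] * d[2] * (iz - 1))
}

#' Build a complete study phantom in one call
#'
#' Convenience wrapper: [build_head_phantom()] + [insert_pathology()] +
#' [place_quincunx()] / [apply_sr_surgery()].
#'
#' @param geom a [head_geometry()] (default [head_geometry()]).
#' @param voxel_mm voxel size in mm.
#' @param sr_variant SR-surgery variant passed to [place_quincunx()];
#'   `"none"` gives the no-hole control.
#' @return a [label_volume()].
#' @export
#' @examples
#' vol <- build_study_phantom(voxel_mm = 4, sr_variant = "none")
build_study_phantom <- function(geom = head_geometry(), voxel_mm = 3,
                                sr_variant = "over_tumor") {
  vol <- build_head_phantom(geom, voxel_mm)
  vol <- insert_pathology(vol)
  apply_sr_surgery(vol, place_quincunx(vol, sr_variant))
}
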