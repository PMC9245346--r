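# Dose statistics: per-region medians and 99th-percentile peaks, cumulative
# exposure curves, and absolute/percent enhancement against a no-hole control.

#' Derive the evaluation regions from a labeled phantom
#'
#' Builds named voxel masks for white matter, gray matter, the residual
#' tumor, the resection cavity, and a peritumoral shell: brain voxels (GM or
#' WM) within `peritumoral_margin_mm` of the cavity or tumor, excluding the
#' cavity, funnel and tumor themselves. The margin is a morphological
#' dilation with a Euclidean ball on the voxel grid.
#'
#' @param vol a [label_volume()] with pathology labels.
#' @param peritumoral_margin_mm dilation margin (mm), must be positive.
#' @return object of class `region_set`: a named list of logical 3-D masks
#'   (`wm`, `gm`, `peritumoral`, `residual_tumor`, `resection_cavity`) with
#'   the derivation recorded in `attr(, "provenance")`.
#' @export
derive_regions <- function(vol, peritumoral_margin_mm = 10) {
  stopifnot(inherits(vol, "label_volume"))
  if (!is.numeric(peritumoral_margin_mm) || peritumoral_margin_mm <= 0)
    stop("peritumoral margin must be positive")
  lab <- vol$labels
  has_pathology <- any(lab == TISSUE_LABELS[["residual_tumor"]]) ||
    any(lab == TISSUE_LABELS[["resection_cavity"]])
  if (!has_pathology) stop("volume carries no pathology labels")

  wm <- lab == TISSUE_LABELS[["wm"]]
  gm <- lab == TISSUE_LABELS[["gm"]]
  tumor <- lab == TISSUE_LABELS[["residual_tumor"]]
  cavity <- lab == TISSUE_LABELS[["resection_cavity"]]
  funnel <- lab == TISSUE_LABELS[["funnel"]]

  core <- tumor | cavity
  dil <- dilate_mask(core, peritumoral_margin_mm, vol$voxel_mm)
  peri <- dil & (wm | gm)

  structure(list(wm = wm, gm = gm, peritumoral = peri,
                 residual_tumor = tumor, resection_cavity = cavity),
            provenance = sprintf(
                 "peritumoral = (GM|WM) within %g mm of cavity|tumor, minus cavity/funnel/tumor",
                 peritumoral_margin_mm),
            class = "region_set")
}

# Binary dilation of a 3-D mask by a Euclidean ball of radius_mm, implemented
# as an OR over all voxel offsets inside the ball.
dilate_mask <- function(mask, radius_mm, voxel_mm) {
  d <- dim(mask)
  noff <- floor(radius_mm / voxel_mm)
  offs <- expand.grid(ox = -noff[1]:noff[1], oy = -noff[2]:noff[2],
                      oz = -noff[3]:noff[3])
  r2 <- (offs$ox * voxel_mm[1])^2 + (offs$oy * voxel_mm[2])^2 +
    (offs$oz * voxel_mm[3])^2
  offs <- offs[r2 <= radius_mm^2, , drop = FALSE]
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    sx <- seq_len(d[1]) - o[1]; ok_x <- sx >= 1 & sx <= d[1]
    sy <- seq_len(d[2]) - o[2]; ok_y <- sy >= 1 & sy <= d[2]
    sz <- seq_len(d[3]) - o[3]; ok_z <- sz >= 1 & sz <= d[3]
    out[ok_x, ok_y, ok_z] <- out[ok_x, ok_y, ok_z] |
      mask[sx[ok_x], sy[ok_y], sz[ok_z]]
  }
  out
}

#' Per-region dose statistics
#'
#' For each region mask: the voxelwise median field intensity, the peak
#' (defined as the 99th percentile), the voxel count, and the cumulative
#' exposure curve (fraction of the region with |E| above each threshold on a
#' regular grid). Voxels are equally weighted (regular lattice). Percentiles
#' use linear interpolation between order statistics (`stats::quantile`
#' type 7, matching the numpy default).
#'
#' @param sol a `field_solution`.
#' @param regions a `region_set` from [derive_regions()], or any named list
#'   of logical masks on the solution lattice.
#' @param curve_max_Vm,curve_step_Vm sampling grid of the cumulative curve
#'   (default 0-400 V/m in 2 V/m steps).
#' @return object of class `dose_report`: `stats` (data.frame with columns
#'   region, median_Vm, peak_Vm, n_voxels, empty) and `curves` (data.frame
#'   with columns region, threshold_Vm, fraction_above).
#' @export
region_stats <- function(sol, regions, curve_max_Vm = 400, curve_step_Vm = 2) {
  stopifnot(inherits(sol, "field_solution"))
  xs <- seq(0, curve_max_Vm, by = curve_step_Vm)
  rows <- list(); curves <- list()
  for (nm in names(regions)) {
    mask <- regions[[nm]]
    if (!identical(dim(mask), dim(sol$normE)))
      stop("region '", nm, "' is not on the solution lattice")
    v <- sol$normE[mask]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      rows[[nm]] <- data.frame(region = nm, median_Vm = NA_real_,
                               peak_Vm = NA_real_, n_voxels = 0L, empty = TRUE)
      next
    }
    rows[[nm]] <- data.frame(
      region = nm,
      median_Vm = stats::median(v),
      peak_Vm = unname(stats::quantile(v, 0.99, type = 7)),
      n_voxels = length(v), empty = FALSE)
    frac <- vapply(xs, function(x) mean(v > x), numeric(1))
    curves[[nm]] <- data.frame(region = nm, threshold_Vm = xs,
                               fraction_above = frac)
  }
  structure(list(stats = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 curves = do.call(rbind, c(curves, list(make.row.names = FALSE)))),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("Dose report (|E|, V/m):\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Field enhancement relative to a no-hole control
#'
#' Voxelwise absolute enhancement `dE = |E|_holes - |E|_control` and percent
#' enhancement `100 * dE / |E|_control`. Voxels whose control intensity is
#' below `floor_Vm` are flagged undefined in the percent map (never silently
#' infinite) and excluded from voxelwise summaries. Per-region summaries use
#' the median-ratio form: `median_holes - median_control` and that
#' difference divided by `median_control`, which needs no floor.
#'
#' @param sol_holes,sol_control `field_solution`s on the same lattice solved
#'   with the identical array layout (holes vs. no-hole phantom).
#' @param regions a `region_set` (masks from the hole-free anatomy apply to
#'   both solutions).
#' @param floor_Vm control-intensity floor for the voxelwise percent map.
#' @return object of class `enhancement_result`: `dE` and `pct` (3-D arrays;
#'   `pct` is NA where undefined), `pct_undefined` (logical mask of floored
#'   voxels), and `summary` (data.frame with region, median_holes_Vm,
#'   median_control_Vm, enhancement_Vm, enhancement_pct).
#' @export
enhancement <- function(sol_holes, sol_control, regions, floor_Vm = 1) {
  stopifnot(inherits(sol_holes, "field_solution"),
            inherits(sol_control, "field_solution"))
  if (!identical(dim(sol_holes$normE), dim(sol_control$normE)))
    stop("solutions are not on a common lattice")
  if (!identical(sol_holes$layout, sol_control$layout))
    stop("solutions were computed with different array layouts")

  dE <- sol_holes$normE - sol_control$normE
  undef <- !is.na(sol_control$normE) & sol_control$normE < floor_Vm
  pct <- 100 * dE / sol_control$normE
  pct[undef] <- NA_real_

  rows <- lapply(names(regions), function(nm) {
    v_h <- sol_holes$normE[regions[[nm]]]
    v_c <- sol_control$normE[regions[[nm]]]
    ok <- !is.na(v_h) & !is.na(v_c)
    if (!any(ok))
      return(data.frame(region = nm, median_holes_Vm = NA_real_,
                        median_control_Vm = NA_real_, enhancement_Vm = NA_real_,
                        enhancement_pct = NA_real_))
    mh <- stats::median(v_h[ok]); mc <- stats::median(v_c[ok])
    data.frame(region = nm, median_holes_Vm = mh, median_control_Vm = mc,
               enhancement_Vm = mh - mc,
               enhancement_pct = 100 * (mh - mc) / mc)
  })
  structure(list(dE = dE, pct = pct, pct_undefined = undef,
                 summary = do.call(rbind, rows)),
            class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat("Field enhancement vs. matched no-hole control:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Brain mask within a lateral distance of the quincunx axis
#'
#' The quincunx axis is the radial ray from the head center through the
#' quincunx center. Returns brain voxels (GM, WM, tumor, peritumoral tissue)
#' whose perpendicular distance to that axis is at most `radius_mm` — the
#' "directly underneath the holes" region used for localization checks and
#' the uncertainty analysis.
#'
#' @param vol a [label_volume()] whose quincunx is set (after
#'   [apply_sr_surgery()]), or `axis_point` given explicitly.
#' @param radius_mm lateral radius (mm), default 20.
#' @param axis_point optional world point defining the axis direction.
#' @param include optional character vector of labels to include (defaults to
#'   brain tissue plus pathology).
#' @return logical 3-D mask.
#' @export
subhole_mask <- function(vol, radius_mm = 20, axis_point = NULL,
                         include = c("gm", "wm", "residual_tumor",
                                     "resection_cavity", "funnel")) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(axis_point)) {
    if (is.null(vol$quincunx)) stop("volume has no quincunx; give axis_point")
    axis_point <- vol$quincunx$center
  }
  u <- axis_point / sqrt(sum(axis_point^2))
  co <- voxel_coords(vol)
  tpar <- co$X * u[1] + co$Y * u[2] + co$Z * u[3]
  perp2 <- co$X^2 + co$Y^2 + co$Z^2 - tpar^2
  tissue <- array(vol$labels %in% TISSUE_LABELS[include], dim = dim(vol$labels))
  tissue & perp2 <= radius_mm^2 & tpar > 0
}
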