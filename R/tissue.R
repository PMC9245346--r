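# Tissue label -> isotropic conductivity mapping.

#' Default tissue conductivity table
#'
#' Isotropic ohmic conductivities (S/m) for the phantom compartments: skin
#' 0.25, bone 0.010 (the merged spongy/compact skull value; a two-layer skull
#' can use 0.025 / 0.008 via `two_layer_skull`), CSF 1.654, gray matter 0.276,
#' white matter 0.126, residual tumor 0.24, resection cavity (necrotic fluid)
#' 1.0. The funnel track and the burr holes are fluid-filled and default to
#' the CSF value (1.654).
#'
#' @param two_layer_skull if `TRUE`, the single `skull` entry uses the spongy
#'   bone value 0.025 instead of the merged 0.010 (the compact-bone value
#'   0.008 is exposed for users supplying their own multi-layer labels).
#' @param overrides named numeric vector of per-tissue overrides (S/m).
#' @return named numeric vector of class `tissue_table` (tissue name -> S/m).
#' @export
#' @examples
#' tissue_table()[["wm"]]    # 0.126
#' tissue_table(overrides = c(funnel = 1.0))
tissue_table <- function(two_layer_skull = FALSE, overrides = NULL) {
  tab <- c(
    scalp            = 0.25,
    skull            = if (two_layer_skull) 0.025 else 0.010,
    csf              = 1.654,
    gm               = 0.276,
    wm               = 0.126,
    residual_tumor   = 0.24,
    resection_cavity = 1.0,
    funnel           = 1.654,
    burr_hole        = 1.654
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named numeric vector")
    unknown <- setdiff(names(overrides), names(tab))
    if (length(unknown) > 0)
      stop("overrides name unknown tissues: ", paste(unknown, collapse = ", "))
    tab[names(overrides)] <- overrides
  }
  if (any(tab <= 0)) stop("all conductivities must be positive")
  structure(tab, class = c("tissue_table", "numeric"))
}

#' Map tissue labels to a conductivity volume
#'
#' Voxelwise lookup of the label grid in a conductivity table. Background
#' voxels get conductivity 0 and are excluded from the solve domain; every
#' non-background label present in the volume must have a table entry.
#'
#' @param vol a [label_volume()].
#' @param table a [tissue_table()] (or any named numeric vector, S/m).
#' @return object of class `conductivity_volume`: fields `sigma` (3-D numeric
#'   array, S/m, 0 outside the head), plus the source labels, voxel size,
#'   affine and geometry carried over from `vol`.
#' @export
assign_conductivities <- function(vol, table = tissue_table()) {
  stopifnot(inherits(vol, "label_volume"))
  if (any(table <= 0)) stop("all conductivities must be positive")
  present <- setdiff(unique(as.vector(vol$labels)),
                     TISSUE_LABELS[["background"]])
  name_of <- names(vol$label_names)[match(present, vol$label_names)]
  missing <- name_of[!(name_of %in% names(table))]
  if (length(missing) > 0)
    stop("no conductivity for label(s): ", paste(missing, collapse = ", "))

  lut <- numeric(max(vol$label_names) + 1)  # index by label id + 1; bg -> 0
  for (nm in names(table))
    if (nm %in% names(vol$label_names)) lut[vol$label_names[[nm]] + 1] <- table[[nm]]
  sigma <- array(lut[vol$labels + 1L], dim = dim(vol$labels))

  structure(list(sigma = sigma, labels = vol$labels,
                 label_names = vol$label_names, voxel_mm = vol$voxel_mm,
                 affine = vol$affine, geom = vol$geom, table = table,
                 quincunx = vol$quincunx,
                 quincunx_centers = vol$quincunx_centers,
                 pathology = vol$pathology),
            class = "conductivity_volume")
}

#' @export
print.conductivity_volume <- function(x, ...) {
  cat("Conductivity volume:", paste(dim(x$sigma), collapse = " x "),
      "voxels @", paste(x$voxel_mm, collapse = " x "), "mm\n")
  rng <- range(x$sigma[x$sigma > 0])
  cat(sprintf("  sigma range (conductive): %.3f - %.3f S/m; %d conductive voxels\n",
              rng[1], rng[2], sum(x$sigma > 0)))
  invisible(x)
}

#' Override the conductivity of one tissue label
#'
#' Returns a new conductivity volume in which only voxels carrying the named
#' label have their conductivity replaced; the input is not modified. Used by
#' the uncertainty analysis to re-draw the burr-hole conductivity.
#'
#' @param cv a `conductivity_volume` from [assign_conductivities()].
#' @param label tissue name (e.g. `"burr_hole"`).
#' @param value new conductivity (S/m), must be positive.
#' @return a new `conductivity_volume`.
#' @export
override_conductivity <- function(cv, label, value) {
  stopifnot(inherits(cv, "conductivity_volume"))
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value <= 0)
    stop("conductivity override must be a single positive number")
  if (identical(label, "background"))
    stop("background is not part of the conductive domain")
  if (!label %in% names(cv$label_names))
    stop("unknown tissue label: ", label)
  id <- cv$label_names[[label]]
  out <- cv
  out$sigma[out$labels == id] <- value
  out$table[label] <- value
  out
}
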