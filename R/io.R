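# NIfTI readers/writers and run-configuration plumbing.

#' Write a label volume to NIfTI with a JSON label sidecar
#'
#' Labels are stored as int32; the label-id -> tissue-name table is written
#' next to the image as `<path minus .nii(.gz)>.labels.json`.
#'
#' @param vol a [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- nifti_with_affine(vol$labels, vol$affine, vol$voxel_mm,
                           datatype = "int32")
  RNifti::writeNifti(img, path)
  side <- sidecar_path(path)
  jsonlite::write_json(as.list(vol$label_names), side, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".labels.json")
}

#' Read a label volume from NIfTI
#'
#' Expects integer-valued data and the JSON label sidecar written by
#' [write_label_volume()] (or a user-supplied one mapping tissue names to
#' label ids). Round-trips volumes written by this package bit-exactly, with
#' the affine preserved to better than 1e-6.
#'
#' @param path NIfTI file path.
#' @param label_names optional named integer vector overriding the sidecar.
#' @return a [label_volume()] (without phantom geometry).
#' @export
read_label_volume <- function(path, label_names = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (max(abs(arr - round(arr))) > 0)
    stop("volume contains non-integer data where labels were expected")
  if (is.null(label_names)) {
    side <- sidecar_path(path)
    if (!file.exists(side))
      stop("missing label sidecar ", side,
           " (write one mapping tissue names to label ids, or pass label_names)")
    ln <- jsonlite::read_json(side)
    label_names <- stats::setNames(as.integer(unlist(ln)), names(ln))
  }
  arr <- array(as.integer(round(arr)), dim = pad_dim3(dim(arr)))
  affine <- unname(unclass(RNifti::xform(img)))[1:4, 1:4]
  voxel_mm <- as.numeric(RNifti::pixdim(img))[1:3]
  label_volume(arr, voxel_mm, affine, label_names = label_names)
}

pad_dim3 <- function(d) c(d, rep(1L, max(0, 3 - length(d))))

# Build an RNifti image carrying the affine in both qform and sform.
nifti_with_affine <- function(arr, affine, voxel_mm, datatype) {
  attr(arr, "pixdim") <- as.numeric(voxel_mm)
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Write a numeric field (potential, |E|, enhancement map) to NIfTI
#'
#' @param grid 3-D numeric array.
#' @param path output path.
#' @param affine 4x4 voxel-to-world matrix.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, affine = diag(4)) {
  voxel_mm <- abs(diag(as.matrix(affine))[1:3])
  img <- nifti_with_affine(grid, affine, voxel_mm, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a numeric field volume from NIfTI
#' @param path NIfTI file path.
#' @return list with `grid` (numeric array), `affine`, `voxel_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- array(as.numeric(img), dim = pad_dim3(dim(img)))
  list(grid = grid, affine = unname(unclass(RNifti::xform(img)))[1:4, 1:4],
       voxel_mm = as.numeric(RNifti::pixdim(img))[1:3])
}

# --- Run configuration -----------------------------------------------------

default_config <- function() {
  list(
    current_A = 0.9,
    disc_diameter_mm = 20,
    disc_height_mm = 1,
    array_pitch_mm = c(45, 22),
    hole_diameter_mm = 15,
    quincunx_span_mm = 45,
    uq_interval_Sm = c(0.465, 1.654),
    voxel_mm = 3,
    sr_variant = "over_tumor",
    layout = list(family = "circumferential", parameters = seq(0, 165, 15)),
    solver = list(rtol = 1e-8, maxit = 20000, precond = "sgs",
                  cap_sigma = 500),
    dosimetry = list(peritumoral_margin_mm = 10, pct_floor_Vm = 1),
    uq = list(n_draws = 64, label = "burr_hole"),
    seed = 1L
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Fills unspecified fields with the study defaults (0.9 A drive, 20 mm / 1 mm
#' discs at 45 x 22 mm pitch, 15 mm holes in a 45 mm quincunx, uniform
#' burr-hole conductivity on \[0.465, 1.654\] S/m).
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @param strict if `TRUE` (default) unknown top-level keys are an error;
#'   otherwise they raise a warning and are ignored.
#' @return a named list of class `run_config`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yaml",
#'                                package = "ttdose"))
#' cfg$current_A  # 0.9, the default drive
load_config <- function(path = NULL, strict = TRUE) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
            else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      msg <- paste("unknown configuration keys:", paste(unknown, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      user <- user[setdiff(names(user), unknown)]
    }
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  if (!is.numeric(cfg$current_A) || cfg$current_A <= 0)
    problems <- c(problems, "current_A must be positive")
  if (!is.numeric(cfg$voxel_mm) || any(cfg$voxel_mm <= 0))
    problems <- c(problems, "voxel_mm must be positive")
  if (cfg$hole_diameter_mm <= 0)
    problems <- c(problems, "hole_diameter_mm must be positive")
  if (length(cfg$uq_interval_Sm) != 2 || cfg$uq_interval_Sm[1] <= 0 ||
      diff(cfg$uq_interval_Sm) < 0)
    problems <- c(problems, "uq_interval_Sm must be 0 < lo <= hi")
  if (length(problems) > 0)
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  invisible(cfg)
}

#' Hash a configuration (or any R object) for output manifests
#'
#' MD5 of the canonical serialization; used to trace every artifact back to
#' the configuration that produced it.
#'
#' @param x an R object.
#' @return hex digest string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
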