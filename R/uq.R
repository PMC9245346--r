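# Monte-Carlo uncertainty quantification for the burr-hole conductivity.
#
# The burr-hole fill is granulation tissue / fluid whose conductivity is only
# known to lie somewhere between skin and CSF; it is modeled as uniform on
# [0.465, 1.654] S/m. All other tissue conductivities are held fixed.

#' Specify the conductivity-uncertainty analysis
#'
#' @param n_draws number of Monte-Carlo draws (>= 2; default 64).
#' @param seed integer random seed (mandatory, for reproducibility).
#' @param sigma_lo,sigma_hi endpoints of the uniform conductivity interval
#'   (S/m); defaults 0.465 (skin-like) and 1.654 (CSF).
#' @param label tissue whose conductivity is uncertain (default
#'   `"burr_hole"`).
#' @return object of class `uq_spec`.
#' @export
uq_spec <- function(n_draws = 64, seed, sigma_lo = 0.465, sigma_hi = 1.654,
                    label = "burr_hole") {
  if (missing(seed)) stop("a random seed is required for reproducibility")
  if (!is.numeric(n_draws) || n_draws < 2)
    stop("at least 2 draws are required")
  if (!(sigma_lo > 0) || !(sigma_hi >= sigma_lo))
    stop("need 0 < sigma_lo <= sigma_hi")
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 sigma_lo = sigma_lo, sigma_hi = sigma_hi, label = label),
            class = "uq_spec")
}

#' Monte-Carlo uncertainty of the field intensity
#'
#' Draws the target-label conductivity uniformly from
#' `[sigma_lo, sigma_hi]`, re-solves the conduction problem for each draw,
#' and accumulates the voxelwise mean and sample standard deviation
#' (n-1 denominator) of the field intensity. Deterministic for a fixed seed.
#' Successive solves are warm-started from the previous draw's potential.
#'
#' @param cv a `conductivity_volume` whose labels contain the target label.
#' @param pair an array pair (see [layout_circumferential()]).
#' @param spec a [uq_spec()].
#' @param regions optional `region_set` / named list of masks for per-region
#'   summaries.
#' @param solve_fun the field solver; replaceable by a mock for closed-form
#'   tests. Called as `solve_fun(cv, pair, x0 = <previous phi>, ...)` and must
#'   return an object with `normE` and `phi`.
#' @param ... further arguments passed to `solve_fun` (e.g. `rtol`).
#' @return object of class `uq_result`: `mean` and `sd` (voxelwise 3-D
#'   arrays, V/m), `draws` (the conductivities used), and `summary`
#'   (data.frame with region, mean_Vm, sd_Vm, rel_sd per region, where
#'   `mean_Vm`/`sd_Vm` are region medians of the voxelwise maps and `rel_sd`
#'   is the region median of voxelwise sd/mean).
#' @export
run_uq <- function(cv, pair, spec, regions = NULL, solve_fun = solve_fields,
                   ...) {
  stopifnot(inherits(spec, "uq_spec"))
  if (inherits(cv, "conductivity_volume")) {
    id <- cv$label_names[[spec$label]]
    if (is.null(id) || !any(cv$labels == id))
      stop("target label '", spec$label, "' is absent from the volume")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  draws <- stats::runif(spec$n_draws, spec$sigma_lo, spec$sigma_hi)

  s1 <- NULL; s2 <- NULL; x_prev <- NULL
  for (i in seq_along(draws)) {
    cvi <- override_conductivity(cv, spec$label, draws[i])
    sol <- tryCatch(solve_fun(cvi, pair, x0 = x_prev, ...),
                    error = function(e)
                      stop("solver failed at draw ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    x_prev <- sol$phi
    v <- sol$normE
    if (is.null(s1)) { s1 <- v * 0; s2 <- v * 0 }
    s1 <- s1 + v
    s2 <- s2 + v^2
  }
  n <- spec$n_draws
  m <- s1 / n
  var <- pmax((s2 - n * m^2) / (n - 1), 0)
  sdv <- sqrt(var)

  summary <- NULL
  if (!is.null(regions)) {
    rows <- lapply(names(regions), function(nm) {
      mm <- m[regions[[nm]]]; ss <- sdv[regions[[nm]]]
      ok <- !is.na(mm) & !is.na(ss) & mm > 0
      data.frame(region = nm,
                 mean_Vm = stats::median(mm[ok]),
                 sd_Vm = stats::median(ss[ok]),
                 rel_sd = stats::median(ss[ok] / mm[ok]),
                 n_voxels = sum(ok))
    })
    summary <- do.call(rbind, rows)
  }
  structure(list(mean = m, sd = sdv, draws = draws, spec = spec,
                 summary = summary),
            class = "uq_result")
}

#' @export
print.uq_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo conductivity UQ: %d draws of %s ~ U(%.3f, %.3f) S/m\n",
              x$spec$n_draws, x$spec$label, x$spec$sigma_lo, x$spec$sigma_hi))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
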