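# Quasi-static conduction solve: div(sigma grad phi) = 0 with insulating
# head surface and equipotential array terminals, discretized cell-centered
# finite-volume on the voxel lattice (harmonic-mean face conductances) and
# solved by preconditioned conjugate gradients.

#' Find the scalp voxels in contact with each transducer disc
#'
#' A disc's contact patch is the set of scalp-labeled voxels whose center lies
#' within the disc radius of the disc center (distance measured in the disc
#' plane) and within a fixed 4 mm layer under the scalp surface, so the
#' electrode geometry is independent of the grid resolution.
#'
#' @param cv a `conductivity_volume`.
#' @param arr a `transducer_array`.
#' @return list of integer vectors (linear voxel indices), one per disc.
#' @keywords internal
electrode_voxels <- function(cv, arr) {
  d <- dim(cv$sigma)
  ax <- voxel_axes(cv)
  h <- cv$voxel_mm
  maxh <- max(h)
  r <- arr$disc_diameter_mm / 2
  scalp_id <- cv$label_names[["scalp"]]
  out <- vector("list", 9)
  for (k in 1:9) {
    cc <- arr$centers[k, ]
    nn <- arr$normals[k, ]
    pad <- r + 2 * maxh
    ir <- lapply(1:3, function(a) {
      ax_a <- ax[[a]]
      which(ax_a >= cc[a] - pad & ax_a <= cc[a] + pad)
    })
    if (any(lengths(ir) == 0)) { out[[k]] <- integer(0); next }
    sub <- expand.grid(ix = ir[[1]], iy = ir[[2]], iz = ir[[3]])
    lin <- sub$ix + d[1] * (sub$iy - 1) + d[1] * d[2] * (sub$iz - 1)
    keep <- cv$labels[lin] == scalp_id
    sub <- sub[keep, , drop = FALSE]; lin <- lin[keep]
    if (nrow(sub) == 0) { out[[k]] <- integer(0); next }
    dx <- ax$x[sub$ix] - cc[1]
    dy <- ax$y[sub$iy] - cc[2]
    dz <- ax$z[sub$iz] - cc[3]
    s <- dx * nn[1] + dy * nn[2] + dz * nn[3]
    perp2 <- dx^2 + dy^2 + dz^2 - s^2
    hit <- perp2 <= r^2 & s >= -4 & s <= 2  # mm; resolution-independent patch
    out[[k]] <- lin[hit]
  }
  out
}

# Resolve terminal voxel sets for a pair; drops voxels claimed by both arrays
# (physically overlapping footprints) from both terminals.
terminal_sets <- function(cv, pair, require_all_discs = TRUE) {
  ev1 <- electrode_voxels(cv, pair[[1]])
  ev2 <- electrode_voxels(cv, pair[[2]])
  if (require_all_discs) {
    for (k in 1:9) {
      if (length(ev1[[k]]) == 0)
        stop(sprintf("disc %d of the %s array has no scalp contact",
                     k, pair[[1]]$polarity))
      if (length(ev2[[k]]) == 0)
        stop(sprintf("disc %d of the %s array has no scalp contact",
                     k, pair[[2]]$polarity))
    }
  }
  v1 <- unique(unlist(ev1))
  v2 <- unique(unlist(ev2))
  both <- intersect(v1, v2)
  v1 <- setdiff(v1, both)
  v2 <- setdiff(v2, both)
  if (length(v1) == 0 || length(v2) == 0)
    stop("array footprints overlap completely; no usable terminal voxels")
  src <- if (pair[[1]]$polarity == "source") v1 else v2
  snk <- if (pair[[1]]$polarity == "source") v2 else v1
  list(source = src, sink = snk, dropped = both)
}

#' Solve the conduction problem for an explicit pair of terminal voxel sets
#'
#' Low-level entry point used by [solve_fields()] and by oracle tests (e.g. a
#' homogeneous slab with full-face plate terminals). Solves the finite-volume
#' system with the source set fixed at +1 V and the sink set at -1 V, then
#' rescales the potential so the net injected current equals `current_A`
#' (valid by linearity).
#'
#' @param sigma 3-D array of conductivities (S/m); 0 marks voxels outside the
#'   conductive domain.
#' @param voxel_mm voxel edge lengths (mm), scalar or length-3.
#' @param src_idx,snk_idx linear voxel indices of the source and sink
#'   terminal voxels.
#' @param current_A total injected current (A), default 0.9.
#' @param rtol relative residual tolerance of the conjugate-gradient solve.
#' @param maxit iteration cap.
#' @param precond `"sgs"` (symmetric Gauss-Seidel, default) or `"jacobi"`.
#' @param x0 optional initial guess (3-D array, e.g. a previous solution).
#' @return object of class `field_solution`: `phi` (V), `E` (4-D array,
#'   V/m), `normE` (V/m), `I_injected` (A), `I_balance` (relative source/sink
#'   current mismatch), `iterations`, `relres`.
#' @export
solve_voxel_system <- function(sigma, voxel_mm, src_idx, snk_idx,
                               current_A = 0.9, rtol = 1e-8, maxit = 20000L,
                               precond = c("sgs", "jacobi"), x0 = NULL) {
  precond <- match.arg(precond)
  if (!is.numeric(current_A) || length(current_A) != 1 || current_A <= 0)
    stop("current_A must be a single positive number")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  src_idx <- as.integer(src_idx); snk_idx <- as.integer(snk_idx)
  if (length(src_idx) == 0 || length(snk_idx) == 0)
    stop("both terminals need at least one voxel")
  if (length(intersect(src_idx, snk_idx)) > 0)
    stop("a voxel cannot belong to both terminals")

  fixed_idx <- c(src_idx, snk_idx)
  fixed_val <- c(rep(1, length(src_idx)), rep(-1, length(snk_idx)))
  terminal <- c(rep(1L, length(src_idx)), rep(2L, length(snk_idx)))
  res <- fv_solve_cpp(sigma, voxel_mm, fixed_idx, fixed_val, terminal,
                      rtol, as.integer(maxit),
                      if (precond == "sgs") 1L else 0L, x0)
  if (!res$converged)
    stop(sprintf(
      "conduction solve did not converge: relative residual %.3e after %d iterations",
      res$relres, res$iterations))

  I_src <- res$I_src_raw * 1e-3   # face conductances are in S*mm^2/(m*mm)
  I_snk <- res$I_snk_raw * 1e-3
  if (I_src <= 0) stop("realized source current is non-positive; check terminals")
  alpha <- current_A / I_src
  phi <- res$phi * alpha
  grad <- phi_gradient(phi, voxel_mm)
  normE <- sqrt(grad[, , , 1]^2 + grad[, , , 2]^2 + grad[, , , 3]^2)

  structure(list(phi = phi, E = -grad, normE = normE,
                 I_injected = current_A,
                 I_balance = abs(I_src + I_snk) / abs(I_src),
                 iterations = res$iterations, relres = res$relres,
                 voxel_mm = voxel_mm,
                 terminals = list(source = src_idx, sink = snk_idx)),
            class = "field_solution")
}

# Discrete gradient of the potential (V/m): central differences where both
# neighbors are in the conductive domain, one-sided at domain boundaries,
# NA outside the domain.
phi_gradient <- function(phi, voxel_mm) {
  d <- dim(phi)
  grad <- array(NA_real_, dim = c(d, 3))
  for (axis in 1:3) {
    hp <- shift_arr(phi, axis, -1)  # value at i+1
    hm <- shift_arr(phi, axis, +1)  # value at i-1
    g <- array(NA_real_, dim = d)
    both <- !is.na(hp) & !is.na(hm)
    only_p <- !is.na(hp) & is.na(hm)
    only_m <- is.na(hp) & !is.na(hm)
    none <- is.na(hp) & is.na(hm)
    g[both] <- (hp[both] - hm[both]) / (2 * voxel_mm[axis])
    g[only_p] <- (hp[only_p] - phi[only_p]) / voxel_mm[axis]
    g[only_m] <- (phi[only_m] - hm[only_m]) / voxel_mm[axis]
    g[none] <- 0
    g[is.na(phi)] <- NA_real_
    grad[, , , axis] <- g * 1000  # V/mm -> V/m
  }
  grad
}

# Shift a 3-D array along an axis by +1/-1 voxel, filling with NA.
shift_arr <- function(a, axis, by) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) {        # out[i] = a[i - by]
    idx_dst[[axis]] <- (by + 1):d[axis]
    idx_src[[axis]] <- 1:(d[axis] - by)
  } else {             # out[i] = a[i + |by|]
    idx_dst[[axis]] <- 1:(d[axis] + by)
    idx_src[[axis]] <- (1 - by):d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Solve the TTFields conduction problem for an array pair
#'
#' Rasterizes the transducer contact patches onto the scalp, fixes each
#' array's nine discs to a common ideal terminal (complete-electrode-style
#' contract; contact voxels get the cap conductivity `cap_sigma`), solves the
#' finite-volume system and scales the solution to the requested total
#' current.
#'
#' @param cv a `conductivity_volume` from [assign_conductivities()].
#' @param pair an array pair from [layout_circumferential()],
#'   [layout_normal_rotation()] or [layout_vertex_translation()].
#' @param current_A total baseline-to-peak current per pair (A), default 0.9.
#' @param cap_sigma conductivity assigned to electrode contact voxels (S/m).
#' @inheritParams solve_voxel_system
#' @return a `field_solution` (see [solve_voxel_system()]); additionally
#'   carries the layout attributes of `pair`.
#' @export
#' @examples
#' \donttest{
#' vol <- build_study_phantom(voxel_mm = 3, sr_variant = "over_tumor")
#' cv <- assign_conductivities(vol)
#' pair <- layout_circumferential(vol$geom, 60)
#' sol <- solve_fields(cv, pair)
#' median(sol$normE[vol$labels == TISSUE_LABELS[["residual_tumor"]]])
#' }
solve_fields <- function(cv, pair, current_A = 0.9, cap_sigma = 500,
                         rtol = 1e-8, maxit = 20000L,
                         precond = c("sgs", "jacobi"), x0 = NULL) {
  stopifnot(inherits(cv, "conductivity_volume"))
  precond <- match.arg(precond)
  ts <- terminal_sets(cv, pair)
  sigma <- cv$sigma
  sigma[c(ts$source, ts$sink)] <- cap_sigma
  sol <- solve_voxel_system(sigma, cv$voxel_mm, ts$source, ts$sink,
                            current_A = current_A, rtol = rtol,
                            maxit = maxit, precond = precond, x0 = x0)
  sol$layout <- attr(pair, "layout")
  sol$affine <- cv$affine
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Field solution: %s voxels, I = %.3g A, %d CG iterations (relres %.1e)\n",
              paste(dim(x$phi), collapse = " x "), x$I_injected,
              x$iterations, x$relres))
  cat(sprintf("  |E| median (conductive): %.1f V/m\n",
              stats::median(x$normE, na.rm = TRUE)))
  invisible(x)
}

#' Assemble the finite-volume linear system explicitly
#'
#' Exports the symmetric positive-definite system solved by
#' [solve_voxel_system()] as a sparse matrix, for inspection and for
#' cross-checking the matrix-free solver against a direct solve on small
#' grids. Requires the Matrix package.
#'
#' @inheritParams solve_voxel_system
#' @return list with `A` (sparse dgCMatrix over free voxels), `b` (right-hand
#'   side from the Dirichlet terminals), and `voxel` (linear voxel index of
#'   each equation).
#' @export
assemble_system <- function(sigma, voxel_mm, src_idx, snk_idx) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("assemble_system requires the Matrix package")
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  fixed_idx <- as.integer(c(src_idx, snk_idx))
  fixed_val <- c(rep(1, length(src_idx)), rep(-1, length(snk_idx)))
  tri <- fv_system_cpp(sigma, voxel_mm, fixed_idx, fixed_val)
  A <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(tri$n_free, tri$n_free))
  list(A = A, b = tri$b, voxel = tri$voxel)
}

#' Field intensity restricted to a mask
#'
#' Returns the Euclidean norm of the field vector (the TTFields dose metric)
#' on the voxels selected by `mask`, with no interpolation.
#'
#' @param sol a `field_solution`.
#' @param mask logical 3-D array on the same lattice as the solution.
#' @return numeric vector of |E| values (V/m) at the masked voxels.
#' @export
field_intensity <- function(sol, mask) {
  stopifnot(inherits(sol, "field_solution"))
  if (!identical(dim(mask), dim(sol$normE)))
    stop("mask lattice does not match the field solution")
  sol$normE[mask]
}
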