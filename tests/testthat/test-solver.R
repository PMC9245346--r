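# Slab/box fixtures: full-face plate terminals along x.
slab_terminals <- function(dims) {
  list(src = which(slice.index(array(0, dims), 1) == 1),
       snk = which(slice.index(array(0, dims), 1) == dims[1]))
}

test_that("a homogeneous slab reproduces |E| = I / (sigma A) and a linear ramp", {
  n <- 16; h <- 2; sig <- 0.5
  sigma <- array(sig, dim = c(n, n, n))
  tm <- slab_terminals(dim(sigma))
  sol <- solve_voxel_system(sigma, h, tm$src, tm$snk, current_A = 0.9,
                            rtol = 1e-10)
  A_m2 <- (n * h)^2 * 1e-6
  expected <- 0.9 / (sig * A_m2)
  interior <- sol$normE[3:(n - 2), 3:(n - 2), 3:(n - 2)]
  expect_equal(max(abs(interior - expected)) / expected, 0, tolerance = 0.01)
  # potential is a linear ramp along x
  phi_line <- sol$phi[, n %/% 2, n %/% 2]
  fit <- stats::lm(phi_line ~ seq_len(n))
  expect_lt(max(abs(stats::residuals(fit))), 1e-6 * diff(range(phi_line)))
})

test_that("anisotropic voxels carry the correct face areas", {
  # 30 mm cube sampled with 1 x 2 x 2 mm voxels
  dims <- c(30, 15, 15); h <- c(1, 2, 2); sig <- 0.5
  sigma <- array(sig, dim = dims)
  tm <- slab_terminals(dims)
  sol <- solve_voxel_system(sigma, h, tm$src, tm$snk, current_A = 0.9,
                            rtol = 1e-10)
  expected <- 0.9 / (sig * 30 * 30 * 1e-6)
  interior <- sol$normE[5:26, 4:12, 4:12]
  expect_equal(max(abs(interior - expected)) / expected, 0, tolerance = 0.01)
})

test_that("current scaling is exact and polarity swap negates the potential", {
  sigma <- array(1, dim = c(10, 10, 10))
  tm <- slab_terminals(dim(sigma))
  s1 <- solve_voxel_system(sigma, 2, tm$src, tm$snk, current_A = 0.9)
  s2 <- solve_voxel_system(sigma, 2, tm$src, tm$snk, current_A = 1.8)
  expect_identical(s2$phi, 2 * s1$phi)          # post-solve linear scaling
  expect_identical(s2$normE, 2 * s1$normE)
  # polarity swap negates phi up to the solve tolerance (the realized
  # terminal current used for rescaling is recomputed on the swapped set)
  s3 <- solve_voxel_system(sigma, 2, tm$snk, tm$src, current_A = 0.9)
  expect_equal(s3$phi, -s1$phi, tolerance = 1e-6)
  expect_equal(s3$normE, s1$normE, tolerance = 1e-6)
  expect_error(solve_voxel_system(sigma, 2, tm$src, tm$snk, current_A = -1),
               "positive")
  expect_error(solve_voxel_system(sigma, 2, tm$src, tm$src, current_A = 1),
               "both terminals")
})

test_that("source and sink currents balance on the head phantom", {
  cv <- assign_conductivities(coarse_phantom())
  pair <- layout_circumferential(coarse_geom(), 60)
  sol <- solve_fields(cv, pair, rtol = 1e-10)
  expect_lt(sol$I_balance, 1e-6)
  expect_equal(sol$I_injected, 0.9)
})

test_that("reciprocity: exchanging source and sink leaves |E| unchanged", {
  cv <- assign_conductivities(coarse_phantom())
  pair <- layout_circumferential(coarse_geom(), 60)
  sol <- solve_fields(cv, pair, rtol = 1e-10)
  rev_pair <- pair
  rev_pair$ipsi$polarity <- "sink"
  rev_pair$contra$polarity <- "source"
  sol_r <- solve_fields(cv, rev_pair, rtol = 1e-10)
  expect_equal(sol_r$normE, sol$normE, tolerance = 1e-8)
  expect_equal(sol_r$phi, -sol$phi, tolerance = 1e-8)
})

test_that("the assembled system is symmetric, conservative, and matches a direct solve", {
  skip_if_not_installed("Matrix")
  set.seed(7)
  dims <- c(9, 8, 7)
  sigma <- array(sample(c(0.1, 1.5), prod(dims), replace = TRUE), dim = dims)
  tm <- slab_terminals(dims)
  sys <- assemble_system(sigma, 2, tm$src, tm$snk)
  expect_equal(Matrix::norm(sys$A - Matrix::t(sys$A), "M"), 0)
  # interior rows (no Dirichlet neighbor contributes to b) sum to zero
  rs <- Matrix::rowSums(sys$A)
  interior <- sys$b == 0
  expect_lt(max(abs(rs[interior])), 1e-10)
  phi_direct <- as.numeric(Matrix::solve(sys$A, sys$b))
  sol <- solve_voxel_system(sigma, 2, tm$src, tm$snk, rtol = 1e-12)
  expect_equal(sol$phi[sys$voxel] * (1 / sol$phi[tm$src[1]]),
               phi_direct, tolerance = 1e-8)
})

test_that("the solution is invariant under a rigid rotation of the whole problem", {
  build_case <- function(axes, azimuth) {
    geom <- head_geometry(axes, scalp_mm = 6, skull_mm = 7, csf_mm = 4,
                          gm_mm = 5)
    vol <- build_head_phantom(geom, 4)
    vol <- insert_pathology(vol, pathology_spec(geom, azimuth_deg = azimuth))
    vol <- apply_sr_surgery(vol, place_quincunx(vol, "over_tumor"))
    solve_fields(assign_conductivities(vol),
                 layout_circumferential(geom, azimuth))
  }
  solA <- build_case(c(80, 95, 88), 60)
  solB <- build_case(c(95, 80, 88), 150)  # whole problem rotated 90 deg
  dA <- dim(solA$normE)
  # world (x,y,z) -> (y, -x, z): B[iy, nxA+1-ix, iz] corresponds to A[ix,iy,iz]
  mapped <- aperm(solA$normE, c(2, 1, 3))[, dA[1]:1, ]
  ok <- !is.na(mapped) & !is.na(solB$normE)
  expect_gt(mean(ok), 0.2)
  scale <- stats::median(solA$normE, na.rm = TRUE)
  expect_lt(max(abs(mapped[ok] - solB$normE[ok])) / scale, 0.02)
})

test_that("a layered spherical conductor converges under grid refinement", {
  geom <- head_geometry(c(60, 60, 60), scalp_mm = 8, skull_mm = 8,
                        csf_mm = 6, gm_mm = 6)
  med_wm <- sapply(c(4, 2, 1), function(vx) {
    vol <- build_head_phantom(geom, vx)
    cv <- assign_conductivities(vol)
    pair <- layout_circumferential(geom, 0, ring_z_mm = 15)
    sol <- solve_fields(cv, pair)
    stats::median(sol$normE[vol$labels == TISSUE_LABELS[["wm"]]])
  })
  d42 <- abs(med_wm[1] - med_wm[2])
  d21 <- abs(med_wm[2] - med_wm[3])
  expect_lt(d21, 0.6 * d42)               # refinement error contracts
  expect_lt(d21 / med_wm[3], 0.10)        # one refinement agrees within 10%
})

test_that("field_intensity restricts the norm to a matching mask", {
  fake <- structure(list(normE = array(sqrt(3^2 + 4^2), dim = c(2, 2, 2))),
                    class = "field_solution")
  mask <- array(FALSE, dim = c(2, 2, 2)); mask[1, 1, 1] <- TRUE
  expect_equal(field_intensity(fake, mask), 5)
  expect_length(field_intensity(fake, array(FALSE, dim = c(2, 2, 2))), 0)
  expect_error(field_intensity(fake, array(TRUE, dim = c(3, 2, 2))), "lattice")
})

test_that("non-convergence fails loudly with diagnostics", {
  sigma <- array(1, dim = c(12, 12, 12))
  tm <- slab_terminals(dim(sigma))
  expect_error(solve_voxel_system(sigma, 2, tm$src, tm$snk, maxit = 2L),
               "did not converge")
})

test_that("discs without scalp contact are rejected by name", {
  cv <- assign_conductivities(coarse_phantom())
  pair <- layout_circumferential(coarse_geom(), 60)
  # push one disc far off the head
  pair$ipsi$centers[5, ] <- c(500, 500, 500)
  expect_error(solve_fields(cv, pair), "disc 5")
})
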