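# A mock solver whose field responds linearly to the drawn conductivity lets
# the Monte-Carlo moments be checked against the closed-form SD of a uniform
# variable: sd(a + b*sigma) = b * (hi - lo) / sqrt(12).

mock_linear_solver <- function(a = 10, b = 40) {
  function(cv, pair, x0 = NULL, ...) {
    sig <- cv$table[["burr_hole"]]
    structure(list(normE = array(a + b * sig, dim = c(2, 2, 2)), phi = NULL),
              class = "field_solution")
  }
}

test_that("Monte-Carlo moments recover the uniform closed form", {
  base <- coarse_phantom()
  vol <- apply_sr_surgery(base, place_quincunx(base, "over_tumor"))
  cv <- assign_conductivities(vol)
  spec <- uq_spec(n_draws = 4096, seed = 11)
  res <- run_uq(cv, pair = NULL, spec, solve_fun = mock_linear_solver())
  b <- 40; lo <- 0.465; hi <- 1.654
  sd_exact <- b * (hi - lo) / sqrt(12)
  mean_exact <- 10 + b * (lo + hi) / 2
  expect_equal(res$sd[1, 1, 1], sd_exact, tolerance = 0.05)
  expect_equal(res$mean[1, 1, 1], mean_exact, tolerance = 0.01)
})

test_that("a degenerate interval has zero variance", {
  base <- coarse_phantom()
  vol <- apply_sr_surgery(base, place_quincunx(base, "over_tumor"))
  cv <- assign_conductivities(vol)
  spec <- uq_spec(n_draws = 8, seed = 3, sigma_lo = 1.0, sigma_hi = 1.0)
  res <- run_uq(cv, pair = NULL, spec, solve_fun = mock_linear_solver())
  expect_true(all(res$sd == 0))
})

test_that("runs with the same seed are bit-identical", {
  base <- coarse_phantom()
  vol <- apply_sr_surgery(base, place_quincunx(base, "over_tumor"))
  cv <- assign_conductivities(vol)
  spec <- uq_spec(n_draws = 16, seed = 99)
  r1 <- run_uq(cv, pair = NULL, spec, solve_fun = mock_linear_solver())
  r2 <- run_uq(cv, pair = NULL, spec, solve_fun = mock_linear_solver())
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$sd, r2$sd)
  # draws stay inside the declared interval
  expect_true(all(r1$draws >= 0.465 & r1$draws <= 1.654))
})

test_that("invalid specifications are rejected", {
  expect_error(uq_spec(n_draws = 1, seed = 1), "2 draws")
  expect_error(uq_spec(seed = 1, sigma_lo = -1), "sigma_lo")
  expect_error(uq_spec(n_draws = 4), "seed")
  base <- coarse_phantom()
  cv <- assign_conductivities(base)  # no burr holes present
  expect_error(run_uq(cv, NULL, uq_spec(n_draws = 4, seed = 1),
                      solve_fun = mock_linear_solver()), "absent")
})

test_that("solver failures abort carrying the draw index", {
  base <- coarse_phantom()
  vol <- apply_sr_surgery(base, place_quincunx(base, "over_tumor"))
  cv <- assign_conductivities(vol)
  boom <- function(cv, pair, x0 = NULL, ...) stop("numerical blow-up")
  expect_error(run_uq(cv, NULL, uq_spec(n_draws = 4, seed = 5),
                      solve_fun = boom), "draw 1")
})
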