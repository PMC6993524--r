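test_that("theoretical BD is linear in G+C with the expected endpoints", {
  expect_equal(theoretical_bd(0), 1.66)
  expect_equal(theoretical_bd(0.5), 1.709)
  expect_equal(theoretical_bd(1), 1.758)
  gc <- seq(0, 1, length.out = 101)
  bd <- theoretical_bd(gc)
  expect_true(all(diff(bd) > 0))
  expect_equal(range(bd), c(1.66, 1.758))
  expect_error(theoretical_bd(1.2), "\\[0, 1\\]")
  expect_error(theoretical_bd(-0.1), "\\[0, 1\\]")
})

test_that("isotope shift adds atom excess times the per-isotope delta", {
  expect_equal(labeled_bd(1.709, 0, "13C"), 1.709)
  expect_equal(labeled_bd(1.709, 1, "13C"), 1.745)
  expect_equal(labeled_bd(1.70, 1, "15N"), 1.716)
  expect_equal(labeled_bd(1.72, 0.5, "13C"), 1.72 + 0.018)
  expect_error(labeled_bd(1.7, 1, "2H"), "unknown isotope")
  expect_error(labeled_bd(1.7, 1.5, "13C"), "\\[0, 1\\]")
})

test_that("diffusion sigma matches a literal evaluation of the formula", {
  gp <- gradient_params(temperature = 293.15)
  # independent single-line oracle, typed from the model definition
  oracle <- sqrt(1.709 * 8.314 * 293.15 /
                   (1.14e9^2 * 7.87e-10 * 882 * 10000))
  expect_equal(diffusion_sigma(1.709, 10000, gp), oracle, tolerance = 1e-12)
})

test_that("diffusion sigma scales as 1/sqrt(length) and increases with T", {
  gp <- default_params
  set.seed(11)
  rho <- runif(100, 1.66, 1.80)
  l <- runif(100, 500, 50000)
  expect_equal(diffusion_sigma(rho, l, gp) / diffusion_sigma(rho, 4 * l, gp),
               rep(2, 100), tolerance = 1e-12)
  hot <- gradient_params(temperature = 310)
  expect_true(all(diffusion_sigma(rho, l, hot) > diffusion_sigma(rho, l, gp)))
  expect_error(diffusion_sigma(1.7, 0, gp), ">= 1")
})

test_that("isoconcentration point sits between the mean radius and r_max", {
  expect_equal(isoconcentration_point(1, 2), sqrt(7 / 3))
  expect_equal(isoconcentration_point(3, 3), 3)
  # numeric sweep oracle: I >= arithmetic midpoint, and I within [r_min, r_max]
  grid <- expand.grid(r1 = seq(1, 5, by = 0.5), r2 = seq(1, 5, by = 0.5))
  grid <- grid[grid$r1 < grid$r2, ]
  I <- isoconcentration_point(grid$r1, grid$r2)
  expect_true(all(I >= (grid$r1 + grid$r2) / 2))
  expect_true(all(I >= grid$r1 & I <= grid$r2))
  expect_error(isoconcentration_point(-1, 2), "> 0")
})

test_that("equilibrium position inverts exactly through the model gradient", {
  gp <- default_params
  expect_equal(equilibrium_position(gp$avg_density, gp), gp$isoconcentration)
  expect_equal(position_to_bd(gp$isoconcentration, gp), gp$avg_density)
  set.seed(5)
  rho <- runif(1000, 1.66, 1.80)
  x <- equilibrium_position(rho, gp)
  expect_true(all(diff(equilibrium_position(sort(rho), gp)) > 0))
  expect_lt(max(abs(position_to_bd(x, gp) - rho)), 1e-9)
  expect_error(equilibrium_position(1.0, gp), "out of gradient")
})

test_that("tabulated model gradient agrees with the analytic mapping", {
  gp <- default_params
  tab <- model_gradient_table(gp, step = 1e-3)
  at <- seq(gp$r_min, gp$r_max, length.out = 57)
  interp <- stats::approx(tab$position, tab$bd, xout = at)$y
  expect_equal(interp, position_to_bd(at, gp), tolerance = 1e-6)
})

test_that("DBL tube positions shift down-tube as density rises and formulas join continuously", {
  gp <- default_params
  rho <- seq(1.66, 1.80, length.out = 200)
  x <- equilibrium_position(rho, gp)
  rng <- lapply(x, dbl_position_range, params = gp)
  x_min <- vapply(rng, `[[`, 0, "x_min")
  x_max <- vapply(rng, `[[`, 0, "x_max")
  expect_true(all(x_max - x_min > 0))
  # denser fragments band closer to the tube bottom: positions non-increasing
  expect_true(all(diff(x_max) < 1e-12))
  cyl <- x <= gp$r_max - gp$tube_radius * (1 + cos(gp$tube_angle))
  expect_true(all(diff(x_min[cyl]) < 1e-12))
  # cylindrical vs rounded-bottom formulas agree at their junction radii
  rt <- gp$tube_radius; th <- gp$tube_angle; rmax <- gp$r_max
  x_lo <- rmax - rt * (1 + cos(th))
  u <- (x_lo - rmax + rt) / rt
  expect_equal(rt + (rmax - rt * cos(th) - rt - x_lo) / sin(th),
               rt - rt * cos(th - asin(u)), tolerance = 1e-6)
  x_hi <- rmax - rt * (1 - cos(th))
  u <- (x_hi - rmax + rt) / rt
  expect_equal(rt + (rmax + rt * cos(th) - rt - x_hi) / sin(th),
               rt - rt * cos(th - pi + asin(u)), tolerance = 1e-6)
  expect_error(dbl_position_range(gp$r_max + 1, gp), "outside the tube")
})

test_that("DBL buoyant-density range brackets the fragment density", {
  gp <- default_params
  set.seed(9)
  rho <- runif(300, 1.66, 1.78)
  for (r in rho) {
    d <- dbl_position_range(equilibrium_position(r, gp), gp)
    expect_lt(d$rho_dbl_min, r)
    expect_gt(d$rho_dbl_max, r)
  }
})

test_that("gradient parameter validation rejects broken geometry", {
  expect_error(gradient_params(r_min = 5, r_max = 4), "r_min < r_max")
  expect_error(gradient_params(tube_angle = 2), "tube_angle")
  expect_error(gradient_params(avg_density = 0.9), "avg_density")
  expect_error(bd_window(1.77, 1.72), "rho_min")
  expect_error(fraction_set(c(1.7, 1.7)), "strictly increasing")
})
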