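# Rotation kinematics, cylinder strain, gape-limit detection, clearance.

test_that("rotate_about_axis matches a quaternion oracle", {
  expect_equal(rotate_about_axis(c(1, 2, 3), c(0, 0, 0), c(0, 0, 1), 0),
               c(1, 2, 3))
  # a point on the axis never moves
  expect_equal(rotate_about_axis(c(2, 2, 2), c(1, 1, 1), c(3, 3, 3), 123.4),
               c(2, 2, 2), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    p <- rnorm(3, sd = 10); a <- rnorm(3); b <- a + rnorm(3)
    th <- runif(1, -360, 360)
    expect_equal(rotate_about_axis(p, a, b, th),
                 quaternion_rotate(p, a, b, th), tolerance = 1e-9)
  }
  expect_error(rotate_about_axis(c(1, 0, 0), c(1, 1, 1), c(1, 1, 1), 10),
               "degenerate")
})

test_that("rotation preserves distances between mandible-fixed points", {
  set.seed(8)
  for (i in 1:20) {
    p <- rnorm(3, sd = 30); q <- rnorm(3, sd = 30)
    a <- rnorm(3); b <- a + rnorm(3); th <- runif(1, 0, 90)
    d0 <- sqrt(sum((p - q)^2))
    d1 <- sqrt(sum((rotate_about_axis(p, a, b, th) -
                      rotate_about_axis(q, a, b, th))^2))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("planar strain follows the law-of-cosines closed form", {
  r_o <- 30; r_i <- 20; phi0 <- 60; rest <- 5
  m <- make_planar_gape_model(r_o, r_i, phi0, resting_gape = rest)
  l0 <- sqrt(r_o^2 + r_i^2 - 2 * r_o * r_i * cos(phi0 * pi / 180))
  for (th in seq(rest, 80, by = 2.5)) {
    closed <- sqrt(r_o^2 + r_i^2 -
                     2 * r_o * r_i * cos((phi0 + th - rest) * pi / 180)) / l0
    expect_equal(unname(cylinder_strain(m, th)), closed, tolerance = 1e-9)
  }
  expect_equal(unname(cylinder_strain(m, rest)), 1)
  # equilateral configuration: resting length equals the radius
  me <- make_planar_gape_model(10, 10, 60, resting_gape = 5)
  cyl <- me$adductors[[1]]
  expect_equal(sqrt(sum((cyl$origin - cyl$insertion)^2)), 10,
               tolerance = 1e-12)
})

test_that("strain is monotone in gape for randomized planar adductors", {
  set.seed(9)
  for (i in 1:25) {
    m <- make_planar_gape_model(runif(1, 10, 50), runif(1, 10, 50),
                                runif(1, 20, 120), resting_gape = 5)
    s <- vapply(seq(5, 60, by = 0.5), function(th)
      unname(cylinder_strain(m, th)), numeric(1))
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("gape limits agree with the analytic inversion on a planar jaw", {
  r_o <- 30; r_i <- 20; phi0 <- 60; rest <- 5; step <- 0.5
  m <- make_planar_gape_model(r_o, r_i, phi0, rest, step)
  g <- find_gape_limits(m)
  for (lim in c(opt = 1.3, max = 1.7)) {
    exact <- planar_strain_crossing(r_o, r_i, phi0, lim, rest)
    grid <- rest + step * ceiling((exact - rest) / step)
    got <- if (lim == 1.3) g$theta_optimal else g$theta_maximum
    expect_equal(got, grid)
  }
  expect_identical(g$constraining_cylinder_opt, "adductor1")
  expect_true(g$theta_maximum >= g$theta_optimal)
})

test_that("limit edge cases: immediate crossing, no crossing, tie reporting", {
  m <- make_planar_gape_model(30, 20, 60)
  # optimal limit of 1 + eps crosses at the first step past resting
  g0 <- find_gape_limits(m, strain_limits(optimal = 1 + 1e-12, maximum = 1.7))
  expect_equal(g0$theta_optimal, m$resting_gape + m$step)
  # strain at resting gape is exactly 1 for every adductor
  expect_equal(unname(cylinder_strain(m, m$resting_gape)), 1)
  # unreachable maximum -> open-ended with a warning
  expect_warning(
    gx <- find_gape_limits(m, strain_limits(optimal = 1.3, maximum = 60)),
    "open-ended")
  expect_true(gx$open_ended)
  expect_true(is.na(gx$theta_maximum))
  # two identical cylinders cross together and are both reported, sorted
  cyl1 <- muscle_cylinder("b2", c(20, 0, 25), c(22, 0, 0))
  cyl2 <- muscle_cylinder("a1", c(20, 0, 25), c(22, 0, 0))
  mm <- jaw_model(c(0, -5, 0), c(0, 5, 0), list(cyl1, cyl2))
  gt <- find_gape_limits(mm)
  expect_identical(gt$constraining_cylinder_opt, c("a1", "b2"))
})

test_that("halving the step never shifts a limit by more than the coarse step", {
  set.seed(10)
  n_ok <- 0
  while (n_ok < 10) {
    r_o <- runif(1, 15, 45); r_i <- runif(1, 15, 45)
    phi0 <- runif(1, 30, 100)
    if (is.na(planar_strain_crossing(r_o, r_i, phi0, 1.7))) next
    n_ok <- n_ok + 1
    coarse <- find_gape_limits(make_planar_gape_model(r_o, r_i, phi0,
                                                      step = 1))
    fine <- find_gape_limits(make_planar_gape_model(r_o, r_i, phi0,
                                                    step = 0.5))
    expect_lte(abs(coarse$theta_optimal - fine$theta_optimal), 1)
    expect_lte(abs(coarse$theta_maximum - fine$theta_maximum), 1)
  }
})

test_that("the depressor shortens on opening and is reported post hoc", {
  tx <- make_taxon(synthetic_taxon_spec(seed = 4))
  s_rest <- cylinder_strain(tx$model, tx$model$resting_gape)
  s_open <- cylinder_strain(tx$model, 30)
  expect_lt(s_open[["mDM"]], 1)           # retroarticular insertion
  expect_equal(unname(s_rest), rep(1, length(s_rest)))
  g <- find_gape_limits(tx$model)
  expect_false("mDM" %in% c(g$constraining_cylinder_opt,
                            g$constraining_cylinder_max))
  # elongation factors measured back from the shortest (max gape) state
  expect_gte(g$depressor_factors[["resting"]], g$depressor_factors[["optimal"]])
  expect_gte(g$depressor_factors[["optimal"]], 1)
})

test_that("opening sense is auto-detected and degenerate geometry flagged", {
  # build a model whose coordinates are mirrored so opening is sense -1
  cyl <- muscle_cylinder("m1", c(-20, 0, 25), c(-22, 0, 0))
  m <- jaw_model(c(0, -5, 0), c(0, 5, 0), list(cyl))
  expect_identical(abs(m$sense), 1)
  g <- find_gape_limits(m)
  expect_false(g$open_ended)
  expect_warning(mp <- make_planar_gape_model(10, 10, 180),
                 "not an adductor")
  expect_true(isTRUE(attr(mp, "non_adductor")))
})

test_that("jaw clearance follows the chord law and grows with gape", {
  m <- make_planar_gape_model(30, 20, 60, resting_gape = 0)
  r <- 25
  bp <- c(r, 0, 0)
  expect_equal(jaw_clearance(m, 0, bp, bp), 0)
  for (th in c(10, 25, 40, 90))
    expect_equal(jaw_clearance(m, th, bp, bp),
                 2 * r * sin(th / 2 * pi / 180), tolerance = 1e-9)
  cl <- vapply(seq(0, 90, by = 5), function(th)
    jaw_clearance(m, th, bp, bp), numeric(1))
  expect_true(all(diff(cl) > 0))
})
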