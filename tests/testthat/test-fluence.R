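mach <- machine()

test_that("layer map has the open / blocked / stacked transmission levels", {
  p <- mlc_parameters()   # T = 0.0047 per layer
  g <- fluence_grid(c(-7, 7), c(-7, 7), 0.1)
  ap <- rect_field_aperture(mach, -5, 5, -5, 5)
  fp <- layer_transmission_map(ap$proximal, p, mach, g, "proximal")
  iy <- which(abs(fp$y) < 1e-9); ix <- which(abs(fp$x) < 1e-9)
  expect_equal(fp$values[iy, ix], 1)
  expect_equal(fp$values[1, 1], 0.0047)

  # combined: open*open = 1, closed*closed = product, open*closed = T
  fd <- layer_transmission_map(ap$distal, p, mach, g, "distal")
  fc <- combined_fluence(fp, fd)
  expect_equal(fc$values[iy, ix], 1)
  expect_equal(fc$values[1, 1], 2.209e-5)
  half <- layer_transmission_map(ap$proximal, p, mach, g, "proximal")
  open_map <- half; open_map$values[] <- 1
  expect_equal(combined_fluence(open_map, fd)$values[1, 1], 0.0047)

  g2 <- fluence_grid(c(-6, 6), c(-6, 6), 0.1)
  other <- layer_transmission_map(ap$distal, p, mach, g2, "distal")
  expect_error(combined_fluence(fp, other), "grids")
})

test_that("tip zone transmits sqrt(T) as a half-height leaf", {
  p <- mlc_parameters(tip_width = 0.1)
  # fine grid so a pixel sits fully inside the 0.1 cm tip strip
  g <- fluence_grid(c(4.5, 5.6), c(-1, 1), 0.02)
  ap <- rect_field_aperture(mach, -5, 5, -2, 2)
  fp <- layer_transmission_map(ap$proximal, p, mach, g, "proximal")
  iy <- which(abs(fp$y) < 1e-9)
  # tip strip sits on the leaf side of the tip: [5.0, 5.1]
  ix <- which.min(abs(fp$x - 5.05))
  expect_equal(fp$values[iy, ix], sqrt(0.0047), tolerance = 1e-6)
  expect_equal(sqrt(0.0047), 0.0686, tolerance = 1e-3)
  ix_deep <- which.min(abs(fp$x - 5.4))
  expect_equal(fp$values[iy, ix_deep], 0.0047)
})

test_that("values stay within [stacked transmission, 1] and maps are symmetric", {
  p <- mlc_parameters(offset = 0.01)
  g <- fluence_grid(c(-7, 7), c(-7, 7), 0.1)
  ap <- rect_field_aperture(mach, -4, 4, -4, 4)
  fc <- dual_layer_fluence(ap, p, mach, g)
  expect_true(all(fc$values >= 2.209e-5 - 1e-12))
  expect_true(all(fc$values <= 1 + 1e-12))
  # mirror symmetry about x = 0 for a symmetric aperture, gain = curv = 0
  expect_equal(fc$values, fc$values[, rev(seq_along(fc$x))],
               tolerance = 1e-12)
})

test_that("enlarging an aperture never decreases fluence", {
  p <- mlc_parameters(tip_width = 0.05)
  g <- fluence_grid(c(-6, 6), c(-6, 6), 0.1)
  set.seed(5)
  for (i in 1:5) {
    x1 <- stats::runif(1, -4, -1); x2 <- stats::runif(1, 1, 4)
    y1 <- stats::runif(1, -4, -1); y2 <- stats::runif(1, 1, 4)
    small <- dual_layer_fluence(rect_field_aperture(mach, x1, x2, y1, y2),
                                p, mach, g)
    big <- dual_layer_fluence(
      rect_field_aperture(mach, x1 - 0.7, x2 + 0.4, y1 - 1, y2 + 0.5),
      p, mach, g)
    expect_true(all(big$values - small$values >= -1e-9))
  }
})

test_that("complementary bar patterns sum to uniform away from T&G strips", {
  p0 <- mlc_parameters(tng_width = 0)
  g <- fluence_grid(c(-1, 1), c(-4.6, 4.6), 0.05)
  bars <- dualmlc:::.bar_apertures(mach, "proximal")
  open_d <- rect_field_aperture(mach, -4.5, 4.5, -4.7, 4.7)$distal
  f_a <- dual_layer_fluence(list(proximal = bars$a, distal = open_d),
                            p0, mach, g)
  f_b <- dual_layer_fluence(list(proximal = bars$b, distal = open_d),
                            p0, mach, g)
  s0 <- f_a$values + f_b$values
  mid <- which(abs(g$y) <= 3.4)
  expect_lt(diff(range(s0[mid, ])), 1e-9)   # exactly uniform, tng = 0

  p5 <- mlc_parameters(tng_width = 0.05)
  f_a5 <- dual_layer_fluence(list(proximal = bars$a, distal = open_d),
                             p5, mach, g)
  f_b5 <- dual_layer_fluence(list(proximal = bars$b, distal = open_d),
                             p5, mach, g)
  s5 <- f_a5$values + f_b5$values
  # dips at row borders (integer y), plateau elsewhere
  iy_border <- which.min(abs(g$y - 1))
  iy_mid <- which.min(abs(g$y - 1.5))
  ix <- which.min(abs(g$x))
  expect_lt(s5[iy_border, ix], 0.7 * s5[iy_mid, ix])
})

test_that("dynamic accumulation equals the static map for one control point", {
  p <- mlc_parameters()
  ap <- rect_field_aperture(mach, -3, 3, -3, 3)
  pl <- mlc_plan(list(control_point(ap, 1)), arc = FALSE)
  g <- fluence_grid(c(-5, 5), c(-5, 5), 0.1)
  f1 <- accumulate_dynamic_fluence(pl, p, mach, g)
  f2 <- dual_layer_fluence(ap, p, mach, g)
  expect_equal(f1$values, f2$values, tolerance = 1e-14)
})

test_that("sweeping gap matches brute-force time integration", {
  p <- mlc_parameters()
  geom <- beam_geometry(90, 10, mach)
  # package path (closed form over one static map)
  fast <- dualmlc:::.sweep_reading(2.0, 0, p, mach, geom)
  brute <- sweep_integral_oracle(2.0, 0, p, mach, geom, -5, 5)
  expect_equal(fast, brute, tolerance = 2e-3)
  # central-axis fluence ~ gap / sweep length plus leakage
  expect_equal(fast / pdd(10, mach), 2.0 / 10, tolerance = 0.01)

  # an offset widens the effective gap by 2*offset in the same oracle
  po <- mlc_parameters(offset = 0.05)
  fast_o <- dualmlc:::.sweep_reading(2.0, 0, po, mach, geom)
  widening <- (fast_o - fast) / pdd(10, mach) * 10
  expect_equal(widening, 0.1, tolerance = 0.01)
})

test_that("map grid and csv formats round-trip", {
  p <- mlc_parameters()
  g <- fluence_grid(c(-2, 2), c(-2, 2), 0.1)
  f <- dual_layer_fluence(rect_field_aperture(mach, -1, 1, -1, 1),
                          p, mach, g)
  fg <- withr::local_tempfile(fileext = ".txt")
  write_map_grid(f, fg)
  back <- read_map_grid(fg)
  expect_equal(back$x, f$x, tolerance = 1e-9)
  expect_equal(back$values, f$values, tolerance = 1e-9)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(f, fc)
  back2 <- read_map_csv(fc)
  expect_equal(back2$values, f$values, tolerance = 1e-9)
  expect_error(read_map_grid(fc), "not a dualmlc map")
})
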