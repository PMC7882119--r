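mach <- machine()

test_that("depth dose is normalized at d_max and hits 0.63 at 10 cm", {
  expect_equal(pdd(1.3, mach), 1)
  expect_equal(pdd(10, mach), 0.63)
  expect_equal(pdd(0.65, mach), 0.5)
  expect_true(all(diff(pdd(seq(1.3, 30, by = 0.5), mach)) < 0))
})

test_that("source blur preserves uniform maps and conserves integrals", {
  u <- make_map(matrix(0.8, 60, 60))
  b <- source_blur(u, mach)
  expect_equal(b$values, u$values, tolerance = 1e-10)

  # interior field integral conserved
  v <- matrix(0, 80, 80); v[30:50, 30:50] <- 1
  f <- make_map(v)
  bf <- source_blur(f, mach)
  expect_equal(sum(bf$values), sum(v), tolerance = 1e-3)
})

test_that("a narrow slit blurs to a Gaussian of the projected source size", {
  v <- matrix(0, 81, 81); v[, 41] <- 1
  f <- make_map(v, spacing = 0.02)
  b <- source_blur(f, mach)
  prof <- b$values[41, ]
  x <- f$x
  mu <- sum(x * prof) / sum(prof)
  sig <- sqrt(sum((x - mu)^2 * prof) / sum(prof))
  d_mlc <- (mach$layer_distance_proximal + mach$layer_distance_distal) / 2
  sig_pred <- sqrt((mach$source_sigma_x * (mach$sad - d_mlc) / d_mlc)^2 +
                     0.02^2 / 12)  # plus the pixel width variance
  expect_equal(sig, sig_pred, tolerance = 0.05)
})

test_that("dose plane normalizes, scales linearly and magnifies edges", {
  p <- mlc_parameters()
  g <- fluence_grid(c(-7, 7), c(-7, 7), 0.1)
  f <- dual_layer_fluence(rect_field_aperture(mach, -5, 5, -5, 5),
                          p, mach, g)
  d_dmax <- dose_plane(f, beam_geometry(100 - 1.3, 1.3, mach), mach)
  expect_equal(point_dose(d_dmax, c(0, 0)), 1, tolerance = 1e-6)

  f2 <- f; f2$values <- 2 * f$values
  d1 <- dose_plane(f, beam_geometry(90, 10, mach), mach)
  d2 <- dose_plane(f2, beam_geometry(90, 10, mach), mach)
  expect_equal(2 * d1$values, d2$values, tolerance = 1e-12)

  # SSD 95 + 10 cm depth: plane magnification 1.05
  d105 <- dose_plane(f, beam_geometry(95, 10, mach), mach)
  e105 <- field_edge_inflection(extract_profile(d105, "x", 0),
                                c(3.5, 6.9))
  e100 <- field_edge_inflection(extract_profile(d1, "x", 0), c(3.5, 6.5))
  expect_equal(e105 / e100, 1.05, tolerance = 0.002)
})

test_that("point dose interpolates exactly at nodes and superposes", {
  p <- mlc_parameters()
  g <- fluence_grid(c(-7, 7), c(-7, 7), 0.1)
  f <- dual_layer_fluence(rect_field_aperture(mach, -5, 5, -5, 5),
                          p, mach, g)
  d <- dose_plane(f, beam_geometry(90, 10, mach), mach)
  iy <- which(abs(d$y - 1) < 1e-9); ix <- which(abs(d$x - 2) < 1e-9)
  expect_identical(point_dose(d, c(2, 1)), d$values[iy, ix])
  expect_error(point_dose(d, c(10, 0)), "outside")

  # two parallel-opposed copies double the single-field dose
  d2 <- d; d2$values <- d$values + d$values
  expect_equal(point_dose(d2, c(1.234, -0.567)),
               2 * point_dose(d, c(1.234, -0.567)), tolerance = 1e-6)

  # center of a symmetric field is the profile maximum
  prof <- extract_profile(d, "x", 0)
  expect_equal(max(prof$values), point_dose(d, c(0, 0)),
               tolerance = 1e-9)
})

test_that("field edge detection finds the inflection of an erf edge", {
  x <- seq(0, 4, by = 0.1)
  p <- profile1d(x, stats::pnorm((2.00 - x) / 0.15))
  expect_equal(field_edge_inflection(p), 2.00, tolerance = 0.01)

  # translation equivariance
  p2 <- profile1d(x, stats::pnorm((2.37 - x) / 0.15))
  expect_equal(field_edge_inflection(p2) - field_edge_inflection(p),
               0.37, tolerance = 0.005)

  # constant-derivative ramp is ambiguous
  ramp <- profile1d(x, 1 - x / 4)
  expect_error(field_edge_inflection(ramp), "ambiguous|degenerate")
  flat <- profile1d(x, rep(1, length(x)))
  expect_error(field_edge_inflection(flat), "flat")
})

test_that("a tip offset shifts the detected edge by the same amount", {
  g <- fluence_grid(c(2, 8), c(-2, 2), 0.1)
  geom <- beam_geometry(90, 10, mach)
  edges <- vapply(c(0, 0.007), function(o) {
    p <- mlc_parameters(offset = o)
    f <- dual_layer_fluence(rect_field_aperture(mach, -5, 5, -2, 2),
                            p, mach, g)
    field_edge_inflection(extract_profile(dose_plane(f, geom, mach),
                                          "x", 0), c(3.8, 6.2))
  }, numeric(1))
  expect_equal(edges[2] - edges[1], 0.007, tolerance = 0.003)
})

test_that("profiles write and read back with metadata", {
  p <- profile1d(seq(-2, 2, 0.1), stats::runif(41), axis = "y",
                 meta = list(depth = 10, ssd = 90, x_nom = -3.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  q <- read_profile_csv(f)
  expect_equal(q$positions, p$positions)
  expect_equal(q$values, p$values, tolerance = 1e-9)
  expect_equal(q$axis, "y")
  expect_equal(q$meta$x_nom, -3.5)
})
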