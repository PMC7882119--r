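test_that("leaf tip position follows the bank equations", {
  expect_equal(leaf_tip_position(3, "right", mlc_parameters()), 3.0)
  expect_equal(leaf_tip_position(5, "right",
                                 mlc_parameters(offset = 0.007)), 5.007)
  expect_equal(leaf_tip_position(10, "right",
                                 mlc_parameters(curvature = -4e-5)),
               9.996)
  # identity for the left bank with all parameters zero
  x <- seq(-14, 14, by = 0.5)
  expect_equal(leaf_tip_position(x, "left", mlc_parameters()), x)
  expect_error(leaf_tip_position(15, "right", mlc_parameters()),
               "out of range")
})

test_that("dosimetric offset and midpoint shift have their closed forms", {
  p <- mlc_parameters(offset = 0.007, gain = 0.3, curvature = 0)
  expect_equal(dosimetric_offset(2.5, p), 0.007)   # gain cancels
  expect_equal(dosimetric_offset(10, mlc_parameters(curvature = -4e-5)),
               -0.004)
  expect_equal(midpoint_shift(10, mlc_parameters()), 0)
  expect_equal(midpoint_shift(10, mlc_parameters(gain = -4e-4)), -0.004)
})

test_that("derived offsets equal the bracketed two-tip computations", {
  set.seed(42)
  for (i in 1:100) {
    p <- mlc_parameters(offset = stats::runif(1, -0.05, 0.05),
                        gain = stats::runif(1, -0.01, 0.01),
                        curvature = stats::runif(1, -1e-4, 1e-4),
                        tip_width = stats::runif(1, 0, 0.1))
    x <- stats::runif(1, -14, 14)
    lt <- leaf_tip_position(x, "left", p)
    rt <- leaf_tip_position(x, "right", p)
    expect_lt(abs(dosimetric_offset(x, p) - (rt - lt) / 2), 1e-12)
    expect_lt(abs(midpoint_shift(x, p) - ((lt + rt) / 2 - x)), 1e-12)
  }
})

test_that("dosimetric offset ignores gain; midpoint ignores offset/curvature", {
  set.seed(7)
  for (i in 1:50) {
    o <- stats::runif(1, -0.05, 0.05)
    g <- stats::runif(1, -0.01, 0.01)
    cv <- stats::runif(1, -1e-4, 1e-4)
    x <- stats::runif(1, -14, 14)
    base <- mlc_parameters(offset = o, gain = g, curvature = cv)
    gain_off <- mlc_parameters(offset = o, gain = 0, curvature = cv)
    oc_off <- mlc_parameters(offset = 0, gain = g, curvature = 0)
    expect_identical(dosimetric_offset(x, base),
                     dosimetric_offset(x, gain_off))
    expect_identical(midpoint_shift(x, base), midpoint_shift(x, oc_off))
  }
})

test_that("equivalent square matches the 2ab/(a+b) rule and its bounds", {
  expect_equal(equivalent_square(2, 2), 2)
  expect_equal(equivalent_square(0.333, 1), 0.4996, tolerance = 1e-4)
  expect_equal(equivalent_square(1, 3), 1.5)
  expect_equal(equivalent_square(1, 3), equivalent_square(3, 1))
  set.seed(3)
  a <- stats::runif(20, 0.1, 30); b <- stats::runif(20, 0.1, 30)
  es <- equivalent_square(a, b)
  expect_true(all(es >= pmin(a, b) - 1e-12 & es <= pmax(a, b) + 1e-12))
  expect_error(equivalent_square(0, 1), "positive")
})

test_that("parameter and machine invariants are enforced", {
  expect_error(mlc_parameters(layer_transmission = 0), "layer_transmission")
  expect_error(mlc_parameters(tip_width = -1))
  expect_error(machine(layer_distance_proximal = 50,
                       layer_distance_distal = 40),
               "proximal < distal")
  expect_error(machine(sad = -1), "positive")
})

test_that("aperture validation flags bounds, speed, MU/deg and min-gap", {
  m <- machine()
  p <- mlc_parameters()
  ap10 <- rect_field_aperture(m, -5, 5, -5, 5)
  cp <- control_point(ap10, 1, 0)
  expect_true(validate_aperture(cp, m, p)$valid)

  # static plan that requires > 5 cm/s leaf travel: 1 degree apart,
  # 2 cm leaf move, 0.1 MU in the segment
  ap_a <- rect_field_aperture(m, -2, 0, -2, 2)
  ap_b <- rect_field_aperture(m, 0, 2, -2, 2)
  pl <- mlc_plan(list(control_point(ap_a, 0.5, 0),
                      control_point(ap_b, 0.5, 1)),
                 total_mu = 0.2, arc = TRUE)
  v <- validate_aperture(pl, m, p)
  expect_false(v$valid)
  expect_true("leaf_speed" %in% v$violations$type)

  # dynamic pair with a 0.05 cm gap violates the 0.06 cm minimum
  ap_c <- rect_field_aperture(m, 0, 0.05, -2, 2)
  ap_d <- rect_field_aperture(m, 1, 1.05, -2, 2)
  pl2 <- mlc_plan(list(control_point(ap_c, 0.5, 0),
                       control_point(ap_d, 0.5, 0)),
                  total_mu = 100, arc = FALSE)
  v2 <- validate_aperture(pl2, m, p)
  expect_false(v2$valid)
  expect_true("min_gap" %in% v2$violations$type)

  # MU/deg below 0.1 on an arc
  pl3 <- mlc_plan(list(control_point(ap10, 0.5, 0),
                       control_point(ap10, 0.5, 10)),
                  total_mu = 0.5, arc = TRUE)
  v3 <- validate_aperture(pl3, m, p)
  expect_true("mu_per_deg" %in% v3$violations$type)

  # leaf beyond the 28 x 28 field
  ap_big <- rect_field_aperture(m, -15, 5, -5, 5)
  v4 <- validate_aperture(control_point(ap_big, 1, 0), m, p)
  expect_true("field_bounds" %in% v4$violations$type)
})

test_that("machine JSON round-trips", {
  m <- machine(source_sigma_x = 0.08)
  p <- mlc_parameters(offset = -0.0123, tng_width = 0.04)
  f <- withr::local_tempfile(fileext = ".json")
  write_machine_json(m, p, f)
  back <- read_machine_json(f)
  expect_equal(unclass(back$machine), unclass(m))
  expect_equal(back$params$offset, p$offset)
  expect_equal(back$params$layer_transmission, p$layer_transmission)
})
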