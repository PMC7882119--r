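# Virtual laboratory: reproducibility and the physics each session is
# built to expose.

gt_nf <- ground_truth(noise_sd = 0, seed = 101)

test_that("sessions are pure functions of the ground truth and arguments", {
  gt <- ground_truth(seed = 5)
  a <- gen_sweep_session(gt, gaps_mm = c(2, 10, 20), positions_cm = 0)
  b <- gen_sweep_session(gt, gaps_mm = c(2, 10, 20), positions_cm = 0)
  expect_identical(a$reading, b$reading)
  gt2 <- ground_truth(seed = 6)
  c2 <- gen_sweep_session(gt2, gaps_mm = c(2, 10, 20), positions_cm = 0)
  expect_false(identical(a$reading, c2$reading))
  # global RNG state is untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(gen_sweep_session(gt, gaps_mm = c(2, 6),
                                            positions_cm = 0))
  expect_identical(stats::runif(1), before)
})

test_that("noise-free sweep readings are linear in the gap width", {
  s <- gen_sweep_session(gt_nf, positions_cm = 0)
  sw <- s[s$kind == "sweep", ]
  leak <- s$reading[s$kind == "leakage"]
  fit <- stats::lm(I(reading - leak) ~ gap_mm, data = sw)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)

  # leakage record equals the stacked-transmission dose level
  expect_equal(leak, 0.0047^2 * pdd(10, machine()), tolerance = 1e-9)

  # doubling the gap doubles the leakage-subtracted reading (flat tip,
  # offset 0)
  gt0 <- ground_truth(mlc_parameters(offset = 0), noise_sd = 0, seed = 1)
  s0 <- gen_sweep_session(gt0, gaps_mm = c(5, 10), positions_cm = 0)
  net <- s0$reading[s0$kind == "sweep"] -
    s0$reading[s0$kind == "leakage"]
  expect_equal(net[2] / net[1], 2, tolerance = 0.01)
})

test_that("undeliverable gaps are refused", {
  gt_wide <- ground_truth(mlc_parameters(dynamic_min_gap = 0.5),
                          noise_sd = 0, seed = 1)
  expect_error(gen_sweep_session(gt_wide, gaps_mm = c(4, 10),
                                 positions_cm = 0), "undeliverable")
  expect_error(gen_sweep_session(gt_nf, gaps_mm = c(1, 10),
                                 positions_cm = 0), "2-20")
})

test_that("abutting sessions expose the leaf-end offset sign", {
  mk <- function(o, seed) ground_truth(mlc_parameters(offset = o),
                                       noise_sd = 0, seed = seed)
  pos <- gen_abutting_session(mk(0.01, 2), junctions = 0)[[1]]$sum
  neg <- gen_abutting_session(mk(-0.01, 2), junctions = 0)[[1]]$sum
  zero <- gen_abutting_session(mk(0, 2), junctions = 0)[[1]]$sum
  rel <- function(p) p$values[abs(p$positions) < 1.6] /
    stats::median(p$values[abs(p$positions) < 1.6])
  expect_gt(max(rel(pos)), 1.03)
  expect_lt(min(rel(neg)), 0.97)
  expect_true(all(abs(rel(zero) - 1) < 0.015))
})

test_that("averaging three runs shrinks the noise like sqrt(3)", {
  dev_of <- function(n_runs, seed) {
    gt <- ground_truth(noise_sd = 0.01, seed = seed)
    s <- gen_abutting_session(gt, junctions = 0, n_runs = n_runs)[[1]]$sum
    gt0 <- ground_truth(noise_sd = 0, seed = seed)
    s0 <- gen_abutting_session(gt0, junctions = 0, n_runs = 1)[[1]]$sum
    keep <- abs(s$positions) < 1.5
    (s$values[keep] - s0$values[keep]) / s0$values[keep]
  }
  # pooled RMS deviation across seeds: the per-run noise (iid point
  # component plus per-field normalization component) scales as
  # 1/sqrt(n_runs)
  d1 <- unlist(lapply(1:8, function(s) dev_of(1, s)))
  d3 <- unlist(lapply(1:8, function(s) dev_of(3, s)))
  ratio <- sqrt(mean(d1^2) / mean(d3^2))
  expect_lt(abs(ratio - sqrt(3)), 0.2 * sqrt(3))
})

test_that("bar sessions reveal tongue-and-groove dips", {
  gt0 <- ground_truth(mlc_parameters(tng_width = 0), noise_sd = 0,
                      seed = 4)
  s0 <- gen_bar_session(gt0, "proximal")$sum
  keep <- abs(s0$positions) <= 3.2
  expect_lt(diff(range(s0$values[keep])) /
              stats::median(s0$values[keep]), 0.01)

  dip_depth <- function(w) {
    gt <- ground_truth(mlc_parameters(tng_width = w), noise_sd = 0,
                       seed = 4)
    s <- gen_bar_session(gt, "proximal")$sum
    v <- s$values[abs(s$positions) <= 3.2]
    1 - min(v) / stats::median(v)
  }
  depths <- vapply(c(0, 0.05, 0.1), dip_depth, numeric(1))
  expect_true(all(diff(depths) > 0.02))   # monotone in the width

  # dips sit at the leaf borders of the scanned layer (1 cm period,
  # integer y for the proximal layer)
  gt5 <- ground_truth(noise_sd = 0, seed = 4)
  s5 <- gen_bar_session(gt5, "proximal")$sum
  v <- s5$values; pos <- s5$positions
  local_min <- which(v < c(v[-1], Inf) & v < c(Inf, v[-length(v)]) &
                       abs(pos) <= 2.6)
  expect_true(all(abs(pos[local_min] - round(pos[local_min])) < 0.11))
  # the staggered distal layer dips half a leaf width away
  s5d <- gen_bar_session(gt5, "distal")$sum
  vd <- s5d$values; posd <- s5d$positions
  ld <- which(vd < c(vd[-1], Inf) & vd < c(Inf, vd[-length(vd)]) &
                abs(posd) <= 2.6)
  expect_true(all(abs(posd[ld] - (round(posd[ld] - 0.5) + 0.5)) < 0.11))
})

test_that("edge sessions recover the leaf-end geometry exactly when noise-free", {
  es <- gen_edge_session(gt_nf, centers = c(-5, 0, 5))
  obs <- edge_observations(es)
  expect_equal(obs$dxmp, rep(0, 3), tolerance = 5e-4)
  expect_equal(obs$dxd, rep(0.007, 3), tolerance = 1e-3)
})

test_that("plan suites respect their construction contracts", {
  gt <- ground_truth(seed = 31)
  suite <- gen_plan_suite(gt, n_plans = 2, technique = "sw_vmat",
                          modulation = 6)
  # chamber dose ratios within 0.4-0.8 by construction
  ch <- suite$chambers
  ratios <- ch$dose_true[ch$role == "low"] /
    ch$dose_true[ch$role == "high"]
  expect_true(all(ratios >= 0.4 & ratios <= 0.8))

  # sliding-window plans: every leaf moves monotonically in one direction
  for (pl in suite$plans) {
    for (lay in c("proximal", "distal")) {
      xs <- sapply(pl$control_points, function(cp)
        cp$apertures[[lay]]$x_left)
      expect_true(all(apply(xs, 1, function(v) all(diff(v) >= -1e-9))))
      xr <- sapply(pl$control_points, function(cp)
        cp$apertures[[lay]]$x_right)
      expect_true(all(apply(xr, 1, function(v) all(diff(v) >= -1e-9))))
    }
    expect_true(validate_aperture(pl, gt$machine, gt$true_params)$valid)
  }

  # array samples: 581-1009 diodes on the 10.5 cm cylinder
  for (a in suite$arrays) {
    expect_true(nrow(a) >= 581 && nrow(a) <= 1009)
    expect_equal(a$x, 10.5 * sin(a$theta), tolerance = 1e-12)
  }

  # bit-identical regeneration from the same seed
  suite2 <- gen_plan_suite(gt, n_plans = 2, technique = "sw_vmat",
                           modulation = 6)
  expect_identical(suite$chambers$dose, suite2$chambers$dose)
  expect_identical(suite$arrays[[1]]$dose, suite2$arrays[[1]]$dose)

  expect_error(gen_plan_suite(gt, 1, "vmat", modulation = 12),
               "modulation")
})
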