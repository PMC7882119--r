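mach <- machine()
geom10 <- beam_geometry(90, 10, mach)

test_that("fit_dlg reads off a constructed intercept exactly", {
  gaps <- c(2, 6, 10, 16, 20)
  ms <- data.frame(kind = c(rep("sweep", 5), "leakage"),
                   gap_mm = c(gaps, 0),
                   position_cm = 0, depth_cm = 10, ssd_cm = 90,
                   detector = "farmer",
                   leakage = c(rep(FALSE, 5), TRUE),
                   reading = c(0.003 * (gaps + 0.4) + 1e-4, 1e-4))
  f <- fit_dlg(ms)
  expect_equal(f$estimate, 0.4, tolerance = 1e-9)

  ms_flat <- ms
  ms_flat$reading <- c(rep(0.01, 5), 1e-4)
  expect_error(fit_dlg(ms_flat), "slope")
})

test_that("RMS offset method recovers a negative leaf-end offset", {
  gt <- ground_truth(mlc_parameters(offset = -0.015), noise_sd = 0,
                     seed = 21)
  s <- gen_sweep_session(gt, positions_cm = c(0, 3))
  ctx <- model_context(mach, mlc_parameters(offset = 0), geom10)
  f <- fit_offset_rms(s, seq(-0.03, 0.01, by = 0.005), ctx)
  expect_lt(abs(f$estimate - (-0.015)), 0.002)
  # identifiability: RMS at the truth below RMS one grid step away
  d <- f$details
  k <- which.min(abs(d$offset - (-0.015)))
  expect_lt(d$rms_pct[k], d$rms_pct[k - 2])
  expect_lt(d$rms_pct[k], d$rms_pct[k + 2])
})

test_that("DLG and RMS methods disagree on rounded tips, agree on flat", {
  ctx_tip <- model_context(mach, mlc_parameters(offset = 0,
                                                tip_width = 0.1), geom10)
  gt_tip <- ground_truth(mlc_parameters(offset = 0.007, tip_width = 0.1),
                         noise_sd = 0, seed = 8)
  s_tip <- gen_sweep_session(gt_tip, positions_cm = 0)
  dlg_tip <- fit_dlg(s_tip)$diagnostics$dlg_cm_half
  rms_tip <- fit_offset_rms(s_tip, seq(-0.003, 0.017, 0.005),
                            ctx_tip)$estimate
  # the half-height tip zone inflates the sweep fluence integral by
  # 2 * tip_width * (T - T^2) (stacked layers), so DLG/2 sits above the
  # true offset while the model-based RMS method stays at it
  expect_gt(dlg_tip - rms_tip, 2e-4)

  gt_flat <- ground_truth(mlc_parameters(offset = 0.007), noise_sd = 0,
                          seed = 8)
  s_flat <- gen_sweep_session(gt_flat, positions_cm = 0)
  ctx <- model_context(mach, mlc_parameters(offset = 0), geom10)
  dlg_flat <- fit_dlg(s_flat)$diagnostics$dlg_cm_half
  rms_flat <- fit_offset_rms(s_flat, seq(-0.003, 0.017, 0.005),
                             ctx)$estimate
  expect_lt(abs(dlg_flat - rms_flat), 1.5e-4)
  expect_gt(dlg_tip - rms_tip, 2 * abs(dlg_flat - rms_flat))
})

test_that("gain regression estimates and tests the slope", {
  pairs <- data.frame(x_nom = c(-10, -5, 0, 5, 10))
  pairs$dxmp <- 0.001 * pairs$x_nom
  f <- fit_gain(pairs)
  expect_equal(f$estimate, 0.001, tolerance = 1e-12)
  expect_equal(f$decision, 0.001, tolerance = 1e-12)

  expect_error(fit_gain(data.frame(x_nom = rep(1, 5),
                                   dxmp = stats::rnorm(5))),
               "distinct")
})

test_that("transmission check confirms the standard value", {
  gt <- ground_truth(seed = 13)
  s <- gen_sweep_session(gt, gaps_mm = c(6, 20), positions_cm = c(0, 5))
  ctx <- model_context(mach, mlc_parameters(), geom10)
  f <- fit_transmission(s, ctx)
  expect_equal(f$estimate, 0.0047, tolerance = 0.05)
  expect_equal(f$decision, 0.0047)
})

test_that("T&G width check lands on the truth over the candidate grid", {
  gt <- ground_truth(noise_sd = 0, seed = 17)   # tng 0.05 truth
  bar <- gen_bar_session(gt, "proximal")
  ctx <- model_context(mach, mlc_parameters(offset = 0.007,
                                            tng_width = 0), geom10)
  f <- tng_check(bar, ctx, widths = seq(0, 0.1, by = 0.01))
  expect_equal(f$decision, 0.05)
  # RMS grows monotonically away from the argmin
  d <- f$details
  k <- which.min(d$rms_pct)
  expect_true(all(diff(d$rms_pct[k:nrow(d)]) > 0))
  expect_true(all(diff(d$rms_pct[1:k]) < 0))

  gt0 <- ground_truth(mlc_parameters(tng_width = 0), noise_sd = 0,
                      seed = 17)
  bar0 <- gen_bar_session(gt0, "proximal")
  f0 <- tng_check(bar0, ctx, widths = c(0, 0.05, 0.1))
  expect_equal(f0$decision, 0)
})

test_that("offset scan inverts the forward model and handles noise", {
  gt <- ground_truth(noise_sd = 0, seed = 41)   # true offset +0.007
  suites <- list(gen_plan_suite(gt, n_plans = 3, technique = "vmat",
                                modulation = 4),
                 gen_plan_suite(gt, n_plans = 2, technique = "sw_vmat",
                                modulation = 4))
  plans <- unlist(lapply(suites, `[[`, "plans"), recursive = FALSE)
  chambers <- do.call(rbind, lapply(suites, `[[`, "chambers"))
  ctx <- model_context(mach, mlc_parameters(), geom10)
  offsets <- seq(-0.013, 0.027, by = 0.01)
  f <- offset_scan(plans, chambers, offsets, ctx)
  expect_lt(abs(f$estimate - 0.007), 0.001)
  # mean difference is monotone in the model offset
  expect_true(all(diff(f$details$mean_diff_pct) > 0))

  # noisy replicates reuse the calculated doses: small bias, small sd
  ests <- vapply(1:50, function(r) {
    ch <- chambers
    set.seed(5000 + r)
    ch$dose <- ch$dose_true * exp(stats::rnorm(nrow(ch), 0, 0.005))
    offset_scan(plans, ch, offsets, ctx, calc = f$details_calc)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.007), 0.001)
  expect_lt(stats::sd(ests), 0.003)
  expect_error(offset_scan(plans, chambers[1:6, ], offsets, ctx),
               ">= 10")
})

test_that("the RMS method tolerates 0.5% chamber noise", {
  gt <- ground_truth(seed = 4)   # 0.5% noise, true offset +0.007
  s <- gen_sweep_session(gt, positions_cm = c(0, 5))
  ctx <- model_context(mach, mlc_parameters(offset = 0), geom10)
  f <- fit_offset_rms(s, seq(-0.01, 0.02, 0.005), ctx)
  expect_lt(abs(f$estimate - 0.007), 0.005)
  # residual RMS at the optimum is at the noise level, well under 2%
  expect_gt(f$diagnostics$rms_at_min, 0.1)
  expect_lt(f$diagnostics$rms_at_min, 2)
})
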