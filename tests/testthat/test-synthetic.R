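test_that("the cardiac waveform matches its analytic definition", {
  expect_equal(make_waveform(72, 15, 30, 1.0), rep(1, 30))

  w0 <- make_waveform(72, 15, 75, 0.0)
  expect_equal(min(w0), 0, tolerance = 0.02)      # touches 0 each cycle
  expect_equal(max(w0), 1, tolerance = 0.01)

  # 72 bpm at 15 Hz for 5 s: 6 systolic peaks at analytic positions
  w <- make_waveform(72, 15, 75, 0.2)
  peaks <- which(diff(sign(diff(w))) == -2) + 1
  expected <- round((0.5 + 0:5) * 60 / 72 * 15) + 1
  expect_equal(length(peaks), 6)
  expect_true(all(abs(peaks - expected) <= 1))

  expect_error(make_waveform(180, 3, 10, 0.5), "frame rate too low",
               class = "dopplerperf_error_waveform")
})

test_that("case synthesis is deterministic in (params, seed)", {
  p <- small_params()
  a <- synthesize_case(p, seed = 123)
  b <- synthesize_case(p, seed = 123)
  expect_identical(a$cine$frames, b$cine$frames)
  expect_identical(a$truth, b$truth)
  c2 <- synthesize_case(p, seed = 124)
  expect_false(identical(a$cine$frames, c2$cine$frames))
})

test_that("drawn cohorts are calibrated to the published group summaries", {
  dp <- draw_cohort_params(500, 500, seed = 202)
  mal <- dp[dp$label == "malignant", ]
  inf <- dp[dp$label == "inflammatory", ]
  # per-label mean/median within 5% (relative) of the calibration targets
  rel <- function(x, target) abs(x / target - 1)
  expect_lt(rel(mean(mal$tfv), 1.422), 0.05)
  expect_lt(rel(mean(inf$tfv), 2.653), 0.05)
  expect_lt(rel(median(mal$tpi), 0.004), 0.05)
  expect_lt(rel(median(inf$tpi), 0.016), 0.05)
  expect_lt(rel(median(mal$fv), 1.592), 0.05)
  expect_lt(rel(median(inf$fv), 3.397), 0.05)
  expect_lt(rel(median(mal$volf), 0.010), 0.05)
  expect_lt(rel(median(inf$volf), 0.032), 0.05)
  expect_identical(median(mal$tri), 1.0)
  expect_identical(median(mal$ri), 1.0)
  expect_lt(rel(median(inf$tri), 0.776), 0.05)
  expect_lt(rel(median(inf$ri), 0.843), 0.05)
  # degenerate malignant quartiles
  expect_equal(unname(quantile(mal$tri, c(.25, .75))), c(1, 1))
  # stochastic ordering between the labels
  expect_lt(median(mal$tpi), median(inf$tpi))
  expect_gt(median(mal$tri), median(inf$tri))
})

test_that("rendered cases honour geometry and vascular fraction", {
  # horizontal vessel is perpendicular to the vertical beam
  case <- synthesize_case(small_params(angle_deg = 90), seed = 5)
  expect_true(is.na(case$truth$fv))
  vsq <- decode_cine(case$cine)
  expect_error(suppressWarnings(svfm(vsq)), "unmeasurable",
               class = "dopplerperf_error_angle")

  # decode-and-count: time-averaged perfused fraction near the constructed one
  case2 <- synthesize_case(small_params(), seed = 6)
  vs2 <- decode_cine(case2$cine)
  tr <- perfusion_trace(vs2)
  cyc <- detect_cycles(tr)
  win <- min(cyc$start_frame):(max(cyc$end_frame) - 1)
  measured_frac <- mean(tr$area[win]) / attr(tr, "roi_area")
  expect_equal(measured_frac, case2$truth$vasc_frac,
               tolerance = 0.10 * case2$truth$vasc_frac)
})

test_that("generated cohorts are reproducible and schema-stable", {
  m1 <- generate_cohort(1, 1, seed = 9, max_roi_side = 100)$manifest
  m2 <- generate_cohort(1, 1, seed = 9, max_roi_side = 100)$manifest
  expect_identical(m1, m2)
  m3 <- generate_cohort(1, 1, seed = 10, max_roi_side = 100)$manifest
  expect_identical(names(m1), names(m3))
  expect_false(identical(m1$true_tfv, m3$true_tfv))
  expect_equal(nrow(m1), 2)
})
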