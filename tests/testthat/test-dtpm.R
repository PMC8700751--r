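test_that("perfusion trace implements the per-frame definitions exactly", {
  # 100-px ROI, 50 px perfused at 2.0 cm/s
  f <- matrix(NaN, 10, 10)
  f[1:50] <- 2.0
  vs <- vfs_from_fields(list(f), frame_rate = 15, pixel_spacing = 0.1)
  tr <- perfusion_trace(vs)
  expect_equal(tr$mean_v, 2.0)
  expect_equal(tr$area / attr(tr, "roi_area"), 0.5)
  expect_equal(tr$intensity, 1.0)

  # no perfused pixel: the diastolic no-flow convention
  vs0 <- vfs_from_fields(list(matrix(NaN, 10, 10)))
  tr0 <- perfusion_trace(vs0)
  expect_equal(tr0$mean_v, 0)
  expect_equal(tr0$intensity, 0)
  expect_equal(tr0$area, 0)
})

test_that("intensity equals the brute-force pixel sum over the ROI pixel count", {
  set.seed(7)
  for (rep in 1:20) {
    f <- matrix(runif(144, -5, 5), 12, 12)
    f[sample(144, sample(30:120, 1))] <- NaN
    roi <- matrix(runif(144) > 0.3, 12, 12)
    if (!any(roi)) next
    vs <- vfs_from_fields(list(f), roi = roi)
    tr <- perfusion_trace(vs)
    inside <- f[roi]
    expect_equal(tr$intensity, sum(abs(inside[is.finite(inside)])) / sum(roi))
    expect_lte(tr$intensity, tr$mean_v + 1e-12)
  }
})

test_that("cycle detection finds the systolic peaks of a raised-cosine train", {
  # 72 bpm at 15 Hz for 5 s: peaks at u = 0.5, 1.5, ..., 5.5 -> 6 peaks,
  # 5 complete cycles
  w <- make_waveform(72, 15, 75, pulsatility = 0.1)
  tr <- tibble::tibble(frame = 1:75, t = (0:74) / 15, mean_v = w,
                       intensity = w)
  cyc <- detect_cycles(tr)
  expect_equal(nrow(cyc), 5)
  expected_peaks <- round((0.5 + 0:5) * 60 / 72 * 15) + 1
  expect_true(all(abs(cyc$start_frame - expected_peaks[1:5]) <= 1))
  expect_true(all(abs(cyc$end_frame - expected_peaks[2:6]) <= 1))

  # constant trace: no cycle
  trc <- tibble::tibble(frame = 1:30, t = (0:29) / 15, mean_v = 1,
                        intensity = 1)
  expect_error(detect_cycles(trc), "no complete cardiac cycle",
               class = "dopplerperf_error_cycles")

  # exactly two peaks: one cycle spanning the inter-peak interval
  x <- rep(0, 30); x[8] <- 1; x[22] <- 1
  tr2 <- tibble::tibble(frame = 1:30, t = (0:29) / 15, mean_v = x,
                        intensity = x)
  cyc2 <- detect_cycles(tr2)
  expect_equal(nrow(cyc2), 1)
  expect_equal(c(cyc2$start_frame, cyc2$end_frame), c(8, 22))
})

test_that("TFV, TRI, TPI follow their defining formulas", {
  mk_trace <- function(mean_v, intensity = mean_v) {
    tibble::tibble(frame = seq_along(mean_v), t = (seq_along(mean_v) - 1) / 15,
                   mean_v = mean_v, intensity = intensity)
  }
  one_cycle <- tibble::tibble(cycle = 1L, start_frame = 1L, end_frame = 3L,
                              vmax = 3, vmin = 1)
  res <- compute_dtpm(mk_trace(c(3, 1, 9)), one_cycle)
  expect_equal(res$tri, 2 / 3)
  expect_equal(res$tfv, 2.0)          # frames past the last peak discarded

  # a cycle whose diastolic frames have no perfused area: TRI = 1, the
  # malignant no-flow pattern
  cyc0 <- tibble::tibble(cycle = 1L, start_frame = 1L, end_frame = 4L,
                         vmax = 2, vmin = 0)
  res0 <- compute_dtpm(mk_trace(c(2, 1, 0, 2)), cyc0)
  expect_equal(res0$tri, 1.0)

  # vmax = 0 convention
  resz <- compute_dtpm(mk_trace(c(0, 0)),
                       tibble::tibble(cycle = 1L, start_frame = 1L,
                                      end_frame = 2L, vmax = 0, vmin = 0))
  expect_equal(resz$tri, 0)

  expect_error(compute_dtpm(mk_trace(numeric(0)), NULL), "empty input",
               class = "dopplerperf_error_input")
})

test_that("whole-trace fallback engages with a warning when no cycle exists", {
  f <- matrix(NaN, 6, 6); f[1:5] <- 1.5
  vs <- vfs_from_fields(list(f, f, f), frame_rate = 2)
  expect_warning(res <- dtpm(vs), "falling back")
  expect_true(res$fallback)
  expect_equal(res$n_cycles, 0L)
  expect_equal(res$tfv, 1.5)
  expect_equal(res$tri, 0)            # constant flow
})

test_that("DTPM scale and ROI invariances hold", {
  set.seed(11)
  w <- make_waveform(75, 15, 45, 0.3)
  fields <- lapply(w, function(wi) {
    f <- matrix(NaN, 10, 10)
    f[1:30] <- wi * runif(30, 1, 3)
    f
  })
  vs <- vfs_from_fields(fields)
  r1 <- suppressWarnings(dtpm(vs))
  expect_lte(r1$tpi, r1$tfv + 1e-12)

  # scaling every velocity by k scales tfv and tpi by k, leaves tri unchanged
  k <- 2.7
  vs_k <- vfs_from_fields(lapply(fields, function(f) f * k))
  r2 <- suppressWarnings(dtpm(vs_k))
  expect_equal(r2$tfv, k * r1$tfv)
  expect_equal(r2$tpi, k * r1$tpi)
  expect_equal(r2$tri, r1$tri)

  # doubling the ROI with no new perfused pixels halves tpi only
  roi_big <- matrix(FALSE, 10, 20)
  roi_big[, 1:10] <- TRUE
  fields_big <- lapply(fields, function(f) cbind(f, matrix(NaN, 10, 10)))
  arr <- vfs_from_fields(fields_big, roi = matrix(TRUE, 10, 20))
  r3 <- suppressWarnings(dtpm(arr))
  expect_equal(r3$tfv, r1$tfv)
  expect_equal(r3$tri, r1$tri)
  expect_equal(r3$tpi, r1$tpi / 2)
})
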