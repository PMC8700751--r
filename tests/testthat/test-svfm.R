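test_that("vessel candidates are the 4-connected components, size-ordered", {
  f <- matrix(NaN, 12, 12)
  f[2:7, 2:6] <- 1.5          # 30 px blob
  vs <- vfs_from_fields(list(f))
  cand <- segment_vessels(vs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_px, 30)

  f[10:11, 8:12] <- -2        # second, 10 px blob
  cand2 <- segment_vessels(vfs_from_fields(list(f)))
  expect_equal(cand2$n_px, c(30, 10))

  expect_error(segment_vessels(vfs_from_fields(list(matrix(NaN, 5, 5)))),
               "no vessel visible", class = "dopplerperf_error_novessel")
})

test_that("component labeling agrees with an independent graph-based oracle", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:10) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    if (!any(mask)) next
    f <- matrix(NaN, 20, 20); f[mask] <- 1
    cand <- segment_vessels(vfs_from_fields(list(f)))
    # oracle: connected components of the 4-neighbour adjacency graph
    idx <- which(mask)
    rc <- cbind((idx - 1) %% 20 + 1, (idx - 1) %/% 20 + 1)
    edges <- integer(0)
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i < j && sum(abs(rc[i, ] - rc[j, ])) == 1) edges <- c(edges, i, j)
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    comp <- igraph::components(g)
    expect_equal(nrow(cand), comp$no)
    expect_equal(sort(cand$n_px), sort(unname(comp$csize)))
  }
})

test_that("vessel selection honours size and direction-consistency in that order", {
  # large blob with alternating sign (inconsistent), small steady blob
  mk <- function(sign_seq) {
    lapply(sign_seq, function(s) {
      f <- matrix(NaN, 12, 12)
      f[2:7, 2:6] <- 2 * s          # 30 px, flipping
      f[10:11, 9:11] <- 1.2         # 6 px, steady
      f
    })
  }
  vs <- vfs_from_fields(mk(c(1, -1, 1, -1)))
  cand <- segment_vessels(vs)
  expect_equal(cand$consistency[cand$n_px == 30], 0.5)
  seg <- select_largest_vessel(cand)
  expect_equal(sum(seg$mask), 6)

  # steady large blob wins
  vs2 <- vfs_from_fields(mk(c(1, 1, 1, 1)))
  seg2 <- select_largest_vessel(segment_vessels(vs2))
  expect_equal(sum(seg2$mask), 30)

  # all inconsistent: excluded from single-vessel analysis
  f <- matrix(NaN, 8, 8); f[2:5, 2:5] <- 1
  vs3 <- vfs_from_fields(list(f, -f, f, -f))
  expect_error(select_largest_vessel(segment_vessels(vs3)),
               "no vessel with known flow direction",
               class = "dopplerperf_error_direction")
})

test_that("axis and Doppler angle estimation matches known geometries", {
  # vertical 1x20 line is parallel to the (0,-1) beam: angle 0
  m <- matrix(FALSE, 24, 24); m[3:22, 12] <- TRUE
  g <- estimate_axis_and_angle(m, 0.01)
  expect_equal(g$angle_deg, 0, tolerance = 1e-6)

  # 45-degree diagonal
  m2 <- matrix(FALSE, 24, 24)
  for (i in 1:20) m2[i + 2, i + 2] <- TRUE
  g2 <- estimate_axis_and_angle(m2, 0.01)
  expect_equal(g2$angle_deg, 45, tolerance = 1)

  # elongated rectangle at a known orientation: axis within 2 degrees
  for (ang in c(20, 35, 60)) {
    v <- rasterize_vessel_dbg(40, 7, ang)
    mm <- matrix(FALSE, 80, 80)
    mm[cbind(41 + v$dy, 41 + v$dx)] <- TRUE
    gg <- estimate_axis_and_angle(mm, 0.01)
    expect_equal(gg$angle_deg, ang, tolerance = 2)
  }

  expect_error(estimate_axis_and_angle(matrix(FALSE, 4, 4), 0.01),
               "axis undefined", class = "dopplerperf_error_axis")
})

test_that("angle correction divides by cos(angle) and flags beyond 60 degrees", {
  f <- matrix(NaN, 8, 8); f[3:6, 4] <- c(1.0, 1.5, 1.2, 0.8)
  vs <- vfs_from_fields(list(f))
  seg <- list(mask = is.finite(f), angle_deg = 60)
  tr <- spectral_trace(seg, vs)
  expect_equal(tr$measured, 1.5)
  expect_equal(tr$corrected, 3.0)     # cos 60 = 0.5 doubles the peak
  expect_true(attr(tr, "angle_valid"))

  seg$angle_deg <- 0
  expect_equal(spectral_trace(seg, vs)$corrected, 1.5)

  seg$angle_deg <- 75
  expect_false(attr(spectral_trace(seg, vs), "angle_valid"))

  seg$angle_deg <- 90
  expect_error(spectral_trace(seg, vs), "unmeasurable",
               class = "dopplerperf_error_angle")
})

test_that("FV, RI, VolF follow their defining formulas", {
  tr <- tibble::tibble(frame = 1:2, t = c(0, 1), corrected = c(4, 1))
  cyc <- tibble::tibble(cycle = 1L, start_frame = 1L, end_frame = 3L,
                        vmax = 4, vmin = 1)
  res <- compute_svfm(tr, cyc, diameter = 0.1, angle_deg = 30)
  expect_equal(res$ri, 0.75)                       # (PSV - EDV)/PSV
  expect_equal(res$fv, 2.5)
  expect_equal(res$volf, 2.5 * pi * 0.05^2)

  res2 <- compute_svfm(tibble::tibble(frame = 1, t = 0, corrected = 3),
                       NULL, diameter = 0.1)
  expect_equal(res2$volf, 3 * pi * 0.0025, tolerance = 1e-9)
  expect_equal(round(res2$volf, 4), 0.0236)

  # volf scales with diameter^2 at fixed fv
  res3 <- compute_svfm(tr, cyc, diameter = 0.2, angle_deg = 30)
  expect_equal(res3$volf, 4 * res$volf)
})

test_that("corrected FV agrees across renderings of one vessel at 0-60 degrees", {
  base <- small_params()
  fvs <- sapply(c(0, 30, 45, 60), function(a) {
    case <- synthesize_case(utils::modifyList(base, list(angle_deg = a)),
                            seed = 99, label = "inflammatory")
    sv <- suppressWarnings(svfm(decode_cine(case$cine)))
    c(sv$fv, sv$ri)
  })
  # cos-compensation: corrected FV recovers the same true flow velocity
  expect_lt(diff(range(fvs[1, ])) / mean(fvs[1, ]), 0.10)
  # RI is invariant to the correction
  expect_lt(diff(range(fvs[2, ])), 0.05)
})
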