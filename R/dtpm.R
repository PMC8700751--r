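#' Per-frame perfusion trace over the ROI
#'
#' For every frame, summarizes the perfused pixels inside the ROI: the mean
#' speed `mean_v` (cm/s; 0 when no pixel is perfused — a diastolic no-flow
#' frame is a real physiological state, not missing data), the perfused area
#' `area` (cm^2) and the perfusion intensity
#' `intensity = mean_v * area / roi_area` (cm/s), i.e. the mean speed weighted
#' by the vascular fraction of the ROI.
#'
#' @param v_seq A [velocity_field_sequence()].
#' @return A tibble of class `perfusion_trace` with columns `frame`, `t` (s),
#'   `mean_v`, `area`, `intensity`, and attributes `roi_area` (cm^2),
#'   `frame_rate`, `pixel_spacing`.
#' @export
perfusion_trace <- function(v_seq) {
  stopifnot(inherits(v_seq, "velocity_field_sequence"))
  d <- dim(v_seq$fields)
  n_roi <- sum(v_seq$roi_mask)
  if (n_roi == 0) abort("degenerate ROI", class = "dopplerperf_error_roi")
  sp2 <- v_seq$pixel_spacing^2
  roi_idx <- which(v_seq$roi_mask)
  npx <- d[1] * d[2]
  mean_v <- area <- intensity <- numeric(d[3])
  for (i in seq_len(d[3])) {
    vals <- v_seq$fields[roi_idx + (i - 1L) * npx]
    fin <- is.finite(vals)
    n_perf <- sum(fin)
    s <- if (n_perf > 0) sum(abs(vals[fin])) else 0
    mean_v[i] <- if (n_perf > 0) s / n_perf else 0
    area[i] <- n_perf * sp2
    intensity[i] <- s / n_roi
  }
  out <- tibble(
    frame = seq_len(d[3]),
    t = (seq_len(d[3]) - 1) / v_seq$frame_rate,
    mean_v = mean_v, area = area, intensity = intensity
  )
  attr(out, "roi_area") <- n_roi * sp2
  attr(out, "frame_rate") <- v_seq$frame_rate
  attr(out, "pixel_spacing") <- v_seq$pixel_spacing
  class(out) <- c("perfusion_trace", class(out))
  out
}

# local maxima of x with prominence >= min_prom; returns indices
find_peaks_ <- function(x, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # collapse plateaus: candidate peaks are runs strictly above both neighbors
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  for (j in seq_len(k)) {
    left_ok <- j > 1 && r$values[j - 1] < r$values[j]
    right_ok <- j < k && r$values[j + 1] < r$values[j]
    if (left_ok && right_ok) {
      cand <- c(cand, starts[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  if (length(cand) == 0) return(integer(0))
  keep <- vapply(cand, function(p) {
    # prominence: drop to the higher of the two key saddles
    lmin <- x[p]; i <- p
    while (i > 1 && x[i - 1] <= x[p]) { i <- i - 1; lmin <- min(lmin, x[i]) }
    left_base <- if (i == 1 && x[1] <= x[p]) min(x[1:p]) else lmin
    rmin <- x[p]; i <- p
    while (i < n && x[i + 1] <= x[p]) { i <- i + 1; rmin <- min(rmin, x[i]) }
    right_base <- if (i == n && x[n] <= x[p]) min(x[p:n]) else rmin
    (x[p] - max(left_base, right_base)) >= min_prom
  }, logical(1))
  cand[keep]
}

#' Segment a perfusion trace into cardiac cycles
#'
#' Cardiac cycles are delimited by successive systolic peaks of the chosen
#' signal (intensity by default: it pools area and velocity pulsation and is
#' the smoother of the two). A peak must have prominence of at least 20% of
#' the signal range, and consecutive peaks must be spaced consistently with a
#' heart rate inside `hr_bounds`. Frames before the first and after the last
#' accepted peak are discarded from cycle-based averaging.
#'
#' @param trace A [perfusion_trace()], or any tibble with columns `t` and the
#'   requested signal column.
#' @param hr_bounds Plausible heart-rate range, beats/min.
#' @param signal Column used for peak detection: `"intensity"` (default) or
#'   `"mean_v"` for a tissue trace; any other numeric column name works, e.g.
#'   the corrected velocity of a single-vessel trace.
#' @param min_prominence Peak prominence as a fraction of the signal range.
#' @return A tibble of class `cardiac_cycles` with columns `cycle`,
#'   `start_frame`, `end_frame` (half-open `[start, end)`), `vmax`, `vmin`
#'   (extrema of `mean_v`, or of the signal itself if `mean_v` is absent).
#'   Errors with `"no complete cardiac cycle"` when fewer than two valid peaks
#'   are found; wrappers catch this and fall back to whole-trace extrema.
#' @export
detect_cycles <- function(trace, hr_bounds = c(40, 180), signal = "intensity",
                          min_prominence = 0.2) {
  stopifnot(signal %in% names(trace), "t" %in% names(trace))
  x <- trace[[signal]]
  rng <- diff(range(x))
  if (rng <= 0) {
    abort("no complete cardiac cycle", class = "dopplerperf_error_cycles")
  }
  peaks <- find_peaks_(x, min_prom = min_prominence * rng)
  if (length(peaks) >= 2) {
    # enforce inter-peak spacing compatible with hr_bounds (greedy: keep the
    # higher of two peaks closer together than the fastest plausible heart)
    dt <- diff(trace$t[1:2])
    min_gap <- 60 / hr_bounds[2] / dt
    kept <- peaks[1]
    for (p in peaks[-1]) {
      if (p - kept[length(kept)] < min_gap) {
        if (x[p] > x[kept[length(kept)]]) kept[length(kept)] <- p
      } else kept <- c(kept, p)
    }
    peaks <- kept
  }
  if (length(peaks) < 2) {
    abort("no complete cardiac cycle", class = "dopplerperf_error_cycles")
  }
  dt <- diff(trace$t[1:2])
  max_gap <- 60 / hr_bounds[1] / dt
  v_col <- if ("mean_v" %in% names(trace)) "mean_v" else signal
  rows <- list()
  for (i in seq_len(length(peaks) - 1)) {
    s <- peaks[i]; e <- peaks[i + 1]
    if ((e - s) > max_gap) next
    seg <- trace[[v_col]][s:(e - 1)]
    rows[[length(rows) + 1]] <- tibble(
      start_frame = s, end_frame = e, vmax = max(seg), vmin = min(seg)
    )
  }
  if (length(rows) == 0) {
    abort("no complete cardiac cycle", class = "dopplerperf_error_cycles")
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, cycle = dplyr::row_number(), .before = 1)
  class(out) <- c("cardiac_cycles", class(out))
  out
}

#' Tissue perfusion parameters from a trace and its cardiac cycles
#'
#' Computes the three dynamic tissue-perfusion parameters over the union of
#' complete cardiac cycles:
#' \describe{
#'   \item{TFV}{tissue flow velocity, cm/s: time average of the per-frame mean
#'     speed.}
#'   \item{TRI}{tissue resistive index: `(vmax - vmin)/vmax` per cycle,
#'     averaged across cycles (0 for a cycle whose `vmax` is 0). A TRI of 1
#'     means diastolic no-flow — the hallmark of high-impedance malignant
#'     vasculature.}
#'   \item{TPI}{tissue perfusion intensity, cm/s: time average of the
#'     intensity signal, i.e. TFV weighted by the vascular fraction; always
#'     `<= TFV`.}
#' }
#'
#' @param trace A [perfusion_trace()].
#' @param cycles A `cardiac_cycles` tibble from [detect_cycles()], or `NULL`
#'   to fall back to whole-trace extrema (flagged, used when no complete cycle
#'   is detectable).
#' @return An object of class `dtpm_result` with fields `tfv`, `tri`, `tpi`,
#'   `n_cycles`, `fallback`.
#' @export
compute_dtpm <- function(trace, cycles) {
  if (nrow(trace) == 0) abort("empty input", class = "dopplerperf_error_input")
  fallback <- is.null(cycles) || nrow(cycles) == 0
  if (fallback) {
    frames <- trace$frame
    vmax <- max(trace$mean_v); vmin <- min(trace$mean_v)
    tri <- if (vmax > 0) (vmax - vmin) / vmax else 0
    n_cycles <- 0L
  } else {
    frames <- unique(unlist(lapply(seq_len(nrow(cycles)), function(i) {
      cycles$start_frame[i]:(cycles$end_frame[i] - 1)
    })))
    tri_i <- ifelse(cycles$vmax > 0, (cycles$vmax - cycles$vmin) / cycles$vmax, 0)
    tri <- mean(tri_i)
    n_cycles <- nrow(cycles)
  }
  sel <- trace$frame %in% frames
  structure(
    list(tfv = mean(trace$mean_v[sel]),
         tri = tri,
         tpi = mean(trace$intensity[sel]),
         n_cycles = n_cycles,
         fallback = fallback),
    class = "dtpm_result"
  )
}

#' Dynamic tissue perfusion measurement of a decoded cine
#'
#' Convenience wrapper: builds the perfusion trace, segments cardiac cycles
#' (falling back, with a warning, to whole-trace extrema when fewer than two
#' systolic peaks are detectable) and computes TFV/TRI/TPI.
#'
#' @inheritParams perfusion_trace
#' @inheritParams detect_cycles
#' @return A `dtpm_result`; see [compute_dtpm()].
#' @export
#' @examples
#' case <- synthesize_case(seed = 7)
#' dtpm(decode_cine(case$cine))
dtpm <- function(v_seq, hr_bounds = c(40, 180), signal = "intensity") {
  trace <- perfusion_trace(v_seq)
  cycles <- tryCatch(
    detect_cycles(trace, hr_bounds = hr_bounds, signal = signal),
    dopplerperf_error_cycles = function(e) {
      warn("no complete cardiac cycle: falling back to whole-trace extrema")
      NULL
    }
  )
  compute_dtpm(trace, cycles)
}

#' @export
print.dtpm_result <- function(x, ...) {
  cat(sprintf("<dtpm_result> TFV %.3f cm/s, TRI %.3f, TPI %.4f cm/s (%d cycles%s)\n",
              x$tfv, x$tri, x$tpi, x$n_cycles,
              if (x$fallback) ", whole-trace fallback" else ""))
  invisible(x)
}

#' @export
tidy.dtpm_result <- function(x, ...) {
  tibble(parameter = c("tfv", "tri", "tpi"),
         estimate = c(x$tfv, x$tri, x$tpi),
         unit = c("cm/s", "ratio", "cm/s"))
}

#' @export
glance.dtpm_result <- function(x, ...) {
  tibble(tfv = x$tfv, tri = x$tri, tpi = x$tpi,
         n_cycles = x$n_cycles, fallback = x$fallback)
}

#' Plot a perfusion trace with detected cycles
#'
#' @param object A [perfusion_trace()].
#' @param cycles Optional `cardiac_cycles` tibble; systolic peaks are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perfusion_trace <- function(object, cycles = NULL, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("mean_v", "intensity"),
                            names_to = "signal", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "cm/s")
  if (!is.null(cycles) && nrow(cycles) > 0) {
    pk <- object$t[unique(c(cycles$start_frame, cycles$end_frame))]
    p <- p + ggplot2::geom_vline(xintercept = pk, linetype = 2, colour = "red")
  }
  p
}
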