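# 4-connected component labeling via BFS over foreground pixels
label_components_ <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      nb <- c(if (r > 1) p - 1L, if (r < h) p + 1L,
              if (cc > 1) p - h, if (cc < w) p + h)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Candidate vessel segments in a velocity field sequence
#'
#' A pixel belongs to the temporal-maximum perfusion mask if it is perfused in
#' at least one frame. Its 4-connected components are the vessel candidates;
#' each is scored for flow-direction consistency: the fraction of frames (among
#' frames where the component carries any signal) in which the component's
#' modal velocity sign agrees with its overall modal sign. A steadily arterial
#' or venous vessel scores 1; an aliasing or bidirectional blob scores near
#' 0.5.
#'
#' @param v_seq A [velocity_field_sequence()].
#' @return A tibble with one row per candidate, ordered by decreasing size:
#'   `id`, `n_px`, `consistency`, and a list-column `mask` of logical
#'   matrices. Errors with `"no vessel visible"` when nothing is perfused in
#'   any frame (the pre-analysis exclusion criterion).
#' @export
segment_vessels <- function(v_seq) {
  stopifnot(inherits(v_seq, "velocity_field_sequence"))
  any_perf <- apply(is.finite(v_seq$fields), c(1, 2), any) & v_seq$roi_mask
  if (!any(any_perf)) {
    abort("no vessel visible", class = "dopplerperf_error_novessel")
  }
  lab <- label_components_(any_perf)
  ids <- seq_len(max(lab))
  d <- dim(v_seq$fields)
  npx <- d[1] * d[2]
  rows <- purrr::map(ids, function(id) {
    idx <- which(lab == id)
    # per-frame modal sign over the component
    signs <- vapply(seq_len(d[3]), function(i) {
      vals <- v_seq$fields[idx + (i - 1L) * npx]
      vals <- vals[is.finite(vals) & vals != 0]
      if (length(vals) == 0) return(NA_real_)
      s <- sum(sign(vals))
      if (s > 0) 1 else if (s < 0) -1 else 0
    }, numeric(1))
    signs <- signs[!is.na(signs)]
    consistency <- if (length(signs) == 0) 0 else max(mean(signs > 0), mean(signs < 0))
    m <- matrix(FALSE, d[1], d[2]); m[idx] <- TRUE
    tibble(id = id, n_px = length(idx), consistency = consistency, mask = list(m))
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$n_px))
}

#' Select the measurement vessel
#'
#' The single-vessel method measures the largest vessel whose flow direction
#' is known; operationally, the largest candidate whose direction-consistency
#' score reaches `consistency_threshold`.
#'
#' @param candidates Output of [segment_vessels()].
#' @param consistency_threshold Minimum direction-consistency (default 0.8).
#' @return A list of class `vessel_segment` with the mask and bookkeeping
#'   fields (axis/angle/diameter filled in by [estimate_axis_and_angle()]).
#'   Errors with `"no vessel with known flow direction"` when no candidate
#'   qualifies — such a case is excluded from single-vessel analysis but stays
#'   eligible for tissue perfusion analysis.
#' @export
select_largest_vessel <- function(candidates, consistency_threshold = 0.8) {
  stopifnot(nrow(candidates) >= 1)
  ok <- candidates$consistency >= consistency_threshold
  if (!any(ok)) {
    abort("no vessel with known flow direction",
          class = "dopplerperf_error_direction")
  }
  row <- candidates[ok, ][1, ]     # candidates are size-ordered
  structure(
    list(mask = row$mask[[1]], n_px = row$n_px,
         consistency = row$consistency, direction_known = TRUE,
         axis = NULL, angle_deg = NULL, diameter = NULL),
    class = "vessel_segment"
  )
}

#' Vessel axis, Doppler angle and diameter from a segment mask
#'
#' The vessel axis is the principal direction of the mask's pixel coordinates;
#' the Doppler angle is the angle between that axis and the beam axis, folded
#' into \[0, 90\] degrees. The diameter is the mean extent perpendicular to the
#' axis, `mask area / axis length` — an average width, less sensitive to
#' pixelation than a single perpendicular profile.
#'
#' @param mask Logical `H x W` vessel mask with at least 3 pixels.
#' @param pixel_spacing cm/pixel.
#' @param beam_axis Unit 2-vector `(x, y)` in image coordinates.
#' @return A list with `axis` (unit 2-vector), `angle_deg`, `diameter` (cm),
#'   `length` (cm).
#' @export
estimate_axis_and_angle <- function(mask, pixel_spacing, beam_axis = c(0, -1)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) abort("axis undefined", class = "dopplerperf_error_axis")
  # (x, y) with x = column, y = row (grows downward)
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  if (nrow(unique(xy)) < 2) abort("axis undefined", class = "dopplerperf_error_axis")
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  axis <- eg$vectors[, 1]
  axis <- axis / sqrt(sum(axis^2))
  beam_axis <- beam_axis / sqrt(sum(beam_axis^2))
  angle_deg <- acos(pmin(1, abs(sum(axis * beam_axis)))) * 180 / pi
  proj <- xy %*% axis
  len <- (max(proj) - min(proj) + 1) * pixel_spacing
  area <- nrow(xy) * pixel_spacing^2
  list(axis = axis, angle_deg = as.numeric(angle_deg),
       diameter = area / len, length = len)
}

#' Angle-corrected spectral velocity trace of a vessel
#'
#' Approximates a pulsed-wave gate on the vessel: per frame, the peak speed
#' over the segment pixels (the spectral envelope is conventionally defined on
#' the peak, not the mean), divided by `cos(angle)` to recover the true flow
#' speed from its beam-projected measurement. Frames where the vessel carries
#' no signal contribute 0 (diastolic no-flow).
#'
#' Correction is only physically trustworthy up to 60 degrees; beyond that the
#' `1/cos` factor amplifies small angle errors into large velocity errors, so
#' the trace is still computed but flagged `angle_valid = FALSE`. At 90
#' degrees flow is perpendicular to the beam and unmeasurable.
#'
#' @param segment A `vessel_segment` with `angle_deg` set (see
#'   [estimate_axis_and_angle()]), or a list with `mask` and `angle_deg`.
#' @param v_seq A [velocity_field_sequence()].
#' @param angle_cap Validity cap in degrees (default 60).
#' @return A tibble with columns `frame`, `t`, `measured` (peak speed, cm/s)
#'   and `corrected`; attribute `angle_valid`.
#' @export
spectral_trace <- function(segment, v_seq, angle_cap = 60) {
  angle <- segment$angle_deg
  stopifnot(is.numeric(angle), length(angle) == 1)
  if (angle >= 89.5) {
    abort("unmeasurable: flow perpendicular to beam",
          class = "dopplerperf_error_angle")
  }
  d <- dim(v_seq$fields)
  npx <- d[1] * d[2]
  idx <- which(segment$mask)
  measured <- vapply(seq_len(d[3]), function(i) {
    vals <- v_seq$fields[idx + (i - 1L) * npx]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) 0 else max(abs(vals))
  }, numeric(1))
  out <- tibble(
    frame = seq_len(d[3]),
    t = (seq_len(d[3]) - 1) / v_seq$frame_rate,
    measured = measured,
    corrected = measured / cos(angle * pi / 180)
  )
  attr(out, "angle_valid") <- angle <= angle_cap
  attr(out, "angle_deg") <- angle
  out
}

#' Single-vessel flow parameters from a corrected trace
#'
#' Per cardiac cycle, PSV and EDV are the extrema of the corrected trace;
#' `ri = mean((PSV - EDV)/PSV)` across cycles (the resistive index is
#' insensitive to angle correction because numerator and denominator scale
#' together), `fv` is the time-averaged corrected velocity over complete
#' cycles, and `volf = fv * pi * (diameter/2)^2` in mL/s (1 cm^3 = 1 mL).
#'
#' @param trace Output of [spectral_trace()].
#' @param cycles A `cardiac_cycles` tibble from [detect_cycles()] run on the
#'   corrected trace, or `NULL` for the whole-trace fallback.
#' @param diameter Vessel diameter, cm.
#' @param angle_deg Doppler angle used for the correction (reported).
#' @param angle_cap Validity cap in degrees.
#' @return An object of class `svfm_result` with fields `fv`, `ri`, `volf`,
#'   `angle_deg`, `angle_valid`, `n_cycles`, `fallback`.
#' @export
compute_svfm <- function(trace, cycles, diameter, angle_deg = NA_real_,
                         angle_cap = 60) {
  if (nrow(trace) == 0) abort("empty input", class = "dopplerperf_error_input")
  fallback <- is.null(cycles) || nrow(cycles) == 0
  if (fallback) {
    frames <- trace$frame
    psv <- max(trace$corrected); edv <- min(trace$corrected)
    ri <- if (psv > 0) (psv - edv) / psv else 0
    n_cycles <- 0L
  } else {
    frames <- unique(unlist(lapply(seq_len(nrow(cycles)), function(i) {
      cycles$start_frame[i]:(cycles$end_frame[i] - 1)
    })))
    ri_i <- ifelse(cycles$vmax > 0, (cycles$vmax - cycles$vmin) / cycles$vmax, 0)
    ri <- mean(ri_i)
    n_cycles <- nrow(cycles)
  }
  fv <- mean(trace$corrected[trace$frame %in% frames])
  structure(
    list(fv = fv, ri = ri, volf = fv * pi * (diameter / 2)^2,
         diameter = diameter, angle_deg = angle_deg,
         angle_valid = isTRUE(is.na(angle_deg)) || angle_deg <= angle_cap,
         n_cycles = n_cycles, fallback = fallback),
    class = "svfm_result"
  )
}

#' Single-vessel flow measurement of a decoded cine
#'
#' End-to-end wrapper: segments vessel candidates, selects the largest one
#' with a known flow direction, estimates its axis and Doppler angle, builds
#' the angle-corrected spectral trace, segments cardiac cycles on it and
#' computes FV/RI/VolF.
#'
#' @param v_seq A [velocity_field_sequence()].
#' @param beam_axis Insonation direction, image coordinates.
#' @param consistency_threshold Passed to [select_largest_vessel()].
#' @param angle_cap Angle validity cap, degrees.
#' @param hr_bounds Heart-rate range for cycle detection, beats/min.
#' @return An `svfm_result`; see [compute_svfm()].
#' @export
#' @examples
#' case <- synthesize_case(seed = 7)
#' svfm(decode_cine(case$cine))
svfm <- function(v_seq, beam_axis = c(0, -1), consistency_threshold = 0.8,
                 angle_cap = 60, hr_bounds = c(40, 180)) {
  candidates <- segment_vessels(v_seq)
  seg <- select_largest_vessel(candidates, consistency_threshold)
  geo <- estimate_axis_and_angle(seg$mask, v_seq$pixel_spacing, beam_axis)
  seg$axis <- geo$axis; seg$angle_deg <- geo$angle_deg; seg$diameter <- geo$diameter
  trace <- spectral_trace(seg, v_seq, angle_cap = angle_cap)
  cycles <- tryCatch(
    detect_cycles(trace, hr_bounds = hr_bounds, signal = "corrected"),
    dopplerperf_error_cycles = function(e) {
      warn("no complete cardiac cycle: falling back to whole-trace extrema")
      NULL
    }
  )
  compute_svfm(trace, cycles, diameter = geo$diameter,
               angle_deg = geo$angle_deg, angle_cap = angle_cap)
}

#' @export
print.svfm_result <- function(x, ...) {
  cat(sprintf(
    "<svfm_result> FV %.3f cm/s, RI %.3f, VolF %.4f mL/s (angle %.1f deg%s, %d cycles%s)\n",
    x$fv, x$ri, x$volf, x$angle_deg,
    if (x$angle_valid) "" else ", INVALID > cap", x$n_cycles,
    if (x$fallback) ", whole-trace fallback" else ""))
  invisible(x)
}

#' @export
tidy.svfm_result <- function(x, ...) {
  tibble(parameter = c("fv", "ri", "volf"),
         estimate = c(x$fv, x$ri, x$volf),
         unit = c("cm/s", "ratio", "mL/s"))
}

#' @export
glance.svfm_result <- function(x, ...) {
  tibble(fv = x$fv, ri = x$ri, volf = x$volf, diameter = x$diameter,
         angle_deg = x$angle_deg, angle_valid = x$angle_valid,
         n_cycles = x$n_cycles, fallback = x$fallback)
}
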