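#' Velocity field sequence
#'
#' Decoded counterpart of a cine sequence: one signed velocity map (cm/s) per
#' frame, `NaN` wherever a pixel is not perfused (gray B-mode background or
#' outside the ROI), plus the acquisition constants needed downstream.
#'
#' @param fields Numeric array `H x W x T` of signed velocities with `NaN` at
#'   non-perfused pixels.
#' @param roi_mask Logical `H x W` mask.
#' @param frame_rate Hz.
#' @param pixel_spacing cm/pixel.
#' @return An object of class `velocity_field_sequence`.
#' @export
velocity_field_sequence <- function(fields, roi_mask, frame_rate, pixel_spacing) {
  stopifnot(is.array(fields), length(dim(fields)) == 3)
  roi_mask <- as.matrix(roi_mask) > 0
  stopifnot(identical(dim(roi_mask), dim(fields)[1:2]),
            frame_rate > 0, pixel_spacing > 0)
  structure(
    list(fields = fields, roi_mask = roi_mask,
         frame_rate = frame_rate, pixel_spacing = pixel_spacing),
    class = "velocity_field_sequence"
  )
}

#' @export
print.velocity_field_sequence <- function(x, ...) {
  d <- dim(x$fields)
  cat(sprintf(
    "<velocity_field_sequence> %d frames of %dx%d, %.1f Hz, %.3g cm/px, %.1f%% perfused\n",
    d[3], d[1], d[2], x$frame_rate, x$pixel_spacing,
    100 * mean(is.finite(x$fields))))
  invisible(x)
}

#' Decode one color-Doppler frame into a velocity map
#'
#' A pixel counts as perfused when its chroma `max(R,G,B) - min(R,G,B)`
#' exceeds `chroma_threshold` (the B-mode background is gray, i.e. zero
#' chroma) and it lies inside the ROI. Perfused pixels take the velocity of
#' the nearest LUT color in Euclidean RGB distance; distance ties resolve
#' towards the smaller speed so that decoding never inflates perfusion.
#' Everything else is `NaN`.
#'
#' @param rgb Integer `H x W x 3` array, 0--255.
#' @param lut A `color_lut`.
#' @param roi Optional logical `H x W` mask; `NULL` means the full frame.
#' @param chroma_threshold Chroma above which a pixel is treated as colored
#'   (default 24 of 255).
#' @return Numeric `H x W` matrix of signed velocities with `NaN` at
#'   non-perfused pixels.
#' @export
decode_frame <- function(rgb, lut, roi = NULL, chroma_threshold = 24) {
  stopifnot(inherits(lut, "color_lut"), length(dim(rgb)) == 3)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  if (!identical(dim(roi), c(h, w))) {
    abort("inconsistent frames: ROI shape mismatch",
          class = "dopplerperf_error_frames")
  }
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  chroma <- pmax(r, g, b) - pmin(r, g, b)
  cand <- which(roi & chroma > chroma_threshold)
  out <- matrix(NaN, h, w)
  if (length(cand) == 0) return(out)
  key <- r[cand] * 65536 + g[cand] * 256 + b[cand]
  hit <- match(key, lut$key)
  exact <- !is.na(hit)
  out[cand[exact]] <- lut$velocity[hit[exact]]
  rest <- cand[!exact]
  if (length(rest) > 0) {
    # nearest LUT color; LUT columns ordered by |velocity| so that
    # ties.method = "first" breaks distance ties towards the smaller speed
    ord <- order(abs(lut$velocity), lut$velocity)
    m <- t(lut$rgb[ord, , drop = FALSE])
    px <- cbind(r[rest], g[rest], b[rest])
    d2 <- outer(rowSums(px^2), colSums(m^2), "+") - 2 * (px %*% m)
    idx <- max.col(-d2, ties.method = "first")
    out[rest] <- lut$velocity[ord][idx]
  }
  out
}

#' Render a velocity map as a color-Doppler overlay
#'
#' Inverse of [decode_frame()], used by the synthetic generator: every finite
#' pixel is painted with the color of the nearest LUT velocity, `NaN` pixels
#' copy the grayscale background.
#'
#' @param v Numeric `H x W` velocity map (cm/s), `NaN` = not perfused.
#' @param lut A `color_lut`.
#' @param background `H x W` grayscale matrix (0--255) or `H x W x 3` array.
#' @return Integer `H x W x 3` array, 0--255.
#' @export
encode_frame <- function(v, lut, background) {
  stopifnot(inherits(lut, "color_lut"))
  h <- nrow(v); w <- ncol(v)
  if (length(dim(background)) == 2) {
    bg <- array(as.integer(round(background)), c(h, w, 3))
  } else {
    bg <- background
  }
  stopifnot(identical(dim(bg)[1:2], c(h, w)))
  out <- bg
  storage.mode(out) <- "integer"
  fin <- which(is.finite(v))
  if (length(fin) == 0) return(out)
  vv <- v[fin]
  if (any(abs(vv) > max(abs(lut$velocity)) + 1e-9)) {
    abort("out of colorbar range", class = "dopplerperf_error_lut")
  }
  vs <- lut$velocity                     # sorted ascending by build_lut
  mids <- (vs[-1] + vs[-length(vs)]) / 2
  idx <- findInterval(vv, mids) + 1L
  npx <- h * w
  out[fin] <- lut$rgb[idx, 1]
  out[fin + npx] <- lut$rgb[idx, 2]
  out[fin + 2L * npx] <- lut$rgb[idx, 3]
  out
}

#' Decode a whole cine sequence
#'
#' Applies [decode_frame()] to every frame using the sequence's own LUT and
#' ROI, yielding the [velocity_field_sequence()] all perfusion and
#' single-vessel analysis operates on.
#'
#' @param seq A [cine_sequence()].
#' @param chroma_threshold Passed to [decode_frame()].
#' @return A `velocity_field_sequence`.
#' @export
decode_cine <- function(seq, chroma_threshold = 24) {
  stopifnot(inherits(seq, "cine_sequence"))
  d <- dim(seq$frames)
  fields <- array(NaN, c(d[1], d[2], d[4]))
  for (i in seq_len(d[4])) {
    fields[, , i] <- decode_frame(seq$frames[, , , i], seq$calibration$lut,
                                  roi = seq$roi_mask,
                                  chroma_threshold = chroma_threshold)
  }
  velocity_field_sequence(fields, seq$roi_mask,
                          frame_rate = seq$calibration$frame_rate,
                          pixel_spacing = seq$calibration$pixel_spacing)
}
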