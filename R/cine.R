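#' Color-Doppler cine sequence
#'
#' Container for one lesion recording: an RGB frame stack, its acquisition
#' calibration, the region-of-interest mask drawn over the lesion, a case
#' identifier and the histological label.
#'
#' @param frames Integer array `H x W x 3 x T` with values in 0--255, or a list
#'   of `H x W x 3` arrays (one per frame).
#' @param calibration A [calibration()] object.
#' @param roi_mask Logical `H x W` matrix with at least one `TRUE` pixel.
#' @param case_id Character scalar.
#' @param label One of `"malignant"`, `"inflammatory"`, `"unknown"`.
#'
#' @details Analysis expects clip durations between 1 and 30 s (clinical
#' recordings are typically 3--5 s); durations outside that range are rejected
#' as a calibration/recording error.
#'
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, calibration, roi_mask,
                          case_id = "case", label = "unknown") {
  if (is.list(frames)) {
    dims <- vapply(frames, function(f) dim(f)[1:2], numeric(2))
    if (length(frames) == 0 || any(dims[1, ] != dims[1, 1]) ||
        any(dims[2, ] != dims[2, 1])) {
      abort("inconsistent frames", class = "dopplerperf_error_frames")
    }
    arr <- array(0L, c(dims[1, 1], dims[2, 1], 3, length(frames)))
    for (i in seq_along(frames)) arr[, , , i] <- frames[[i]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 4 || dim(frames)[3] != 3) {
    abort("inconsistent frames", class = "dopplerperf_error_frames")
  }
  storage.mode(frames) <- "integer"
  if (anyNA(frames) || min(frames) < 0L || max(frames) > 255L) {
    abort("inconsistent frames: values outside 0-255",
          class = "dopplerperf_error_frames")
  }
  if (!inherits(calibration, "doppler_calibration")) {
    abort("calibration invalid", class = "dopplerperf_error_calibration")
  }
  roi_mask <- as.matrix(roi_mask)
  if (!is.logical(roi_mask)) roi_mask <- roi_mask > 0
  if (!identical(dim(roi_mask), dim(frames)[1:2])) {
    abort("inconsistent frames: ROI shape mismatch",
          class = "dopplerperf_error_frames")
  }
  if (!any(roi_mask)) abort("degenerate ROI", class = "dopplerperf_error_roi")
  label <- match.arg(label, c("malignant", "inflammatory", "unknown"))
  n_frames <- dim(frames)[4]
  duration <- n_frames / calibration$frame_rate
  if (duration < 1 || duration > 30) {
    abort(sprintf("calibration invalid: clip duration %.2f s outside [1, 30] s",
                  duration),
          class = "dopplerperf_error_calibration")
  }
  structure(
    list(frames = frames, calibration = calibration, roi_mask = roi_mask,
         case_id = as.character(case_id), label = label),
    class = "cine_sequence"
  )
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_sequence> %s [%s]: %d frames of %dx%d, %.2f s, ROI %d px\n",
              x$case_id, x$label, d[4], d[1], d[2],
              d[4] / x$calibration$frame_rate, sum(x$roi_mask)))
  invisible(x)
}

#' Number of frames in a cine sequence
#' @param seq A `cine_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[4]

lut_to_json_ <- function(lut) {
  lapply(seq_along(lut$velocity),
         function(i) list(as.integer(lut$rgb[i, ]), lut$velocity[i]))
}

lut_from_json_ <- function(pairs) {
  rgb <- t(vapply(pairs, function(p) as.integer(unlist(p[[1]])), integer(3)))
  build_lut(data.frame(r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                       velocity = vapply(pairs, function(p) as.numeric(p[[2]]),
                                         numeric(1))))
}

#' Write a cine sequence to a case directory
#'
#' Serializes the sequence losslessly: `frames.tif` (multi-page 8-bit RGB TIFF,
#' deflate compression), `calibration.json` (pixel spacing, frame rate, beam
#' axis, the LUT as ordered `[[R,G,B], velocity]` pairs, case id and label) and
#' `roi.png` (8-bit 0/255 mask). An optional ground-truth sidecar is written as
#' `truth.json` for synthetic cases.
#'
#' Lossless storage is not a nicety here: velocity decoding is LUT-exact, so a
#' lossy codec would corrupt the decoded velocity field.
#'
#' @param seq A [cine_sequence()].
#' @param path Case directory (created if missing).
#' @param truth Optional named list of ground-truth values (synthetic cases).
#' @return `path`, invisibly.
#' @seealso [read_cine()]
#' @export
write_cine <- function(seq, path, truth = NULL) {
  stopifnot(inherits(seq, "cine_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(seq$frames)
  pages <- lapply(seq_len(d[4]), function(i) seq$frames[, , , i] / 255)
  tiff::writeTIFF(pages, file.path(path, "frames.tif"),
                  bits.per.sample = 8L, compression = "deflate")
  png::writePNG(ifelse(seq$roi_mask, 1, 0), file.path(path, "roi.png"))
  cal <- seq$calibration
  side <- list(
    pixel_spacing = cal$pixel_spacing,
    frame_rate = cal$frame_rate,
    beam_axis = cal$beam_axis,
    lut = lut_to_json_(cal$lut),
    case_id = seq$case_id,
    label = seq$label
  )
  jsonlite::write_json(side, file.path(path, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- truth
    if (!is.null(tr$vessel_mask)) {
      tr$vessel_mask_idx <- which(tr$vessel_mask)
      tr$vessel_mask_dim <- dim(tr$vessel_mask)
      tr$vessel_mask <- NULL
    }
    jsonlite::write_json(tr, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cine sequence from a case directory
#'
#' Inverse of [write_cine()]: expects `frames.tif`, `calibration.json` and
#' `roi.png` in `path`. All container invariants are re-validated on read, and
#' the round trip `read_cine(write_cine(seq))` reproduces frames, ROI,
#' calibration and label exactly.
#'
#' @param path Case directory.
#' @return A `cine_sequence`. If a `truth.json` sidecar exists it is attached
#'   as attribute `"truth"` (with any vessel mask re-inflated to a logical
#'   matrix).
#' @export
read_cine <- function(path) {
  fr_path <- file.path(path, "frames.tif")
  cal_path <- file.path(path, "calibration.json")
  roi_path <- file.path(path, "roi.png")
  if (!file.exists(cal_path)) {
    abort("calibration missing", class = "dopplerperf_error_calibration")
  }
  if (!file.exists(fr_path) || !file.exists(roi_path)) {
    abort("inconsistent frames: missing frames.tif or roi.png",
          class = "dopplerperf_error_frames")
  }
  side <- jsonlite::read_json(cal_path)
  if (is.null(side$pixel_spacing) || is.null(side$frame_rate) ||
      is.null(side$lut)) {
    abort("calibration invalid", class = "dopplerperf_error_calibration")
  }
  cal <- calibration(
    pixel_spacing = as.numeric(side$pixel_spacing),
    frame_rate = as.numeric(side$frame_rate),
    lut = lut_from_json_(side$lut),
    beam_axis = as.numeric(unlist(side$beam_axis %||% c(0, -1)))
  )
  pages <- tiff::readTIFF(fr_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 2) p <- array(rep(p, 3), c(dim(p), 3))
    round(p[, , 1:3] * 255)
  })
  roi <- png::readPNG(roi_path)
  if (length(dim(roi)) == 3) roi <- roi[, , 1]
  roi <- roi > 0.5
  out <- cine_sequence(frames, cal, roi,
                       case_id = side$case_id %||% basename(path),
                       label = side$label %||% "unknown")
  truth_path <- file.path(path, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(tr$vessel_mask_idx)) {
      m <- matrix(FALSE, tr$vessel_mask_dim[1], tr$vessel_mask_dim[2])
      m[tr$vessel_mask_idx] <- TRUE
      tr$vessel_mask <- m
      tr$vessel_mask_idx <- NULL
      tr$vessel_mask_dim <- NULL
    }
    attr(out, "truth") <- tr
  }
  out
}
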