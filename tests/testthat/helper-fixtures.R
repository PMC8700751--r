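# small 4+4-entry colorbar for unit tests
tiny_lut <- function() {
  build_lut(data.frame(
    r = c(0, 0, 0, 0, 255, 255, 255, 255),
    g = c(0, 60, 120, 180, 180, 120, 60, 0),
    b = c(255, 255, 255, 255, 0, 0, 0, 0),
    velocity = c(-8, -4, -2, -1, 1, 2, 4, 8)
  ))
}

# uniform-color test frame
flat_frame <- function(h, w, rgb) {
  arr <- array(0L, c(h, w, 3))
  arr[, , 1] <- rgb[1]; arr[, , 2] <- rgb[2]; arr[, , 3] <- rgb[3]
  arr
}

# minimal valid cine: n gray frames with one colored pixel
tiny_cine <- function(n_frames = 2, frame_rate = 1, h = 4, w = 4,
                      lut = tiny_lut(), label = "unknown") {
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- flat_frame(h, w, c(120, 120, 120))
    f[2, 2, ] <- lut$rgb[length(lut$velocity), ]   # fastest positive color
    f
  })
  cine_sequence(frames,
                calibration(pixel_spacing = 0.01, frame_rate = frame_rate,
                            lut = lut),
                matrix(TRUE, h, w), case_id = "tiny", label = label)
}

# velocity field sequence built directly from a list of velocity matrices
vfs_from_fields <- function(fields, roi = NULL, frame_rate = 15,
                            pixel_spacing = 0.01) {
  h <- nrow(fields[[1]]); w <- ncol(fields[[1]])
  arr <- array(NaN, c(h, w, length(fields)))
  for (i in seq_along(fields)) arr[, , i] <- fields[[i]]
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  velocity_field_sequence(arr, roi, frame_rate, pixel_spacing)
}

# brute-force pairwise-concordance AUC oracle (higher score => positive)
auc_bruteforce <- function(values, positive) {
  x <- values[positive]; y <- values[!positive]
  s <- 0
  for (xi in x) for (yi in y) s <- s + (xi > yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}

# internal rasterizer, reachable from tests for geometry oracles
rasterize_vessel_dbg <- function(...) dopplerperf:::rasterize_vessel_(...)

# generative parameters of a small, fast test lesion (high vascular fraction
# keeps the ROI small); override fields as needed
small_params <- function(...) {
  utils::modifyList(
    list(tfv = 2.5, tpi = 0.05, fv = 3.2, volf = 0.03, tri = 0.75, ri = 0.82,
         heart_rate = 75, angle_deg = 40, noise_sd = 0, duration_s = 3),
    list(...)
  )
}
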