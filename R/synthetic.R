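#' Cardiac waveform as per-frame scale factors
#'
#' A periodic raised-cosine pulse train with maximum 1 at systole and minimum
#' `pulsatility` at end-diastole; period `60/heart_rate` seconds. The
#' generated tissue resistive index of a lesion driven by this waveform is
#' `1 - pulsatility`: a pulsatility of 0 produces the diastolic no-flow state
#' characteristic of high-impedance malignant vasculature.
#'
#' @param heart_rate Beats per minute.
#' @param frame_rate Hz; must resolve the cycle (`frame_rate >= 2 *
#'   heart_rate / 60`).
#' @param n_frames Number of frames.
#' @param pulsatility Diastolic floor in \[0, 1\].
#' @return Numeric vector of length `n_frames` in `[pulsatility, 1]`, starting
#'   at end-diastole.
#' @export
#' @examples
#' w <- make_waveform(72, 15, 75, pulsatility = 0.2)
#' range(w)
make_waveform <- function(heart_rate, frame_rate, n_frames, pulsatility) {
  stopifnot(heart_rate > 0, n_frames >= 1,
            pulsatility >= 0, pulsatility <= 1)
  if (frame_rate < 2 * heart_rate / 60) {
    abort("frame rate too low", class = "dopplerperf_error_waveform")
  }
  u <- (seq_len(n_frames) - 1) / frame_rate * heart_rate / 60
  pulsatility + (1 - pulsatility) * (1 - cos(2 * pi * u)) / 2
}

# log-normal solved from a printed median and IQR: the median is matched
# exactly, sigma is the least-squares fit to the two quartiles
lnorm_fit_ <- function(med, q1, q3) {
  c(mu = log(med), sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

#' Cohort calibration for the synthetic generator
#'
#' Per-label distributions of the generative lesion parameters, calibrated so
#' that the six measured flow parameters reproduce the published group
#' summaries of malignant vs inflammatory pancreatic lesions: tissue flow
#' velocity is normal (the one parameter reported as mean ± SD), the skewed
#' positive parameters (TPI, FV, VolF) are log-normal solved from median and
#' IQR, and the resistive indices use bounded families on \[0, 1\] — the
#' malignant groups a point mass at 1 (degenerate quartiles, diastolic
#' no-flow) with a small lower tail, the inflammatory groups logit-normal
#' (with a ceiling mass at 1 for the single-vessel RI whose upper quartile is
#' 1).
#'
#' Within a case the four flow-scale parameters share one latent quantile and
#' the two resistive indices another (comonotone coupling): a lesion that is
#' hypovascular by one measure is hypovascular by all, which keeps joint
#' constraints (TPI below TFV, a realizable vessel diameter) almost always
#' feasible and mirrors that all six parameters measure one vascular bed.
#'
#' @param tfv,tpi,fv,volf Per-label distribution parameters; see defaults.
#' @param resist_mal_mass Point mass at 1 for the malignant resistive indices.
#' @param resist_mal_tail Range of the malignant lower tail.
#' @param ri_inf_ceiling Mass at 1 for the inflammatory single-vessel RI.
#' @param heart_rate Mean and SD of the heart rate, bpm.
#' @param angle Mean, SD and truncation of the Doppler angle draw, degrees.
#' @param noise_sd RGB noise SD added to rendered frames (0 = noiseless).
#' @param duration_s Clip duration in seconds.
#' @return A list of class `cohort_calibration`.
#' @export
cohort_calibration <- function(
    tfv = list(malignant = c(mean = 1.422, sd = 0.742),
               inflammatory = c(mean = 2.653, sd = 0.733)),
    tpi = list(malignant = lnorm_fit_(0.004, 0.001, 0.007),
               inflammatory = lnorm_fit_(0.016, 0.010, 0.024)),
    fv = list(malignant = lnorm_fit_(1.592, 0.953, 3.148),
              inflammatory = lnorm_fit_(3.397, 2.696, 4.350)),
    volf = list(malignant = lnorm_fit_(0.010, 0.004, 0.035),
                inflammatory = lnorm_fit_(0.032, 0.022, 0.059)),
    resist_mal_mass = 0.80,
    resist_mal_tail = c(0.40, 0.85),
    ri_inf_ceiling = 0.28,
    heart_rate = c(mean = 75, sd = 8),
    angle = c(mean = 48.7, sd = 19.1, lo = 5, hi = 60),
    noise_sd = 0,
    duration_s = 3) {
  # inflammatory TRI: logit-normal through the printed median and quartiles
  tri_inf <- c(
    mu = qlogis(0.776),
    sigma = (qlogis(0.880) - qlogis(0.601)) / (2 * qnorm(0.75))
  )
  # inflammatory RI: ceiling mass at 1 (upper quartile is 1.000), logit-normal
  # below, solved from the overall median and lower quartile
  pc <- 1 - ri_inf_ceiling
  z_med <- qnorm(0.5 / pc); z_q1 <- qnorm(0.25 / pc)
  sig <- (qlogis(0.843) - qlogis(0.648)) / (z_med - z_q1)
  ri_inf <- c(mu = qlogis(0.843) - z_med * sig, sigma = sig,
              ceiling = ri_inf_ceiling)
  structure(
    list(tfv = tfv, tpi = tpi, fv = fv, volf = volf,
         tri_inf = tri_inf, ri_inf = ri_inf,
         resist_mal_mass = resist_mal_mass, resist_mal_tail = resist_mal_tail,
         heart_rate = heart_rate, angle = angle,
         noise_sd = noise_sd, duration_s = duration_s),
    class = "cohort_calibration"
  )
}

q_resist_mal_ <- function(u, mass, tail) {
  ifelse(u < 1 - mass, tail[1] + diff(tail) * u / (1 - mass), 1)
}

q_tri_inf_ <- function(u, par) plogis(qnorm(u) * par["sigma"] + par["mu"])

q_ri_inf_ <- function(u, par) {
  pc <- 1 - par["ceiling"]
  ifelse(u >= pc, 1, plogis(qnorm(pmin(u, pc - 1e-12) / pc) * par["sigma"] +
                              par["mu"]))
}

# draw one case's generative parameters; redraw until jointly feasible
draw_case_params_ <- function(label, calib) {
  for (i in 1:200) {
    u_flow <- runif(1); u_res <- runif(1)
    g <- if (label == "malignant") "malignant" else "inflammatory"
    # physical floors are applied by clipping the marginal, not by rejecting
    # the joint draw: rejection would drag every comonotone median upward
    tfv <- max(qnorm(u_flow, calib$tfv[[g]]["mean"], calib$tfv[[g]]["sd"]),
               0.15)
    tpi <- qlnorm(u_flow, calib$tpi[[g]]["mu"], calib$tpi[[g]]["sigma"])
    fv <- min(max(qlnorm(u_flow, calib$fv[[g]]["mu"], calib$fv[[g]]["sigma"]),
                  0.3), 10)
    volf <- qlnorm(u_flow, calib$volf[[g]]["mu"], calib$volf[[g]]["sigma"])
    if (label == "malignant") {
      tri <- q_resist_mal_(u_res, calib$resist_mal_mass, calib$resist_mal_tail)
      ri <- q_resist_mal_(u_res, calib$resist_mal_mass, calib$resist_mal_tail)
    } else {
      tri <- q_tri_inf_(u_res, calib$tri_inf)
      ri <- q_ri_inf_(u_res, calib$ri_inf)
    }
    d <- 2 * sqrt(volf / (pi * fv))
    ok <- tpi <= 0.5 * tfv && d >= 0.03 && d <= 0.35
    if (ok) {
      hr <- min(max(rnorm(1, calib$heart_rate["mean"], calib$heart_rate["sd"]),
                    55), 105)
      ang <- min(max(rnorm(1, calib$angle["mean"], calib$angle["sd"]),
                     calib$angle["lo"]), calib$angle["hi"])
      return(tibble(tfv = tfv, tpi = tpi, fv = fv, volf = volf,
                    tri = unname(tri), ri = unname(ri), heart_rate = hr,
                    angle_deg = unname(ang), noise_sd = calib$noise_sd,
                    duration_s = calib$duration_s, redraws = i - 1L))
    }
  }
  abort("geometry infeasible: no feasible parameter draw",
        class = "dopplerperf_error_geometry")
}

#' Draw the ground-truth parameter table of a calibrated cohort
#'
#' Samples per-case generative parameters (the six flow parameters plus heart
#' rate and Doppler angle) for a labeled cohort from a [cohort_calibration()],
#' without rendering any frames. [generate_cohort()] feeds these draws to
#' [synthesize_case()]; drawing them alone is the cheap way to study the
#' calibrated parameter distributions at scale.
#'
#' @param n_malignant,n_inflammatory Cases per label (the study cohort was
#'   40 / 29).
#' @param calib A [cohort_calibration()].
#' @param seed Integer seed; the draw is deterministic given `(calib, seed)`.
#' @return A tibble with columns `case_id`, `label`, `seed_case`, the six
#'   parameters `tfv`, `tri`, `tpi`, `fv`, `ri`, `volf`, and `heart_rate`,
#'   `angle_deg`, `noise_sd`, `duration_s`.
#' @export
#' @examples
#' draw_cohort_params(3, 3, seed = 1)
draw_cohort_params <- function(n_malignant = 40, n_inflammatory = 29,
                               calib = cohort_calibration(), seed = 1) {
  stopifnot(n_malignant >= 1, n_inflammatory >= 1)
  labels <- c(rep("malignant", n_malignant), rep("inflammatory", n_inflammatory))
  seeds <- derive_seeds_(seed, length(labels))
  with_seed_(seed, {
    rows <- purrr::map(seq_along(labels), function(i) {
      dplyr::mutate(draw_case_params_(labels[i], calib),
                    case_id = sprintf("case_%03d", i), label = labels[i],
                    seed_case = seeds[i], .before = 1)
    })
    dplyr::bind_rows(rows)
  })
}

# rasterize a straight vessel segment: integer pixel offsets around (0, 0)
# with a parabolic cross-profile, ordered by decreasing profile
rasterize_vessel_ <- function(length_px, diam_px, angle_deg, side_sign = 1,
                              profile_floor = 0.02) {
  a <- angle_deg * pi / 180
  ux <- sin(a) * side_sign; uy <- -cos(a)
  ext <- ceiling(length_px / 2 + diam_px / 2 + 2)
  g <- expand.grid(dx = -ext:ext, dy = -ext:ext)
  along <- g$dx * ux + g$dy * uy
  perp <- -g$dx * uy + g$dy * ux
  keep <- abs(along) <= length_px / 2 & abs(perp) <= diam_px / 2
  g <- g[keep, ]; perp <- perp[keep]
  prof <- 1 - (2 * perp / diam_px)^2
  keep2 <- prof >= profile_floor
  g <- g[keep2, ]; prof <- prof[keep2]
  ord <- order(-prof)
  list(dx = g$dx[ord], dy = g$dy[ord], profile = prof[ord],
       axis = c(ux, uy))
}

# per-frame painted counts for one vessel: profile * w >= eps
painted_counts_ <- function(profile_sorted, w, eps = 0.02) {
  thr <- ifelse(w > 0, eps / w, Inf)
  # profile_sorted is descending; count entries >= thr
  vapply(thr, function(th) sum(profile_sorted >= th), integer(1))
}

#' Synthesize one color-Doppler cine case with ground truth
#'
#' Constructs a lesion phantom — one main straight vessel at a prescribed
#' Doppler angle plus two minor feeding vessels — whose measured parameters
#' are driven to the requested targets, then renders every frame through the
#' colorbar LUT over a gray speckle background. The rendered velocity at a
#' pixel is the beam-projected component `v * cos(angle)`: this is what a
#' Doppler scanner measures, it is what makes angle correction in the
#' single-vessel method meaningful, and it is why the uncorrected tissue
#' parameters underestimate obliquely insonated flow.
#'
#' The construction solves, in order: the main-vessel velocity scale from the
#' target FV, the minor-vessel scale from the target TFV (the per-frame mean
#' is linear in it), the minor-vessel pulsatility from the target TRI (fixed
#' point on the composite trace), and the ROI size from the target TPI. The
#' ground truth sidecar is then *measured* from the constructed, continuous
#' (pre-quantization) velocity trace with the package's own cycle logic, so
#' recovery tests compare the decoded pipeline against exact arithmetic on
#' the noiseless field.
#'
#' @param params A one-row tibble or named list with `tfv`, `tpi`, `fv`,
#'   `volf`, `tri`, `ri`, `heart_rate`, `angle_deg`, and optionally
#'   `noise_sd`, `duration_s`. Defaults to a representative inflammatory
#'   lesion at the published group medians.
#' @param acquisition A [calibration()] (pixel pitch, frame rate, LUT, beam
#'   axis).
#' @param seed Integer seed; identical `(params, seed)` give bit-identical
#'   cases.
#' @param case_id,label Passed into the [cine_sequence()].
#' @param max_roi_side Cap on the ROI side length in pixels (memory guard;
#'   lesions whose target vascular fraction would need a larger ROI get the
#'   capped ROI and a correspondingly larger true TPI, which the ground truth
#'   records faithfully).
#' @return A list with `cine` (a [cine_sequence()]) and `truth` (named list:
#'   `tfv`, `tri`, `tpi`, `fv`, `ri`, `volf`, `angle_deg`, `diameter_cm`,
#'   `vessel_mask`, plus the drawn targets under `target_*`).
#' @export
synthesize_case <- function(params = NULL, acquisition = calibration(),
                            seed = 1, case_id = "case", label = "unknown",
                            max_roi_side = 400) {
  defaults <- list(tfv = 2.653, tpi = 0.016, fv = 3.397, volf = 0.032,
                   tri = 0.776, ri = 0.843, heart_rate = 75, angle_deg = 45,
                   noise_sd = 0, duration_s = 3)
  params <- utils::modifyList(defaults, as.list(params %||% list()))
  sp <- acquisition$pixel_spacing
  fr <- acquisition$frame_rate
  lut <- acquisition$lut
  v_max_lut <- max(abs(lut$velocity))
  n_fr <- round(params$duration_s * fr)

  with_seed_(seed, {
    # vessel geometry (px)
    d_cm <- 2 * sqrt(params$volf / (pi * params$fv))
    d_px <- d_cm / sp
    if (d_px < 2.5) abort("geometry infeasible: vessel thinner than 2.5 px",
                          class = "dopplerperf_error_geometry")
    main <- rasterize_vessel_(0.3 / sp, d_px, params$angle_deg,
                              side_sign = sample(c(-1, 1), 1))
    cos_main <- max(cos(params$angle_deg * pi / 180), 0.05)

    minors <- list()
    # forbid placement within a 2-px halo of existing vessels so that
    # components never touch (4-connectivity must keep vessels separate)
    halo <- expand.grid(hx = -2:2, hy = -2:2)
    occupied <- paste(rep(main$dx, each = nrow(halo)) + halo$hx,
                      rep(main$dy, each = nrow(halo)) + halo$hy)
    for (k in 1:2) {
      for (try in 1:30) {
        m <- rasterize_vessel_(0.18 / sp, 0.05 / sp, runif(1, 0, 40),
                               side_sign = sample(c(-1, 1), 1))
        off_r <- runif(1, 14, 26); off_a <- runif(1, 0, 2 * pi)
        m$dx <- m$dx + round(off_r * cos(off_a))
        m$dy <- m$dy + round(off_r * sin(off_a))
        key <- paste(m$dx, m$dy)
        if (!any(key %in% occupied)) {
          m$cos_f <- max(abs(cos(runif(1, 0, 40) * pi / 180)), 0.05)
          m$sign <- sample(c(-1, 1), 1)
          occupied <- c(occupied,
                        paste(rep(m$dx, each = nrow(halo)) + halo$hx,
                              rep(m$dy, each = nrow(halo)) + halo$hy))
          minors[[k]] <- m
          break
        }
      }
    }

    # waveforms (in phase: one heart drives the lesion)
    p_main <- min(max(1 - params$ri, 0), 1)
    w_main <- make_waveform(params$heart_rate, fr, n_fr, p_main)

    # complete-cycle window from the systolic peaks of the waveform
    pk <- find_peaks_(w_main, min_prom = 0)
    if (length(pk) < 2) pk <- c(1L, n_fr)
    win <- pk[1]:(pk[length(pk)] - 1L)

    # main-vessel scale from the target FV (time-averaged corrected peak)
    cnt_m <- painted_counts_(main$profile, w_main)
    maxprof <- ifelse(cnt_m > 0, main$profile[1], 0)
    corr_rel <- maxprof * w_main * cos_main /
      max(cos(params$angle_deg * pi / 180), 1e-6)
    s_main <- params$fv / mean(corr_rel[win])
    if (s_main * cos_main > v_max_lut) {
      abort("geometry infeasible: velocity out of colorbar range",
            class = "dopplerperf_error_geometry")
    }
    ps_main <- cumsum(main$profile) * cos_main   # prefix sums of projections

    # minor-vessel scale and pulsatility from the target TFV and TRI
    p_minor <- min(max(1 - params$tri, 0), 1)
    if (params$tri >= 0.999 && p_main <= 1e-6) p_minor <- 0
    s_minor <- 1
    tfv_tri_of <- function(s_minor, p_minor) {
      w_n <- make_waveform(params$heart_rate, fr, n_fr, p_minor)
      sum_v <- s_main * w_main * ifelse(cnt_m > 0, ps_main[pmax(cnt_m, 1)], 0)
      n_tot <- cnt_m
      for (m in minors) {
        cnt <- painted_counts_(m$profile, w_n)
        ps <- cumsum(m$profile) * m$cos_f
        sum_v <- sum_v + s_minor * w_n * ifelse(cnt > 0, ps[pmax(cnt, 1)], 0)
        n_tot <- n_tot + cnt
      }
      mean_v <- ifelse(n_tot > 0, sum_v / pmax(n_tot, 1), 0)
      # cycle-wise TRI on the composite trace
      tri_c <- vapply(seq_len(length(pk) - 1), function(i) {
        seg <- mean_v[pk[i]:(pk[i + 1] - 1)]
        if (max(seg) > 0) (max(seg) - min(seg)) / max(seg) else 0
      }, numeric(1))
      list(tfv = mean(mean_v[win]), tri = mean(tri_c), mean_v = mean_v,
           sum_v = sum_v, n_tot = n_tot, w_n = w_n)
    }
    if (length(minors) > 0) {
      for (iter in 1:8) {
        base <- tfv_tri_of(0, p_minor)
        unit <- tfv_tri_of(1, p_minor)
        bslope <- unit$tfv - base$tfv
        s_minor <- if (bslope > 1e-9)
          max((params$tfv - base$tfv) / bslope, 0.1) else 0.1
        cur <- tfv_tri_of(s_minor, p_minor)
        if (abs(cur$tri - params$tri) < 0.005) break
        # fixed-point update of the minor pulsatility towards the target TRI
        adj <- p_minor + (cur$tri - params$tri)
        p_minor <- min(max(adj, 0), 1)
      }
      peak_minor <- s_minor * max(vapply(minors, function(m)
        max(m$profile) * m$cos_f, numeric(1)))
      if (peak_minor > v_max_lut) {
        abort("geometry infeasible: velocity out of colorbar range",
              class = "dopplerperf_error_geometry")
      }
    }
    sol <- tfv_tri_of(s_minor, p_minor)

    # ROI size from the target TPI: tpi = mean over window of sum_v / n_roi
    n_roi_target <- mean(sol$sum_v[win]) / params$tpi
    side <- round(sqrt(max(n_roi_target, 0)))
    side <- min(max(side, 84), max_roi_side)

    margin <- 4L
    hgt <- side + 2L * margin
    ctr <- margin + (side + 1L) %/% 2L
    roi <- matrix(FALSE, hgt, hgt)
    roi[(margin + 1):(margin + side), (margin + 1):(margin + side)] <- TRUE
    n_roi <- sum(roi)

    to_idx <- function(m) {
      r <- ctr + m$dy; c0 <- ctr + m$dx
      if (any(r < margin + 1 | r > margin + side |
              c0 < margin + 1 | c0 > margin + side)) {
        abort("geometry infeasible: vessel does not fit in ROI",
              class = "dopplerperf_error_geometry")
      }
      (c0 - 1L) * hgt + r
    }
    idx_main <- to_idx(main)
    idx_minors <- lapply(minors, to_idx)

    # render
    bg <- matrix(pmin(pmax(round(110 + 20 * rnorm(hgt * hgt)), 45), 185),
                 hgt, hgt)
    cnt_minors <- lapply(minors, function(m) painted_counts_(m$profile, sol$w_n))
    frames <- vector("list", n_fr)
    for (i in seq_len(n_fr)) {
      v <- matrix(NaN, hgt, hgt)
      if (cnt_m[i] > 0) {
        sel <- seq_len(cnt_m[i])
        v[idx_main[sel]] <- s_main * main$profile[sel] * cos_main * w_main[i]
      }
      for (k in seq_along(minors)) {
        ck <- cnt_minors[[k]][i]
        if (ck > 0) {
          sel <- seq_len(ck)
          v[idx_minors[[k]][sel]] <- minors[[k]]$sign * s_minor *
            minors[[k]]$profile[sel] * minors[[k]]$cos_f * sol$w_n[i]
        }
      }
      fr_i <- encode_frame(v, lut, bg)
      if (params$noise_sd > 0) {
        fr_i <- array(pmin(pmax(round(fr_i + rnorm(length(fr_i),
                                                   sd = params$noise_sd)),
                                0), 255), dim(fr_i))
      }
      frames[[i]] <- fr_i
    }
    cine <- cine_sequence(frames, acquisition, roi, case_id = case_id,
                          label = label)

    # ground truth: the package's own cycle logic on the continuous trace
    tr <- tibble(frame = seq_len(n_fr), t = (seq_len(n_fr) - 1) / fr,
                 mean_v = sol$mean_v,
                 area = sol$n_tot * sp^2,
                 intensity = sol$sum_v / n_roi)
    cycles <- tryCatch(detect_cycles(tr, signal = "intensity"),
                       dopplerperf_error_cycles = function(e) NULL)
    dt <- compute_dtpm(tr, cycles)

    if (params$angle_deg < 89.5) {
      ctrace <- tibble(
        frame = seq_len(n_fr), t = (seq_len(n_fr) - 1) / fr,
        corrected = s_main * ifelse(cnt_m > 0, main$profile[1], 0) *
          cos_main * w_main / cos(params$angle_deg * pi / 180))
      ccyc <- tryCatch(detect_cycles(ctrace, signal = "corrected"),
                       dopplerperf_error_cycles = function(e) NULL)
      sv <- compute_svfm(ctrace, ccyc, diameter = d_cm,
                         angle_deg = params$angle_deg)
      fv_true <- sv$fv; ri_true <- sv$ri; volf_true <- sv$volf
    } else {
      fv_true <- NA_real_; ri_true <- NA_real_; volf_true <- NA_real_
    }

    vmask <- matrix(FALSE, hgt, hgt)
    vmask[idx_main] <- TRUE
    truth <- list(
      tfv = dt$tfv, tri = dt$tri, tpi = dt$tpi,
      fv = fv_true, ri = ri_true, volf = volf_true,
      angle_deg = params$angle_deg, diameter_cm = d_cm,
      vasc_frac = mean(sol$n_tot[win]) / n_roi,
      vessel_mask = vmask,
      target_tfv = params$tfv, target_tri = params$tri,
      target_tpi = params$tpi, target_fv = params$fv,
      target_ri = params$ri, target_volf = params$volf
    )
    list(cine = cine, truth = truth)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-case parameters from the calibrated per-label distributions and
#' synthesizes every case. With `dir` set, each case is written as a case
#' directory (`frames.tif`, `calibration.json`, `roi.png`, `truth.json`)
#' plus a cohort `manifest.csv`; otherwise cases are returned in memory.
#'
#' @inheritParams draw_cohort_params
#' @param acquisition A [calibration()] shared by all cases.
#' @param dir Optional output directory.
#' @param max_roi_side Passed to [synthesize_case()].
#' @return A list with `manifest` (tibble: case id, label, per-case seed,
#'   drawn targets and measured ground-truth parameters) and, when `dir` is
#'   `NULL`, `cases` (list of `synthesize_case()` outputs).
#' @export
generate_cohort <- function(n_malignant = 40, n_inflammatory = 29,
                            calib = cohort_calibration(), seed = 1,
                            acquisition = calibration(), dir = NULL,
                            max_roi_side = 400) {
  draws <- draw_cohort_params(n_malignant, n_inflammatory, calib, seed)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- vector("list", nrow(draws))
  truth_rows <- vector("list", nrow(draws))
  for (i in seq_len(nrow(draws))) {
    row <- draws[i, ]
    case <- synthesize_case(
      params = row[c("tfv", "tpi", "fv", "volf", "tri", "ri", "heart_rate",
                     "angle_deg", "noise_sd", "duration_s")],
      acquisition = acquisition, seed = row$seed_case,
      case_id = row$case_id, label = row$label, max_roi_side = max_roi_side
    )
    truth_rows[[i]] <- tibble(
      true_tfv = case$truth$tfv, true_tri = case$truth$tri,
      true_tpi = case$truth$tpi, true_fv = case$truth$fv,
      true_ri = case$truth$ri, true_volf = case$truth$volf
    )
    if (!is.null(dir)) {
      write_cine(case$cine, file.path(dir, row$case_id), truth = case$truth)
    } else {
      cases[[i]] <- case
    }
  }
  manifest <- dplyr::bind_cols(draws, dplyr::bind_rows(truth_rows))
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    list(manifest = manifest, dir = dir)
  } else {
    list(manifest = manifest, cases = cases)
  }
}
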