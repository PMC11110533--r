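#' Optics model for the modified Beer-Lambert law
#'
#' Holds the 2x2 extinction-coefficient matrix (wavelength x chromophore,
#' 1/(mM cm)), the differential pathlength factors and the source-detector
#' separation. Defaults use standard tabulated hemoglobin extinction
#' coefficients at 760 and 830 nm, DPF 6 at both wavelengths and a 3 cm
#' separation (30 mm montage).
#'
#' @param eps 2x2 matrix, rows named by wavelength ("760", "830"), columns
#'   `hbo`, `hbr`, units 1/(mM cm).
#' @param dpf length-2 differential pathlength factor, one per wavelength.
#' @param d_cm source-detector separation, cm.
#' @param i0 nominal baseline intensity (used by the forward model).
#' @return an object of class `fnirs_optics`.
#' @export
default_optics <- function(eps = rbind("760" = c(hbo = 0.586, hbr = 1.5485),
                                       "830" = c(hbo = 0.974, hbr = 0.6930)),
                           dpf = c(6, 6), d_cm = 3, i0 = 0.5) {
  optics <- structure(list(eps = eps, dpf = dpf, d_cm = d_cm, i0 = i0),
                      class = "fnirs_optics")
  validate_optics(optics)
  optics
}

validate_optics <- function(optics) {
  if (!all(dim(optics$eps) == c(2, 2)) ||
      abs(det(optics$eps)) < 1e-12)
    stop("optics error: extinction-coefficient matrix must be 2x2 and nonsingular",
         call. = FALSE)
  if (any(optics$dpf <= 0) || optics$d_cm <= 0)
    stop("optics error: DPF and separation must be positive", call. = FALSE)
  invisible(optics)
}

#' Prune low-quality channels
#'
#' A channel is kept iff, at both wavelengths, its mean intensity lies inside
#' `d_range` and its signal-to-noise ratio (mean/sd) is at least
#' `snr_thresh`. A constant channel (sd 0) has infinite SNR and is kept if
#' its mean is in range. The data are not modified; a logical keep-mask is
#' returned.
#'
#' @param recording an `fnirs_recording`.
#' @param d_range length-2 numeric intensity range, default `c(1e-2, 1e0)`.
#' @param snr_thresh minimum mean/sd ratio, default 2.
#' @return logical vector, one entry per channel.
#' @export
prune_channels <- function(recording, d_range = c(1e-2, 1e0), snr_thresh = 2) {
  x <- recording$intensity
  if (length(x) == 0) stop("empty recording", call. = FALSE)
  nch <- dim(x)[2]
  keep <- rep(TRUE, nch)
  for (ch in seq_len(nch)) {
    for (wl in seq_len(dim(x)[3])) {
      v <- x[, ch, wl]
      m <- mean(v); s <- stats::sd(v)
      snr <- if (is.na(s) || s == 0) Inf else m / s
      if (m < d_range[1] || m > d_range[2] || snr < snr_thresh) {
        keep[ch] <- FALSE
        break
      }
    }
  }
  if (!any(keep)) stop("no usable channels after pruning", call. = FALSE)
  keep
}

#' Convert intensity to optical density change
#'
#' `dOD(t) = -log10(I(t) / Iref)` per channel and wavelength. The reference
#' is the temporal mean over `baseline_idx` (all samples by default), so with
#' the default the mean dOD is approximately zero per channel.
#'
#' @param recording an `fnirs_recording` with positive intensities.
#' @param baseline_idx optional integer sample indices defining the reference
#'   period (e.g. a fasting baseline); default all samples.
#' @return list with `od` (time x channel x wavelength array) inheriting the
#'   recording's sampling rate as attribute `sampling_rate`.
#' @export
intensity_to_od <- function(recording, baseline_idx = NULL) {
  x <- recording$intensity
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive intensity at time index %d, channel %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  if (is.null(baseline_idx)) baseline_idx <- seq_len(dim(x)[1])
  od <- x
  for (ch in seq_len(dim(x)[2])) {
    for (wl in seq_len(dim(x)[3])) {
      iref <- mean(x[baseline_idx, ch, wl])
      od[, ch, wl] <- -log10(x[, ch, wl] / iref)
    }
  }
  attr(od, "sampling_rate") <- recording$sampling_rate
  od
}

#' Detect motion artifacts per channel
#'
#' Scans each channel/wavelength in windows of `t_motion` seconds and flags a
#' window (extended by `t_mask` seconds on both sides) when its peak-to-peak
#' amplitude exceeds `amp_thresh` or its standard deviation exceeds
#' `std_thresh` times the channel's median windowed standard deviation.
#'
#' @param od optical-density array from [intensity_to_od()].
#' @param sampling_rate Hz.
#' @param t_motion window length, s.
#' @param t_mask mask extension, s.
#' @param std_thresh relative standard-deviation threshold.
#' @param amp_thresh absolute peak-to-peak OD threshold.
#' @return logical time x channel matrix (TRUE = artifact).
#' @export
detect_motion_artifacts <- function(od, sampling_rate = attr(od, "sampling_rate"),
                                    t_motion = 1, t_mask = 1,
                                    std_thresh = 10, amp_thresh = 0.2) {
  if (std_thresh <= 0 || amp_thresh <= 0)
    stop("thresholds must be positive", call. = FALSE)
  n <- dim(od)[1]
  w <- max(2L, round(t_motion * sampling_rate))
  if (w > n) stop("motion window longer than series", call. = FALSE)
  pad <- round(t_mask * sampling_rate)
  starts <- seq(1L, n - w + 1L, by = w)
  mask <- matrix(FALSE, n, dim(od)[2])
  nw <- length(starts)
  for (ch in seq_len(dim(od)[2])) {
    for (wl in seq_len(dim(od)[3])) {
      v <- od[, ch, wl]
      m <- matrix(v[seq_len(nw * w)], nrow = w)     # one column per window
      mu <- colMeans(m)
      sds <- sqrt(pmax(colMeans(m^2) - mu^2, 0) * w / (w - 1))
      cmax <- m[1, ]; cmin <- m[1, ]
      for (r in seq_len(w)[-1]) {
        cmax <- pmax(cmax, m[r, ]); cmin <- pmin(cmin, m[r, ])
      }
      p2p <- cmax - cmin
      med <- stats::median(sds)
      flag <- p2p > amp_thresh | (med > 0 & sds > std_thresh * med)
      for (k in which(flag)) {
        lo <- max(1L, starts[k] - pad)
        hi <- min(n, starts[k] + w - 1L + pad)
        mask[lo:hi, ch] <- TRUE
      }
    }
  }
  mask
}

## ---- periodized orthogonal Daubechies-2 DWT -------------------------------
## No discrete-wavelet package ships with this stack, so the transform is
## implemented here: standard Mallat pyramid with periodic boundary handling
## and the orthonormal db2 filter pair. The adjoint is the exact inverse.

db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  idx <- outer((seq_len(half) - 1L) * 2L, 0:3, "+") %% n + 1L
  xm <- matrix(x[idx], half, 4)
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

dwt_db2 <- function(x, level) {
  f <- db2_filters()
  approx <- x
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- dwt_step(approx, f$h, f$g)
    details[[j]] <- st$d
    approx <- st$a
  }
  list(approx = approx, details = details)
}

idwt_db2 <- function(decomp) {
  f <- db2_filters()
  approx <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    d <- decomp$details[[j]]
    n <- 2L * length(d)
    x <- numeric(n)
    ## for even n the positions (2i+k) mod n are distinct within each k
    for (k in 0:3) {
      pos <- ((seq_along(approx) - 1L) * 2L + k) %% n + 1L
      x[pos] <- x[pos] + approx * f$h[k + 1] + d * f$g[k + 1]
    }
    approx <- x
  }
  approx
}

#' Wavelet motion-artifact correction
#'
#' Decomposes each channel/wavelength series with a periodized Daubechies-2
#' discrete wavelet transform and zeroes detail coefficients falling outside
#' the interquartile fences `[Q1 - iqr_factor*IQR, Q3 + iqr_factor*IQR]` at
#' each level, then reconstructs. Localized transients (spikes, steps)
#' produce outlying coefficients across levels and are strongly attenuated;
#' in-band oscillations pass nearly unchanged.
#'
#' @param od time x channel x wavelength array (or plain vector).
#' @param sampling_rate Hz, used for the default decomposition depth.
#' @param level decomposition depth; default
#'   `floor(log2(sampling_rate / 0.01))`, capped so the coarsest level keeps
#'   at least 4 coefficients.
#' @param iqr_factor fence width in IQR units, default 1.5.
#' @return corrected array of the original shape.
#' @export
wavelet_motion_correct <- function(od, sampling_rate = attr(od, "sampling_rate"),
                                   level = NULL, iqr_factor = 1.5) {
  correct_vec <- function(v) {
    n <- length(v)
    lv <- level
    if (is.null(lv)) lv <- floor(log2(sampling_rate / 0.01))
    else if (n < 2^lv) stop("series shorter than 2^level", call. = FALSE)
    lv <- min(lv, floor(log2(n / 4)))
    if (lv < 1) stop("series too short for wavelet decomposition", call. = FALSE)
    npad <- ceiling(n / 2^lv) * 2^lv
    if (npad > n) {
      ext <- v[seq(n, by = -1, length.out = npad - n)]  # reflect tail
      vv <- c(v, ext)
    } else vv <- v
    dec <- dwt_db2(vv, lv)
    for (j in seq_along(dec$details)) {
      d <- dec$details[[j]]
      q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      out <- d < q[1] - iqr_factor * iqr | d > q[2] + iqr_factor * iqr
      d[out] <- 0
      dec$details[[j]] <- d
    }
    idwt_db2(dec)[seq_len(n)]
  }
  if (is.null(dim(od))) return(correct_vec(od))
  out <- od
  for (ch in seq_len(dim(od)[2]))
    for (wl in seq_len(dim(od)[3]))
      out[, ch, wl] <- correct_vec(od[, ch, wl])
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' Zero-phase band filter
#'
#' Forward-backward (zero-phase) Butterworth filtering. The band is realized
#' as a cascade of a low-pass at `high_hz` and, when `low_hz > 0`, a
#' high-pass at `low_hz`; the cascade is numerically robust at the very low
#' normalized cutoffs typical of hemodynamic bands. `low_hz = 0` gives a pure
#' low-pass, preserving slow metabolic trends.
#'
#' @param x numeric series.
#' @param low_hz lower band edge, Hz (0 disables the high-pass).
#' @param high_hz upper band edge, Hz.
#' @param sampling_rate Hz.
#' @param order Butterworth order per section, default 3.
#' @return filtered series, same length as the input.
#' @export
bandpass_filter <- function(x, low_hz = 0.01, high_hz = 0.1,
                            sampling_rate, order = 3) {
  nyq <- sampling_rate / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyq)
    stop("band must satisfy 0 <= low < high < Nyquist", call. = FALSE)
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  y <- signal::filtfilt(lp, x)
  if (low_hz > 0) {
    hp <- signal::butter(order, low_hz / nyq, type = "high")
    y <- signal::filtfilt(hp, y)
  }
  y
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per time point and channel, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) d DPF(lambda)`
#' for the chromophore concentration changes (uM).
#'
#' @param od time x channel x wavelength array.
#' @param optics an `fnirs_optics` object.
#' @return list with `dhbo` and `dhbr` (time x channel matrices, uM) and
#'   `sampling_rate`.
#' @export
od_to_hemo <- function(od, optics = default_optics()) {
  validate_optics(optics)
  a <- optics$eps * (optics$d_cm * optics$dpf) / 1000   # rows scaled by path
  ainv <- solve(a)
  nch <- dim(od)[2]
  dhbo <- matrix(0, dim(od)[1], nch)
  dhbr <- matrix(0, dim(od)[1], nch)
  for (ch in seq_len(nch)) {
    conc <- od[, ch, ] %*% t(ainv)
    dhbo[, ch] <- conc[, 1]
    dhbr[, ch] <- conc[, 2]
  }
  list(dhbo = dhbo, dhbr = dhbr, sampling_rate = attr(od, "sampling_rate"))
}

#' Correlation-based signal improvement (CBSI)
#'
#' Enforces the physiological anti-correlation between HbO and HbR:
#' with `alpha = sd(HbO)/sd(HbR)`, `HbO' = (HbO - alpha*HbR)/2` and
#' `HbR' = -HbO'/alpha`, so that `cor(HbO', HbR') = -1` exactly.
#' Channels with zero-variance HbR are left unchanged and flagged.
#'
#' @param hemo list with `dhbo`, `dhbr` matrices (time x channel).
#' @return the same structure with corrected series and a logical
#'   `cbsi_skipped` vector per channel.
#' @export
cbsi_correct <- function(hemo) {
  dhbo <- hemo$dhbo; dhbr <- hemo$dhbr
  skipped <- logical(ncol(dhbo))
  for (ch in seq_len(ncol(dhbo))) {
    s_r <- stats::sd(dhbr[, ch])
    if (is.na(s_r) || s_r == 0) {
      skipped[ch] <- TRUE
      warning("CBSI skipped for zero-variance HbR channel ", ch, call. = FALSE)
      next
    }
    alpha <- stats::sd(dhbo[, ch]) / s_r
    corrected <- (dhbo[, ch] - alpha * dhbr[, ch]) / 2
    dhbo[, ch] <- corrected
    dhbr[, ch] <- -corrected / alpha
  }
  out <- hemo
  out$dhbo <- dhbo; out$dhbr <- dhbr
  out$cbsi_skipped <- skipped
  out
}

#' Default preprocessing parameters
#'
#' @param d_range,snr_thresh channel-pruning thresholds.
#' @param od_baseline `"all"` (per-recording temporal mean) or `"fasting"`
#'   (fasting-segment mean; only meaningful for concatenated sessions).
#' @param motion_detect,wavelet,filter,cbsi logical stage switches.
#' @param band length-2 filter band, Hz; `band[1] = 0` keeps slow trends
#'   (the pipeline default, since the glucose response lies below 0.01 Hz).
#' @param wavelet_level,iqr_factor wavelet-correction settings.
#' @param t_motion,t_mask,std_thresh,amp_thresh artifact-detection settings.
#' @return a named list of parameters for [run_preprocessing()].
#' @export
preprocess_params <- function(d_range = c(1e-2, 1e0), snr_thresh = 2,
                              od_baseline = "all",
                              motion_detect = TRUE, wavelet = TRUE,
                              filter = TRUE, cbsi = TRUE,
                              band = c(0, 0.1),
                              wavelet_level = NULL, iqr_factor = 1.5,
                              t_motion = 1, t_mask = 1,
                              std_thresh = 10, amp_thresh = 0.2) {
  list(d_range = d_range, snr_thresh = snr_thresh, od_baseline = od_baseline,
       motion_detect = motion_detect, wavelet = wavelet, filter = filter,
       cbsi = cbsi, band = band, wavelet_level = wavelet_level,
       iqr_factor = iqr_factor, t_motion = t_motion, t_mask = t_mask,
       std_thresh = std_thresh, amp_thresh = amp_thresh)
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: channel pruning, optical-density conversion, motion
#' artifact detection, wavelet correction, zero-phase band filtering,
#' modified Beer-Lambert inversion and CBSI. Each executed stage is recorded
#' in the provenance attribute.
#'
#' @param recording an `fnirs_recording`.
#' @param params a list from [preprocess_params()].
#' @param optics an `fnirs_optics` object.
#' @param baseline_idx optional OD reference sample indices (overrides
#'   `params$od_baseline`).
#' @return list of class `fnirs_hemo`: `dhbo`, `dhbr` (time x channel, uM),
#'   `sampling_rate`, `channel_keep` mask, `artifact_mask`, `provenance`
#'   (character vector of executed stages, in order).
#' @export
run_preprocessing <- function(recording, params = preprocess_params(),
                              optics = default_optics(),
                              baseline_idx = NULL) {
  prov <- character(0)
  fs <- recording$sampling_rate
  keep <- tryCatch(
    prune_channels(recording, params$d_range, params$snr_thresh),
    error = function(e) stop("prune_channels: ", conditionMessage(e), call. = FALSE))
  prov <- c(prov, "prune_channels")
  od <- tryCatch(intensity_to_od(recording, baseline_idx),
                 error = function(e) stop("intensity_to_od: ", conditionMessage(e),
                                          call. = FALSE))
  prov <- c(prov, "intensity_to_od")
  amask <- NULL
  if (isTRUE(params$motion_detect)) {
    amask <- detect_motion_artifacts(od, fs, params$t_motion, params$t_mask,
                                     params$std_thresh, params$amp_thresh)
    prov <- c(prov, "detect_motion_artifacts")
  }
  if (isTRUE(params$wavelet)) {
    od <- wavelet_motion_correct(od, fs, params$wavelet_level,
                                 params$iqr_factor)
    prov <- c(prov, "wavelet_motion_correct")
  }
  if (isTRUE(params$filter)) {
    for (ch in seq_len(dim(od)[2]))
      for (wl in seq_len(dim(od)[3]))
        od[, ch, wl] <- bandpass_filter(od[, ch, wl], params$band[1],
                                        params$band[2], fs)
    prov <- c(prov, "bandpass_filter")
  }
  hemo <- od_to_hemo(od, optics)
  prov <- c(prov, "od_to_hemo")
  if (isTRUE(params$cbsi)) {
    hemo <- cbsi_correct(hemo)
    prov <- c(prov, "cbsi_correct")
  }
  structure(list(dhbo = hemo$dhbo, dhbr = hemo$dhbr,
                 sampling_rate = fs, channel_keep = keep,
                 artifact_mask = amask,
                 cbsi_skipped = hemo$cbsi_skipped,
                 provenance = prov),
            class = "fnirs_hemo")
}

#' Preprocess one subject's session (fasting + glucose states)
#'
#' Concatenates the fasting and glucose-state recordings into one continuous
#' session, runs the preprocessing chain once with the optical-density
#' reference taken from the fasting baseline, and splits the resulting
#' hemoglobin series back into the two states. Referencing OD to the fasting
#' baseline preserves the between-state concentration contrast that the
#' downstream state comparison and glucose association rely on.
#'
#' @param subject one element of an `fnirs_cohort`'s `subjects` list.
#' @param params preprocessing parameters.
#' @param optics optics model.
#' @return list with per-state `fnirs_hemo` objects (`fasting`, `glucose`).
#' @export
preprocess_subject <- function(subject, params = preprocess_params(),
                               optics = default_optics()) {
  fr <- subject$recordings$fasting
  gr <- subject$recordings$glucose
  n_fast <- dim(fr$intensity)[1]
  combined <- new_recording(subject$subject_id, "session",
                            abind_time(fr$intensity, gr$intensity),
                            fr$sampling_rate, fr$geometry)
  hemo <- run_preprocessing(combined, params, optics,
                            baseline_idx = seq_len(n_fast))
  split_hemo(hemo, n_fast)
}

abind_time <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = dimnames(a))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

split_hemo <- function(hemo, n_fast) {
  n <- nrow(hemo$dhbo)
  mk <- function(idx, offset_s) {
    structure(list(dhbo = hemo$dhbo[idx, , drop = FALSE],
                   dhbr = hemo$dhbr[idx, , drop = FALSE],
                   sampling_rate = hemo$sampling_rate,
                   channel_keep = hemo$channel_keep,
                   time_offset_s = offset_s,
                   provenance = hemo$provenance),
              class = "fnirs_hemo")
  }
  list(fasting = mk(seq_len(n_fast), 0),
       glucose = mk((n_fast + 1):n, n_fast / hemo$sampling_rate))
}
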