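#' Configuration for a synthetic fNIRS glucose cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the package targets: 15 subjects, a 21-channel prefrontal
#' montage at 760/830 nm, a 10-minute fasting recording followed by a
#' 60-minute post-load recording, glucose-coupled oxyhemoglobin responses on
#' channels 7, 12, 15, 18 and 19, cardiac/respiratory/Mayer-wave
#' oscillations, white measurement noise, and Poisson spike/shift motion
#' artifacts.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_channels number of source-detector channels.
#' @param sampling_rate sampling rate of the optical time series, Hz.
#' @param fasting_duration duration of the fasting recording, s.
#' @param glucose_duration duration of the post-load recording, s.
#' @param coupled_channels integer channel indices whose HbO tracks glucose.
#' @param coupling_beta_mean,coupling_beta_sd between-subject distribution of
#'   the HbO-glucose coupling coefficient, uM per mmol/L.
#' @param hbr_ratio magnitude of the anti-correlated HbR response relative to
#'   HbO (HbR = -hbr_ratio * HbO + noise).
#' @param fasting_glucose_mean,fasting_glucose_sd between-subject fasting
#'   glucose level, mmol/L.
#' @param fasting_glucose_noise_sd within-subject fluctuation of the true
#'   glucose curve, mmol/L.
#' @param peak_delta_mean,peak_delta_sd between-subject post-load glucose
#'   excursion amplitude, mmol/L.
#' @param peak_time_mean,peak_time_sd time from glucose load to peak, s.
#' @param decay_tau exponential decay constant of the post-peak return, s.
#' @param plateau_fraction fraction of the excursion retained at the late
#'   plateau (plateau = fasting + plateau_fraction * delta).
#' @param cardiac_hz,resp_hz,mayer_hz frequencies of the physiological
#'   oscillations, Hz.
#' @param cardiac_amp,resp_amp,mayer_amp amplitudes of those oscillations, uM.
#' @param artifact_spike_rate,artifact_shift_rate Poisson rates of transient
#'   spikes and baseline shifts, events per minute per recording.
#' @param noise_sd white-noise standard deviation on HbO, uM.
#' @param glucose_sample_interval spacing of reference fingertip glucose
#'   samples, s.
#' @param ref_noise_sd reference-meter measurement noise, mmol/L.
#' @param i0 baseline detected intensity (arbitrary units); must lie inside
#'   the pruning dRange.
#' @param rng_seed integer root seed; identical configurations give
#'   bit-identical cohorts.
#' @return an object of class `fnirs_config` (a validated list).
#' @export
fnirs_config <- function(n_subjects = 15,
                         n_channels = 21,
                         sampling_rate = 10,
                         fasting_duration = 600,
                         glucose_duration = 3600,
                         coupled_channels = c(7L, 12L, 15L, 18L, 19L),
                         coupling_beta_mean = 0.15,
                         coupling_beta_sd = 0.03,
                         hbr_ratio = 0.3,
                         fasting_glucose_mean = 5.0,
                         fasting_glucose_sd = 0.4,
                         fasting_glucose_noise_sd = 0.05,
                         peak_delta_mean = 3.0,
                         peak_delta_sd = 0.5,
                         peak_time_mean = 1800,
                         peak_time_sd = 300,
                         decay_tau = 900,
                         plateau_fraction = 0.3,
                         cardiac_hz = 1.1, cardiac_amp = 0.08,
                         resp_hz = 0.25, resp_amp = 0.05,
                         mayer_hz = 0.1, mayer_amp = 0.04,
                         artifact_spike_rate = 0.5,
                         artifact_shift_rate = 0.1,
                         noise_sd = 0.05,
                         glucose_sample_interval = 600,
                         ref_noise_sd = 0.1,
                         i0 = 0.5,
                         rng_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate,
    fasting_duration = fasting_duration, glucose_duration = glucose_duration,
    coupled_channels = sort(as.integer(coupled_channels)),
    coupling_beta_mean = coupling_beta_mean, coupling_beta_sd = coupling_beta_sd,
    hbr_ratio = hbr_ratio,
    fasting_glucose_mean = fasting_glucose_mean,
    fasting_glucose_sd = fasting_glucose_sd,
    fasting_glucose_noise_sd = fasting_glucose_noise_sd,
    peak_delta_mean = peak_delta_mean, peak_delta_sd = peak_delta_sd,
    peak_time_mean = peak_time_mean, peak_time_sd = peak_time_sd,
    decay_tau = decay_tau, plateau_fraction = plateau_fraction,
    cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
    resp_hz = resp_hz, resp_amp = resp_amp,
    mayer_hz = mayer_hz, mayer_amp = mayer_amp,
    artifact_spike_rate = artifact_spike_rate,
    artifact_shift_rate = artifact_shift_rate,
    noise_sd = noise_sd,
    glucose_sample_interval = glucose_sample_interval,
    ref_noise_sd = ref_noise_sd,
    i0 = i0,
    rng_seed = as.integer(rng_seed))
  validate_fnirs_config(cfg)
  class(cfg) <- "fnirs_config"
  cfg
}

validate_fnirs_config <- function(cfg) {
  pos <- c("sampling_rate", "fasting_duration", "glucose_duration",
           "peak_time_mean", "decay_tau", "glucose_sample_interval", "i0")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("configuration error: '", f, "' must be a positive scalar",
           call. = FALSE)
  }
  nonneg <- c("coupling_beta_sd", "fasting_glucose_sd",
              "fasting_glucose_noise_sd", "peak_delta_sd", "peak_time_sd",
              "artifact_spike_rate", "artifact_shift_rate", "noise_sd",
              "ref_noise_sd")
  for (f in nonneg) {
    if (cfg[[f]] < 0)
      stop("configuration error: '", f, "' must be >= 0", call. = FALSE)
  }
  if (cfg$n_subjects < 1L || cfg$n_channels < 1L)
    stop("configuration error: need at least one subject and one channel",
         call. = FALSE)
  if (length(cfg$coupled_channels) &&
      (min(cfg$coupled_channels) < 1L ||
       max(cfg$coupled_channels) > cfg$n_channels))
    stop("configuration error: coupled_channels outside 1..n_channels",
         call. = FALSE)
  invisible(cfg)
}

## Deterministic per-subject / per-stage substreams from the root seed.
## Simple affine hash of a tag keeps every derived seed inside 32-bit range.
derive_seed <- function(root, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(root) * 7919 + h * 104729) %% 2147483629) + 1L
}

#' Simulate one subject's true glucose curve
#'
#' The curve is piecewise: a stationary fasting level, a linear rise from the
#' glucose load to `fasting + delta` at the subject's peak time, then an
#' exponential decay toward a plateau at `fasting + plateau_fraction * delta`.
#' Small white fluctuations are superimposed; the deterministic backbone is
#' continuous at the state boundary.
#'
#' @param config an [fnirs_config()].
#' @param subject_seed integer seed for this subject's draws.
#' @return a data.frame with columns `time_s`, `state` ("fasting"/"glucose"),
#'   `glucose` (mmol/L), plus attributes `fasting_level`, `peak_delta`,
#'   `peak_time` (drawn subject parameters).
#' @export
generate_glucose_curve <- function(config, subject_seed = config$rng_seed) {
  validate_fnirs_config(config)
  set.seed(subject_seed)
  fast <- config$fasting_glucose_mean +
    config$fasting_glucose_sd * stats::rnorm(1)
  delta <- config$peak_delta_mean + config$peak_delta_sd * stats::rnorm(1)
  delta <- max(delta, 0.2)
  tp <- config$peak_time_mean + config$peak_time_sd * stats::rnorm(1)
  tp <- min(max(tp, 60), config$glucose_duration - 60)
  dt <- 1 / config$sampling_rate
  ## snap peak time to the sampling grid so the maximum is attained exactly
  tp <- round(tp / dt) * dt

  t_fast <- seq(0, config$fasting_duration - dt, by = dt)
  t_glu <- seq(config$fasting_duration,
               config$fasting_duration + config$glucose_duration - dt, by = dt)
  s <- t_glu - config$fasting_duration
  rise <- fast + delta * s / tp
  plateau <- fast + config$plateau_fraction * delta
  decay <- plateau + (1 - config$plateau_fraction) * delta *
    exp(-(s - tp) / config$decay_tau)
  g_glu <- ifelse(s <= tp, rise, decay)
  g <- c(rep(fast, length(t_fast)), g_glu)
  g <- g + config$fasting_glucose_noise_sd * stats::rnorm(length(g))
  out <- data.frame(
    time_s = c(t_fast, t_glu),
    state = rep(c("fasting", "glucose"), c(length(t_fast), length(t_glu))),
    glucose = g)
  attr(out, "fasting_level") <- fast
  attr(out, "peak_delta") <- delta
  attr(out, "peak_time") <- tp
  out
}

#' Forward hemodynamic model for one channel
#'
#' HbO change is an affine function of the glucose excursion plus cardiac,
#' respiratory and Mayer-wave sinusoids and white noise; HbR is the
#' anti-correlated scaled mirror of HbO with independent noise. Uncoupled
#' channels have coupling coefficient 0.
#'
#' @param glucose_curve output of [generate_glucose_curve()].
#' @param config an [fnirs_config()].
#' @param channel channel index in `1..n_channels`.
#' @param beta coupling coefficient, uM per mmol/L; if `NULL`, drawn from the
#'   configured distribution for coupled channels and 0 otherwise.
#' @param seed seed for phases and noise.
#' @return list with `dhbo`, `dhbr` (uM) and the `beta` used.
#' @export
hemo_forward_model <- function(glucose_curve, config, channel,
                               beta = NULL, seed = config$rng_seed) {
  if (channel < 1 || channel > config$n_channels)
    stop("channel must lie in 1..n_channels", call. = FALSE)
  set.seed(derive_seed(seed, paste0("hemo", channel)))
  if (is.null(beta)) {
    beta <- if (channel %in% config$coupled_channels)
      config$coupling_beta_mean + config$coupling_beta_sd * stats::rnorm(1)
    else 0
  }
  t <- glucose_curve$time_s
  g_fast <- attr(glucose_curve, "fasting_level")
  if (is.null(g_fast)) g_fast <- mean(glucose_curve$glucose[glucose_curve$state == "fasting"])
  phases <- stats::runif(3, 0, 2 * pi)
  osc <- config$cardiac_amp * sin(2 * pi * config$cardiac_hz * t + phases[1]) +
    config$resp_amp * sin(2 * pi * config$resp_hz * t + phases[2]) +
    config$mayer_amp * sin(2 * pi * config$mayer_hz * t + phases[3])
  dhbo <- beta * (glucose_curve$glucose - g_fast) + osc +
    config$noise_sd * stats::rnorm(length(t))
  dhbr <- -config$hbr_ratio * dhbo +
    config$hbr_ratio * config$noise_sd * stats::rnorm(length(t))
  list(dhbo = dhbo, dhbr = dhbr, beta = beta)
}

#' Forward modified Beer-Lambert intensity model
#'
#' Maps chromophore concentration changes to dual-wavelength detected
#' intensity: `dOD(lambda) = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF / 1000`
#' (concentrations in uM, extinction coefficients in 1/(mM cm), separation in
#' cm) and `I = I0 * 10^-dOD`.
#'
#' @param dhbo,dhbr concentration-change series, uM.
#' @param optics an optics model from [default_optics()].
#' @param i0 baseline intensity.
#' @return time x 2 matrix of intensities, columns named by wavelength.
#' @export
forward_mbll_intensity <- function(dhbo, dhbr, optics = default_optics(),
                                   i0 = 0.5) {
  validate_optics(optics)
  conc <- cbind(dhbo, dhbr) / 1000           # uM -> mM
  path <- optics$d_cm * optics$dpf           # per-wavelength path, cm
  dod <- conc %*% t(optics$eps) * rep(path, each = length(dhbo))
  out <- i0 * 10^(-dod)
  colnames(out) <- rownames(optics$eps)
  out
}

#' Inject spike and baseline-shift motion artifacts
#'
#' Adds exponential-decay transients ("spikes") and step baseline shifts at
#' Poisson-distributed times to a recording's intensity array. Events mimic
#' head motion and are applied to every channel and wavelength.
#'
#' @param intensity time x channel x wavelength array.
#' @param config an [fnirs_config()] (rates are read from it).
#' @param sampling_rate Hz.
#' @param seed integer seed.
#' @return list `intensity` (corrupted array) and `events` (data.frame with
#'   columns time_s, type, magnitude, tau_s).
#' @export
inject_artifacts <- function(intensity, config, sampling_rate = config$sampling_rate,
                             seed = config$rng_seed) {
  if (config$artifact_spike_rate < 0 || config$artifact_shift_rate < 0)
    stop("artifact rates must be >= 0", call. = FALSE)
  n <- dim(intensity)[1]
  dur_min <- n / sampling_rate / 60
  set.seed(derive_seed(seed, "artifacts"))
  n_spike <- stats::rpois(1, config$artifact_spike_rate * dur_min)
  n_shift <- stats::rpois(1, config$artifact_shift_rate * dur_min)
  events <- data.frame(time_s = numeric(0), type = character(0),
                       magnitude = numeric(0), tau_s = numeric(0))
  if (n_spike + n_shift == 0)
    return(list(intensity = intensity, events = events))
  t <- (seq_len(n) - 1) / sampling_rate
  disturb <- numeric(n)
  if (n_spike > 0) {
    t0 <- stats::runif(n_spike, 0, max(t))
    amp <- sample(c(-1, 1), n_spike, replace = TRUE) *
      stats::runif(n_spike, 0.05, 0.2) * config$i0
    tau <- stats::runif(n_spike, 0.5, 2)
    for (k in seq_len(n_spike)) {
      idx <- t >= t0[k]
      disturb[idx] <- disturb[idx] + amp[k] * exp(-(t[idx] - t0[k]) / tau[k])
    }
    events <- rbind(events, data.frame(time_s = t0, type = "spike",
                                       magnitude = amp, tau_s = tau))
  }
  if (n_shift > 0) {
    t0 <- stats::runif(n_shift, 0, max(t))
    amp <- sample(c(-1, 1), n_shift, replace = TRUE) *
      stats::runif(n_shift, 0.01, 0.05) * config$i0
    for (k in seq_len(n_shift)) {
      idx <- t >= t0[k]
      disturb[idx] <- disturb[idx] + amp[k]
    }
    events <- rbind(events, data.frame(time_s = t0, type = "shift",
                                       magnitude = amp, tau_s = NA_real_))
  }
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  out <- intensity + array(disturb, dim = dim(intensity))
  out <- pmax(out, 1e-4 * config$i0)   # detectors cannot report <= 0
  list(intensity = out, events = events)
}

new_recording <- function(subject_id, state, intensity, sampling_rate,
                          geometry) {
  structure(list(subject_id = subject_id, state = state,
                 intensity = intensity, sampling_rate = sampling_rate,
                 geometry = geometry),
            class = "fnirs_recording")
}

default_geometry <- function(n_channels) {
  data.frame(channel = seq_len(n_channels),
             source = ((seq_len(n_channels) - 1L) %/% 2L) + 1L,
             detector = ((seq_len(n_channels) - 1L) %% 8L) + 1L,
             separation_mm = 30)
}

#' Generate a full synthetic cohort
#'
#' For every subject: draws the glucose curve, simulates per-channel
#' HbO/HbR via the forward hemodynamic model, maps them to dual-wavelength
#' intensity with the forward Beer-Lambert model, injects motion artifacts,
#' splits the session into fasting and glucose-state recordings, and samples
#' noisy reference fingertip glucose values. All ground truth (true curves,
#' coupling coefficients, artifact logs) is retained.
#'
#' @param config an [fnirs_config()].
#' @param optics optics model used for the forward intensity mapping.
#' @return an object of class `fnirs_cohort`: list with `config`, `optics`,
#'   and per-subject entries (`recordings$fasting`, `recordings$glucose`,
#'   `glucose_refs`, `truth`).
#' @export
generate_cohort <- function(config = fnirs_config(),
                            optics = default_optics(i0 = config$i0)) {
  validate_fnirs_config(config)
  set.seed(config$rng_seed)
  subject_seeds <- sample.int(2147483646L, config$n_subjects)
  subjects <- vector("list", config$n_subjects)
  geom <- default_geometry(config$n_channels)
  for (s in seq_len(config$n_subjects)) {
    subjects[[s]] <- simulate_subject(config, optics, s, subject_seeds[s], geom)
  }
  structure(list(config = config, optics = optics, subjects = subjects),
            class = "fnirs_cohort")
}

simulate_subject <- function(config, optics, subject_id, seed, geom) {
  curve <- generate_glucose_curve(config, seed)
  n <- nrow(curve)
  dhbo <- matrix(0, n, config$n_channels)
  dhbr <- matrix(0, n, config$n_channels)
  betas <- numeric(config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    hm <- hemo_forward_model(curve, config, ch, seed = seed)
    dhbo[, ch] <- hm$dhbo
    dhbr[, ch] <- hm$dhbr
    betas[ch] <- hm$beta
  }
  intensity <- array(0, dim = c(n, config$n_channels, 2),
                     dimnames = list(NULL, NULL, rownames(optics$eps)))
  for (ch in seq_len(config$n_channels)) {
    intensity[, ch, ] <- forward_mbll_intensity(dhbo[, ch], dhbr[, ch],
                                                optics, i0 = config$i0)
  }
  art <- inject_artifacts(intensity, config, config$sampling_rate, seed)
  fast_idx <- which(curve$state == "fasting")
  glu_idx <- which(curve$state == "glucose")
  recs <- list(
    fasting = new_recording(subject_id, "fasting",
                            art$intensity[fast_idx, , , drop = FALSE],
                            config$sampling_rate, geom),
    glucose = new_recording(subject_id, "glucose",
                            art$intensity[glu_idx, , , drop = FALSE],
                            config$sampling_rate, geom))
  refs <- sample_reference_glucose(curve, config, seed)
  list(subject_id = subject_id,
       recordings = recs,
       glucose_refs = refs,
       truth = list(curve = curve, dhbo = dhbo, dhbr = dhbr, betas = betas,
                    events = art$events))
}

## Reference fingertip samples at the midpoint of each window-sized interval,
## with meter noise.
sample_reference_glucose <- function(curve, config, seed) {
  set.seed(derive_seed(seed, "refs"))
  out <- list()
  for (st in c("fasting", "glucose")) {
    sub <- curve[curve$state == st, ]
    t0 <- min(sub$time_s)
    dur <- nrow(sub) / config$sampling_rate
    k <- floor(dur / config$glucose_sample_interval)
    if (k < 1) next
    centers <- t0 + (seq_len(k) - 0.5) * config$glucose_sample_interval
    idx <- vapply(centers, function(tc) which.min(abs(sub$time_s - tc)), 1L)
    out[[st]] <- data.frame(
      state = st, time_s = centers,
      glucose_mmol_per_l = sub$glucose[idx] +
        config$ref_noise_sd * stats::rnorm(k))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
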