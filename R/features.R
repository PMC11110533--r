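#' Cut glucose-referenced signal windows
#'
#' Averages HbO change across the selected channels, cuts non-overlapping
#' windows of `window_s` seconds per state, and attaches the reference
#' glucose value nearest each window center. Windows without a reference
#' within `window_s / 2` of their center are dropped with a warning.
#'
#' @param hemo_states per-subject list with `fasting` and `glucose`
#'   `fnirs_hemo` objects (from [preprocess_subject()]).
#' @param selected_channels integer channel indices to average over.
#' @param window_s window length, s.
#' @param glucose_refs data.frame with columns `state`, `time_s`,
#'   `glucose_mmol_per_l` (session time base).
#' @param subject_id identifier attached to each window.
#' @return list of windows; each is a list with `x` (samples, uM), `dt` (s),
#'   `subject_id`, `state`, `window_index`, `glucose`.
#' @export
segment_windows <- function(hemo_states, selected_channels, window_s,
                            glucose_refs, subject_id = NA_integer_) {
  stopifnot(length(selected_channels) >= 1)
  windows <- list()
  for (st in c("fasting", "glucose")) {
    hemo <- hemo_states[[st]]
    fs <- hemo$sampling_rate
    w <- round(window_s * fs)
    if (w > nrow(hemo$dhbo)) {
      if (st == "fasting") next else
        stop("window longer than recording", call. = FALSE)
    }
    sig <- rowMeans(hemo$dhbo[, selected_channels, drop = FALSE])
    refs <- glucose_refs[glucose_refs$state == st, ]
    k <- length(sig) %/% w
    offset <- if (is.null(hemo$time_offset_s)) 0 else hemo$time_offset_s
    for (i in seq_len(k)) {
      idx <- ((i - 1) * w + 1):(i * w)
      center <- offset + ((i - 1) * w + w / 2) / fs
      if (nrow(refs) == 0) {
        warning("window dropped: no glucose reference in state ", st,
                call. = FALSE)
        next
      }
      j <- which.min(abs(refs$time_s - center))
      if (abs(refs$time_s[j] - center) > window_s / 2) {
        warning("window dropped: nearest glucose reference ",
                round(abs(refs$time_s[j] - center)), " s from center",
                call. = FALSE)
        next
      }
      windows[[length(windows) + 1]] <- list(
        x = sig[idx], dt = 1 / fs, subject_id = subject_id, state = st,
        window_index = i, glucose = refs$glucose_mmol_per_l[j])
    }
  }
  windows
}

#' Ten time-series features of an HbO window
#'
#' Computes, on ordered samples `x_1..x_T` with step `dt`:
#' \describe{
#'   \item{lambda1}{mean, `(1/T) sum(x_i)`}
#'   \item{lambda2}{population standard deviation (divide by T)}
#'   \item{lambda3}{mean first difference, `(1/(T-1)) sum(x_i - x_{i-1})`}
#'   \item{lambda4}{population sd of the T-1 first differences}
#'   \item{lambda5}{mean second difference,
#'     `(1/(T-2)) sum(x_i - 2x_{i-1} + x_{i-2})`}
#'   \item{lambda6}{population sd of the T-2 second differences}
#'   \item{lambda7}{maximum}
#'   \item{lambda8}{peak-to-peak, max - min}
#'   \item{lambda9}{energy, `sum(x_i^2) dt`}
#'   \item{lambda10}{energy entropy, `-sum(x_i^2 ln(x_i^2)) dt` with the
#'     `0 ln 0 -> 0` convention (nats)}
#' }
#' Integrals are discretized as rectangle sums with step `dt`. All standard
#' deviations use population (divide-by-count) denominators.
#'
#' @param x numeric samples (at least 4).
#' @param dt sampling step, s.
#' @param normalized_entropy if TRUE, lambda10 is instead the Shannon entropy
#'   of the normalized energy distribution `p_i = x_i^2 / sum(x_j^2)`.
#' @return named numeric vector `lambda1..lambda10`.
#' @export
compute_features <- function(x, dt = 1, normalized_entropy = FALSE) {
  T <- length(x)
  if (T < 4) stop("window too short: need at least 4 samples", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  d1 <- diff(x)
  d2 <- diff(x, differences = 2)
  x2 <- x^2
  ent_terms <- ifelse(x2 > 0, x2 * log(x2), 0)
  lambda10 <- if (normalized_entropy) {
    p <- x2 / sum(x2)
    -sum(ifelse(p > 0, p * log(p), 0))
  } else {
    -sum(ent_terms) * dt
  }
  c(lambda1 = mean(x),
    lambda2 = pop_sd(x),
    lambda3 = mean(d1),
    lambda4 = pop_sd(d1),
    lambda5 = mean(d2),
    lambda6 = pop_sd(d2),
    lambda7 = max(x),
    lambda8 = max(x) - min(x),
    lambda9 = sum(x2) * dt,
    lambda10 = lambda10)
}

#' Feature table for a list of windows
#'
#' @param windows list from [segment_windows()].
#' @return data.frame with subject_id, state, window_index,
#'   lambda1..lambda10, glucose_mmol_per_l.
#' @export
feature_table <- function(windows) {
  rows <- lapply(windows, function(w) {
    f <- compute_features(w$x, w$dt)
    cbind(data.frame(subject_id = w$subject_id, state = w$state,
                     window_index = w$window_index),
          as.data.frame(as.list(f)),
          data.frame(glucose_mmol_per_l = w$glucose))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

feature_names <- function() paste0("lambda", 1:10)
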