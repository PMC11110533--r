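#' Two-sample t-test between fasting and glucose states
#'
#' Welch two-sample t statistic on per-subject mean-HbO samples, with the
#' one-sided tail convention `p = P(T <= -|t|)` by default (the convention
#' under which printed channel tables with pairs like t = -1.91, p = 0.028
#' are internally consistent at large df). A two-sided option is exposed.
#' Degenerate input (both groups constant and equal) returns t = 0 and the
#' null-central p (0.5 one-sided, 1 two-sided).
#'
#' @param fasting_samples,glucose_samples numeric vectors (>= 2 values each).
#' @param tails "one" (default) or "two".
#' @return list with `t`, `p`, `df`, `fasting_variance`, `glucose_variance`.
#' @export
state_ttest <- function(fasting_samples, glucose_samples,
                        tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (length(fasting_samples) < 2 || length(glucose_samples) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  v1 <- stats::var(fasting_samples)
  v2 <- stats::var(glucose_samples)
  if (v1 == 0 && v2 == 0) {
    return(list(t = 0, p = if (tails == "one") 0.5 else 1,
                df = NA_real_, fasting_variance = v1, glucose_variance = v2))
  }
  tt <- stats::t.test(fasting_samples, glucose_samples, var.equal = FALSE)
  p <- if (tails == "one") tt$p.value / 2 else tt$p.value
  list(t = unname(tt$statistic), p = p, df = unname(tt$parameter),
       fasting_variance = v1, glucose_variance = v2)
}

#' Per-channel state-difference statistics
#'
#' For every channel, tests whether per-subject window means of HbO change
#' differ between the fasting and glucose states. The unit of replication is
#' one value per subject per window per state (window means), pooled across
#' subjects.
#'
#' @param hemo_by_subject list of per-subject results from
#'   [preprocess_subject()] (elements with `fasting` and `glucose`
#'   `fnirs_hemo` objects).
#' @param window_s window length for the within-state means, s. The default
#'   (60 s) is deliberately shorter than the feature windows: with
#'   baseline-referenced optical density a single fasting-length window mean
#'   is pinned near zero by construction, which degenerates the fasting
#'   group variance; minute-scale windows give both states genuine
#'   within-state spread.
#' @param tails tail convention passed to [state_ttest()].
#' @param alpha significance level for the `selected` flag.
#' @return data.frame with channel, fasting_variance, glucose_variance, t, p,
#'   selected.
#' @export
channel_state_stats <- function(hemo_by_subject, window_s = 60,
                                tails = "one", alpha = 0.05) {
  nch <- ncol(hemo_by_subject[[1]]$fasting$dhbo)
  window_means <- function(hemo, ch) {
    w <- round(window_s * hemo$sampling_rate)
    v <- hemo$dhbo[, ch]
    k <- length(v) %/% w
    if (k < 1) return(mean(v))
    vapply(seq_len(k), function(i) mean(v[((i - 1) * w + 1):(i * w)]), 0)
  }
  rows <- lapply(seq_len(nch), function(ch) {
    fast <- unlist(lapply(hemo_by_subject, function(s) window_means(s$fasting, ch)))
    glu <- unlist(lapply(hemo_by_subject, function(s) window_means(s$glucose, ch)))
    st <- state_ttest(fast, glu, tails)
    data.frame(channel = ch,
               fasting_variance = st$fasting_variance,
               glucose_variance = st$glucose_variance,
               t = st$t, p = st$p)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p < alpha
  out
}

#' Select significant channels
#'
#' Channels with `p < alpha`, in ascending channel order. An optional
#' Benjamini-Hochberg correction is available (off by default, matching a
#' raw p < 0.05 rule).
#'
#' @param stats data.frame with columns `channel` and `p`.
#' @param alpha significance level.
#' @param adjust "none" (default) or "BH".
#' @return integer vector of selected channels (possibly empty).
#' @export
select_channels <- function(stats, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- stats$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sel <- sort(stats$channel[p < alpha])
  if (length(sel) == 0)
    message("no channels reached p < ", alpha)
  as.integer(sel)
}
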