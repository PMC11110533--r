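make_rec <- function(intensity, fs = 10) {
  fnirsglucose:::new_recording(1L, "fasting", intensity, fs,
                               fnirsglucose:::default_geometry(dim(intensity)[2]))
}

test_that("channel pruning applies the intensity range and SNR rules", {
  n <- 100
  arr <- array(0, dim = c(n, 4, 2))
  arr[, 1, ] <- 0.5                                   # constant: kept
  arr[, 2, ] <- 5.0                                   # above range: pruned
  arr[, 3, ] <- rep(c(0.2, 0.8), n / 2)               # SNR 1.66: pruned
  set.seed(1)
  arr[, 4, ] <- 0.5 + rnorm(n, sd = 0.01)             # high SNR: kept
  keep <- prune_channels(make_rec(arr))
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE))
  ## all channels bad -> explicit error
  bad <- array(5, dim = c(n, 2, 2))
  expect_error(prune_channels(make_rec(bad)), "no usable channels")
})

test_that("optical density conversion matches the per-sample definition", {
  n <- 200
  arr <- array(0.5, dim = c(n, 2, 2))
  od <- intensity_to_od(make_rec(arr))
  expect_true(all(od == 0))                           # constant intensity
  set.seed(2)
  arr[, 1, 1] <- runif(n, 0.45, 0.55)
  od <- intensity_to_od(make_rec(arr))
  expect_equal(od[, 1, 1], oracle_od(arr[, 1, 1]), tolerance = 1e-12)
  expect_lt(abs(mean(od[, 1, 1])), 1e-3)   # zero up to log-concavity bias
  ## a sample at Iref/10 sits exactly one decade up
  v <- c(1, 0.1, 1, 1)
  od2 <- intensity_to_od(make_rec(array(v, dim = c(4, 1, 1))))
  expect_equal(od2[2, 1, 1], -log10(0.1 / mean(v)) - 0, tolerance = 1e-12)
  ## nonpositive sample -> error naming position
  arr[10, 2, 1] <- 0
  expect_error(intensity_to_od(make_rec(arr)), "time index 10, channel 2")
})

test_that("motion artifact detection flags steps and respects shape", {
  fs <- 10; n <- 600
  set.seed(3)
  clean <- array(0.001 * rnorm(n), dim = c(n, 1, 1))
  mask <- detect_motion_artifacts(clean, fs, amp_thresh = 0.2)
  expect_identical(dim(mask), c(n, 1L) |> as.integer())
  expect_false(any(mask))
  stepped <- clean
  stepped[300:n, 1, 1] <- stepped[300:n, 1, 1] + 2    # 10x amp_thresh
  mask2 <- detect_motion_artifacts(stepped, fs, t_mask = 1, amp_thresh = 0.2)
  expect_true(any(mask2[, 1]))
  expect_true(all(which(mask2[, 1]) >= 300 - fs - 10))
  expect_true(all(which(mask2[, 1]) <= 300 + fs + 10))
  expect_error(detect_motion_artifacts(clean, fs, t_motion = 100),
               "longer than series")
})

test_that("db2 wavelet transform reconstructs perfectly and is orthogonal", {
  set.seed(4)
  for (n in c(64, 256, 1024)) {
    x <- rnorm(n)
    dec <- fnirsglucose:::dwt_db2(x, 3)
    expect_equal(fnirsglucose:::idwt_db2(dec), x, tolerance = 1e-10)
    ## orthogonality: coefficient energy equals signal energy
    energy <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-10)
  }
})

test_that("wavelet correction removes spikes but preserves in-band signal", {
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  sine <- 0.01 * sin(2 * pi * 0.05 * t)
  ## in-band sinusoid: RMS within 10%
  corr <- wavelet_motion_correct(sine, sampling_rate = fs)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(corr) - rms(sine)) / rms(sine), 0.1)
  ## zero in, zero out (linearity)
  expect_true(all(wavelet_motion_correct(rep(0, 512), sampling_rate = fs) == 0))
  ## spike of amplitude A attenuated by >= 80%
  spike <- sine
  idx <- which(t >= 300 & t < 302)
  spike[idx] <- spike[idx] + 0.2 * exp(-(t[idx] - 300) / 0.5)
  corr2 <- wavelet_motion_correct(spike, sampling_rate = fs)
  residual <- corr2 - sine
  expect_lt(max(abs(residual[idx])), 0.2 * 0.2)
  expect_error(wavelet_motion_correct(rnorm(8), sampling_rate = fs, level = 9),
               "2\\^level|too short")
})

test_that("band filter gains meet the pass/stop specification", {
  fs <- 10
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  gain <- function(f) {
    y <- bandpass_filter(sin(2 * pi * f * t), 0.01, 0.1, fs)
    measure_amplitude(y)
  }
  expect_gt(gain(0.05), 0.9)
  expect_lt(gain(0.5), 0.1)
  dc <- bandpass_filter(rep(1, length(t)), 0.01, 0.1, fs)
  expect_lt(measure_amplitude(dc), 0.1)
  y <- bandpass_filter(sin(2 * pi * 0.05 * t), 0.01, 0.1, fs)
  expect_length(y, length(t))
  expect_error(bandpass_filter(t, 0.2, 0.1, fs), "band")
  expect_error(bandpass_filter(t, 0.01, 6, fs), "band")
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  optics <- default_optics()
  ## fixed pair round trip
  I <- forward_mbll_intensity(1.0, -0.5, optics, i0 = 0.5)
  od <- array(-log10(I / 0.5), dim = c(1, 1, 2))
  h <- od_to_hemo(od, optics)
  expect_equal(h$dhbo[1, 1], 1.0, tolerance = 1e-8)
  expect_equal(h$dhbr[1, 1], -0.5, tolerance = 1e-8)
  ## random optics within physical ranges, random concentrations
  set.seed(5)
  for (rep in 1:25) {
    eps <- rbind("760" = c(hbo = runif(1, 0.4, 0.8), hbr = runif(1, 1.2, 1.8)),
                 "830" = c(hbo = runif(1, 0.8, 1.2), hbr = runif(1, 0.5, 0.9)))
    opt <- default_optics(eps = eps, dpf = runif(2, 4, 8), d_cm = runif(1, 2.5, 3.5))
    hbo <- rnorm(20); hbr <- rnorm(20)
    I <- forward_mbll_intensity(hbo, hbr, opt, i0 = 0.5)
    od <- array(0, dim = c(20, 1, 2)); od[, 1, ] <- -log10(I / 0.5)
    h <- od_to_hemo(od, opt)
    expect_lt(max(abs(h$dhbo[, 1] - hbo)), 1e-8)
    expect_lt(max(abs(h$dhbr[, 1] - hbr)), 1e-8)
  }
  ## zero OD maps to zero concentrations; linearity in OD
  z <- array(0, dim = c(5, 1, 2))
  h0 <- od_to_hemo(z, optics)
  expect_true(all(h0$dhbo == 0) && all(h0$dhbr == 0))
})

test_that("CBSI enforces exact anti-correlation and matches the formula", {
  set.seed(6)
  n <- 300
  hbo <- rnorm(n); hbr <- 0.4 * rnorm(n) - 0.2 * hbo
  hemo <- list(dhbo = cbind(hbo), dhbr = cbind(hbr))
  out <- cbsi_correct(hemo)
  expect_equal(cor(out$dhbo[, 1], out$dhbr[, 1]), -1, tolerance = 1e-10)
  orc <- oracle_cbsi(hbo, hbr)
  expect_equal(out$dhbo[, 1], orc$dhbo, tolerance = 1e-10)
  expect_equal(out$dhbr[, 1], orc$dhbr, tolerance = 1e-10)
  ## perfectly mirrored input is a fixed point of the HbO branch
  hemo2 <- list(dhbo = cbind(hbo), dhbr = cbind(-hbo))
  out2 <- cbsi_correct(hemo2)
  expect_equal(out2$dhbo[, 1], hbo, tolerance = 1e-10)
  ## zero-variance HbR skipped with warning
  hemo3 <- list(dhbo = cbind(hbo), dhbr = cbind(rep(0, n)))
  expect_warning(out3 <- cbsi_correct(hemo3), "zero-variance")
  expect_true(out3$cbsi_skipped[1])
})

test_that("preprocessing chain recovers ground truth on a clean channel", {
  cfg <- fnirs_config(n_subjects = 1, n_channels = 2, coupled_channels = 1L,
                      sampling_rate = 4, fasting_duration = 300,
                      glucose_duration = 1200, peak_time_mean = 400,
                      peak_time_sd = 0, noise_sd = 0,
                      fasting_glucose_noise_sd = 0,
                      cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                      artifact_spike_rate = 0, artifact_shift_rate = 0,
                      glucose_sample_interval = 150, rng_seed = 31)
  coh <- generate_cohort(cfg)
  hemo <- preprocess_subject(coh$subjects[[1]],
                             params = preprocess_params(cbsi = FALSE))
  got <- c(hemo$fasting$dhbo[, 1], hemo$glucose$dhbo[, 1])
  truth <- coh$subjects[[1]]$truth$dhbo[, 1]
  expect_gt(cor(got, truth), 0.95)
  ## provenance records the chain in order
  expect_identical(hemo$fasting$provenance,
                   c("prune_channels", "intensity_to_od",
                     "detect_motion_artifacts", "wavelet_motion_correct",
                     "bandpass_filter", "od_to_hemo"))
  ## disabling all corrections reduces to prune -> OD -> MBLL
  plain <- run_preprocessing(coh$subjects[[1]]$recordings$fasting,
                             preprocess_params(motion_detect = FALSE,
                                               wavelet = FALSE,
                                               filter = FALSE, cbsi = FALSE))
  expect_identical(plain$provenance,
                   c("prune_channels", "intensity_to_od", "od_to_hemo"))
})
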