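test_that("glucose curve has the deterministic excursion shape", {
  cfg <- fnirs_config(fasting_glucose_mean = 5, fasting_glucose_sd = 0,
                      peak_delta_mean = 3, peak_delta_sd = 0,
                      fasting_glucose_noise_sd = 0, peak_time_sd = 0,
                      sampling_rate = 2)
  curve <- generate_glucose_curve(cfg, subject_seed = 7)
  expect_equal(max(curve$glucose), 8.0, tolerance = 1e-12)
  expect_equal(curve$time_s[which.max(curve$glucose)],
               cfg$fasting_duration + attr(curve, "peak_time"))
  ## fasting segment constant at the fasting level
  fast <- curve$glucose[curve$state == "fasting"]
  expect_true(all(fast == 5))
  ## post-peak decays toward the plateau, staying above fasting
  glu <- curve$glucose[curve$state == "glucose"]
  expect_true(all(glu >= 5))
  tail_val <- glu[length(glu)]
  expect_lt(tail_val, 8)
  expect_gt(tail_val, 5 + 0.3 * 3 - 0.05)
  ## continuity at the state boundary
  n_fast <- sum(curve$state == "fasting")
  expect_lt(abs(curve$glucose[n_fast + 1] - curve$glucose[n_fast]), 0.05)
})

test_that("fasting fluctuations stay within the configured noise budget", {
  vars <- vapply(1:100, function(s) {
    cfg <- tiny_config(seed = s)
    curve <- generate_glucose_curve(cfg, subject_seed = s)
    var(curve$glucose[curve$state == "fasting"])
  }, 0)
  expect_lt(mean(vars), 3 * fnirs_config()$fasting_glucose_noise_sd^2)
})

test_that("same seed reproduces the same curve and cohort bit-for-bit", {
  cfg <- tiny_config(seed = 11)
  c1 <- generate_glucose_curve(cfg, 99)
  c2 <- generate_glucose_curve(cfg, 99)
  expect_identical(c1, c2)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)
})

test_that("forward hemodynamic model couples HbO to glucose as configured", {
  cfg <- tiny_config(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                     noise_sd = 0, fasting_glucose_noise_sd = 0)
  curve <- generate_glucose_curve(cfg, 5)
  ## beta = 0 and all noise off: identically zero
  h0 <- hemo_forward_model(curve, cfg, channel = 1, beta = 0, seed = 5)
  expect_true(all(h0$dhbo == 0))
  ## beta > 0, noise off: exact affine relation with glucose
  h1 <- hemo_forward_model(curve, cfg, channel = 7, beta = 0.2, seed = 5)
  expect_equal(cor(h1$dhbo, curve$glucose), 1, tolerance = 1e-10)
  ## uncoupled channels draw beta 0, coupled channels nonzero
  expect_identical(hemo_forward_model(curve, tiny_config(), 1, seed = 5)$beta, 0)
  expect_gt(abs(hemo_forward_model(curve, tiny_config(), 7, seed = 5)$beta), 0)
})

test_that("HbO and HbR are anti-correlated on coupled channels", {
  negs <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = s)
    curve <- generate_glucose_curve(cfg, s)
    h <- hemo_forward_model(curve, cfg, channel = 12, seed = s)
    cor(h$dhbo, h$dhbr)
  }, 0)
  expect_true(all(negs < 0))
})

test_that("forward Beer-Lambert intensity behaves linearly in path length", {
  optics <- default_optics()
  n <- 50
  z <- rep(0, n)
  expect_equal(unname(forward_mbll_intensity(z, z, optics, i0 = 0.7)),
               matrix(0.7, n, 2), tolerance = 1e-12)
  set.seed(3)
  hbo <- rnorm(n); hbr <- rnorm(n)
  od1 <- -log10(forward_mbll_intensity(hbo, hbr, optics, 1))
  optics2 <- default_optics(dpf = optics$dpf * 2)
  od2 <- -log10(forward_mbll_intensity(hbo, hbr, optics2, 1))
  expect_equal(od2, 2 * od1, tolerance = 1e-10)
  expect_error(default_optics(eps = matrix(1, 2, 2)), "nonsingular")
})

test_that("artifact injection is Poisson-distributed, logged and seeded", {
  cfg <- tiny_config()
  arr <- array(0.5, dim = c(1200, 2, 2))   # 5 min at 4 Hz
  ## zero rates: identity with empty log
  cfg0 <- tiny_config(artifact_spike_rate = 0, artifact_shift_rate = 0)
  out0 <- inject_artifacts(arr, cfg0, sampling_rate = 4, seed = 1)
  expect_identical(out0$intensity, arr)
  expect_identical(nrow(out0$events), 0L)
  ## spike rate 6/min over 10 min: count in the Poisson 99% interval
  cfg6 <- tiny_config(artifact_spike_rate = 6, artifact_shift_rate = 0)
  arr10 <- array(0.5, dim = c(2400, 1, 2)) # 10 min at 4 Hz
  counts <- vapply(1:20, function(s)
    nrow(inject_artifacts(arr10, cfg6, sampling_rate = 4, seed = s)$events), 0L)
  lo <- qpois(0.005, 60); hi <- qpois(0.995, 60)
  expect_true(all(counts >= lo & counts <= hi))
  ## seeded determinism of the event log
  e1 <- inject_artifacts(arr10, cfg6, sampling_rate = 4, seed = 42)$events
  e2 <- inject_artifacts(arr10, cfg6, sampling_rate = 4, seed = 42)$events
  expect_identical(e1, e2)
})

test_that("cohort has the full design shape and ground truth", {
  cfg <- tiny_config(seed = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, cfg$n_subjects)
  sub <- coh$subjects[[1]]
  expect_identical(dim(sub$recordings$fasting$intensity),
                   c(cfg$fasting_duration * cfg$sampling_rate,
                     cfg$n_channels, 2L) |> as.integer())
  expect_identical(dim(sub$recordings$glucose$intensity)[1],
                   as.integer(cfg$glucose_duration * cfg$sampling_rate))
  ## coupling restricted to the configured channels
  expect_true(all(sub$truth$betas[-cfg$coupled_channels] == 0))
  expect_true(all(sub$truth$betas[cfg$coupled_channels] != 0))
  ## reference glucose sampled in both states
  expect_setequal(unique(sub$glucose_refs$state), c("fasting", "glucose"))
})

test_that("coupled channels show larger state contrasts than uncoupled ones", {
  diffs <- replicate(20, {
    cfg <- tiny_config(seed = sample.int(1e6, 1))
    curve <- generate_glucose_curve(cfg, cfg$rng_seed)
    vapply(c(7, 1), function(ch) {
      h <- hemo_forward_model(curve, cfg, ch, seed = cfg$rng_seed)
      abs(mean(h$dhbo[curve$state == "glucose"]) -
            mean(h$dhbo[curve$state == "fasting"]))
    }, 0)
  })
  expect_gt(mean(diffs[1, ]), mean(diffs[2, ]))
  expect_gt(mean(diffs[1, ] > diffs[2, ]), 0.9)
})

test_that("cohort serialization round-trips", {
  cfg <- fnirs_config(n_subjects = 2, n_channels = 3, sampling_rate = 2,
                      fasting_duration = 60, glucose_duration = 240,
                      peak_time_mean = 120, peak_time_sd = 10,
                      glucose_sample_interval = 60,
                      coupled_channels = 2L, rng_seed = 8)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$config$n_subjects, cfg$n_subjects)
  expect_equal(back$subjects[[1]]$recordings$fasting$intensity,
               coh$subjects[[1]]$recordings$fasting$intensity,
               tolerance = 1e-12)
  expect_equal(back$subjects[[2]]$glucose_refs$glucose_mmol_per_l,
               coh$subjects[[2]]$glucose_refs$glucose_mmol_per_l,
               tolerance = 1e-12)
  ## write -> read -> write is byte-identical
  dir2 <- withr::local_tempdir()
  write_cohort(back, dir2)
  expect_identical(readLines(file.path(dir, "intensity.csv")),
                   readLines(file.path(dir2, "intensity.csv")))
  expect_error(read_cohort(withr::local_tempdir()), "missing cohort file")
})

test_that("invalid configurations are rejected", {
  expect_error(fnirs_config(fasting_duration = -1), "positive")
  expect_error(fnirs_config(noise_sd = -0.1), ">= 0")
  expect_error(fnirs_config(coupled_channels = 25), "coupled_channels")
})
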