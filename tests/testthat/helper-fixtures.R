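# Shared fixture builders. Unit tests use small, fast cohorts; the
# statistical acceptance checks use the default study design (15 subjects,
# 21 channels, 10 min fasting + 60 min glucose) at a reduced 2 Hz sampling
# rate to keep the suite inside its runtime budget without changing the
# study conditions the generator encodes.

tiny_config <- function(seed = 1L, ...) {
  fnirs_config(n_subjects = 3, sampling_rate = 4, fasting_duration = 120,
               glucose_duration = 600, peak_time_mean = 240,
               peak_time_sd = 30, glucose_sample_interval = 120,
               rng_seed = seed, ...)
}

study_config <- function(seed = 1L, ...) {
  fnirs_config(sampling_rate = 2, rng_seed = seed, ...)
}

# analysis-scale preprocessing (keeps the slow metabolic trend)
analysis_params <- function(...) preprocess_params(...)

channel_stats_example <- function() {
  read.csv(system.file("extdata", "channel_stats_example.csv",
                       package = "fnirsglucose"))
}
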