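# Shared fixtures and independent oracles used across test files.

# Small, fast simulation settings for tests that only need structure, not
# power: 20 patients, 90-minute surgeries.
quick_config <- function(n_patients = 20, surgery_duration_min = 90, ...) {
  sim_config(n_patients = n_patients,
             surgery_duration_min = surgery_duration_min, ...)
}

# Noise-free settings: every stochastic component switched off.
silent_config <- function(...) {
  sim_config(common_mode_sd = c(latency = 0, amplitude = 0),
             measurement_noise_sd = c(latency = 0, amplitude = 0),
             interaural_asym_sd = 0,
             patient_scale_sd = c(latency = 0, amplitude = 0),
             dropout_prob = 0,
             audiometry = list(wrs_min = 20, wrs_max = 95, pta_min = 15,
                               pta_max = 85, wrs_noise_sd = 0,
                               pta_noise_sd = 0),
             ...)
}

# Exhaustive concordant-pair AUC oracle (ties half-counted).
brute_auc <- function(score, y) {
  pos <- score[as.logical(y)]
  neg <- score[!as.logical(y)]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Brute-force Youden maximizer over all observed thresholds, for a fixed
# calling direction.
brute_youden <- function(score, y, ge = TRUE) {
  y <- as.logical(y)
  best <- -Inf
  best_c <- NA_real_
  for (c0 in sort(unique(score))) {
    call_pos <- if (ge) score >= c0 else score <= c0
    j <- mean(call_pos[y]) + mean(!call_pos[!y]) - 1
    if (j > best + 1e-12) {
      best <- j
      best_c <- c0
    }
  }
  list(cutoff = best_c, youden = best)
}

# Random indicator vector with waves kept clear of each other so that
# noise-free synthesis -> extraction is a well-posed round trip.
random_wave_features <- function() {
  lat <- c(la_i = runif(1, 1.3, 2.0), la_ii = runif(1, 2.55, 3.05),
           la_iii = runif(1, 3.5, 4.2), la_iv = runif(1, 4.7, 5.2),
           la_v = runif(1, 5.75, 6.6))
  c(as.list(lat),
    list(am_i = runif(1, 0.1, 0.5), am_v = runif(1, 0.1, 0.5)))
}

# A minimal one-sided feature stream for pairing tests.
stream <- function(timestamps, phase = "pre_resection", la_v = 5.7,
                   am_v = 0.3) {
  n <- length(timestamps)
  data.frame(timestamp_s = timestamps, phase = rep_len(phase, n),
             la_v = rep_len(la_v, n), am_v = rep_len(am_v, n))
}

# Phase summary built directly from named affected/healthy vectors.
make_summary <- function(affected, healthy, phase = "pre_resection",
                         n_pairs = 1L) {
  structure(list(phase = phase, n_pairs = n_pairs,
                 affected = affected, healthy = healthy),
            class = "baep_phase_summary")
}

# Latency columns free of the additive injury term (wave V carries it).
BAEP_WAVES_TEST <- c("la_i", "la_ii", "la_iii", "la_iv")
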