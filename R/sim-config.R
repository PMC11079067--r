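#' Configuration for the synthetic binaural BAEP cohort simulator
#'
#' Builds a validated configuration object describing the study conditions the
#' simulator reproduces: an intraoperative timeline with one averaged epoch
#' roughly every 2.8 minutes per ear (2000 sweeps at an 11.9 Hz click rate),
#' a large common-mode interference component shared by both ears, injury
#' effects confined to the affected side and driven by a latent
#' cochlear-nerve-function variable, and audiometric outcomes (PTA/WRS)
#' generated from that same latent variable.
#'
#' @param n_patients Number of patients to simulate (default 127, the size of
#'   a typical single-centre vestibular schwannoma series).
#' @param seed Integer RNG seed; the whole cohort is a deterministic function
#'   of the configuration and this seed.
#' @param surgery_duration_min Total monitored surgery duration, minutes.
#' @param epoch_interval_s Seconds between successive averaged epochs on one
#'   ear. Default 168 s, i.e. 2000 sweeps / 11.9 Hz.
#' @param ear_offset_s Offset between the affected-side and healthy-side epoch
#'   grids, seconds. Interleaved acquisition; exercises the synchronous-pairing
#'   rule non-trivially.
#' @param dropout_prob Probability that any single epoch is lost (electrode
#'   checks, cautery bursts); breaks some affected/healthy pairs.
#' @param reference_latencies Named vector of noise-free baseline wave
#'   latencies in ms, names `la_i`..`la_v`; must be strictly increasing.
#' @param reference_amplitudes Named vector of baseline amplitudes in uV for
#'   `am_i` and `am_v` (BAEP amplitudes are sub-microvolt, 0.1-0.5 uV).
#' @param injury_effect_latency Wave-V latency prolongation in ms per unit
#'   loss of latent cochlear function (affected side only).
#' @param injury_effect_amplitude Fractional wave-V amplitude loss per unit
#'   loss of latent cochlear function (affected side only).
#' @param common_mode_sd Named vector `c(latency=, amplitude=)`: standard
#'   deviation, over the whole surgery, of the two multiplicative log-random
#'   walks (one for latencies, one for amplitudes) applied identically to both
#'   ears.
#' @param measurement_noise_sd Named vector `c(latency=, amplitude=)`:
#'   additive per-epoch measurement noise sd (ms / uV) on each indicator.
#' @param interaural_asym_sd Log-sd of the fixed amplitude asymmetry between a
#'   patient's two ears (electrode placement, anatomy); this is the noise
#'   healthy-side referencing cannot cancel.
#' @param patient_scale_sd Named vector `c(latency=, amplitude=)`: log-sd of
#'   per-patient global scale factors shared by both ears.
#' @param hp_link_slope,hp_link_intercept Slope and midpoint of the logistic
#'   link from latent cochlear function to WRS.
#' @param audiometry List with elements `wrs_min`, `wrs_max` (% at latent
#'   function 0 and 1), `pta_min`, `pta_max` (dB at function 1 and 0),
#'   `wrs_noise_sd`, `pta_noise_sd` (test-retest noise).
#' @param p_preop_hp Target probability that a patient has preoperative
#'   hearing preservation (WRS >= 50 before noise).
#' @param injury_max Maximum injury depth; injury per patient is drawn
#'   Uniform(0, `injury_max`) on the latent-function scale.
#' @param resection_window Length-2 fractions of the surgery at which tumour
#'   exposure may start and complete resection may end.
#'
#' @return An object of class `baep_sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_hearing()]
#' @export
sim_config <- function(n_patients = 127L,
                       seed = 1L,
                       surgery_duration_min = 240,
                       epoch_interval_s = 168,
                       ear_offset_s = 60,
                       dropout_prob = 0.05,
                       reference_latencies = c(la_i = 1.7, la_ii = 2.8,
                                               la_iii = 3.9, la_iv = 5.1,
                                               la_v = 5.7),
                       reference_amplitudes = c(am_i = 0.15, am_v = 0.30),
                       injury_effect_latency = 0.6,
                       injury_effect_amplitude = 0.8,
                       common_mode_sd = c(latency = 0.02, amplitude = 0.25),
                       measurement_noise_sd = c(latency = 0.05,
                                                amplitude = 0.02),
                       interaural_asym_sd = 0.05,
                       patient_scale_sd = c(latency = 0.02, amplitude = 0.20),
                       hp_link_slope = 6,
                       hp_link_intercept = 0.5,
                       audiometry = list(wrs_min = 20, wrs_max = 95,
                                         pta_min = 15, pta_max = 85,
                                         wrs_noise_sd = 3, pta_noise_sd = 4),
                       p_preop_hp = 0.66,
                       injury_max = 0.62,
                       resection_window = c(0.25, 0.75)) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              surgery_duration_min = surgery_duration_min,
              epoch_interval_s = epoch_interval_s, ear_offset_s = ear_offset_s,
              dropout_prob = dropout_prob,
              reference_latencies = reference_latencies,
              reference_amplitudes = reference_amplitudes,
              injury_effect_latency = injury_effect_latency,
              injury_effect_amplitude = injury_effect_amplitude,
              common_mode_sd = common_mode_sd,
              measurement_noise_sd = measurement_noise_sd,
              interaural_asym_sd = interaural_asym_sd,
              patient_scale_sd = patient_scale_sd,
              hp_link_slope = hp_link_slope,
              hp_link_intercept = hp_link_intercept,
              audiometry = audiometry,
              p_preop_hp = p_preop_hp, injury_max = injury_max,
              resection_window = resection_window)
  validate_sim_config(cfg)
  structure(cfg, class = "baep_sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_scalar_number(cfg$n_patients) || cfg$n_patients < 1)
    stop_config("n_patients must be a positive integer, got %s",
                format(cfg$n_patients))
  if (!is_scalar_number(cfg$epoch_interval_s) || cfg$epoch_interval_s <= 0)
    stop_config("epoch_interval_s must be > 0")
  if (!is_scalar_number(cfg$p_preop_hp) ||
      cfg$p_preop_hp < 0 || cfg$p_preop_hp > 1)
    stop_config("p_preop_hp must lie in [0, 1]")
  scales <- c(cfg$dropout_prob, cfg$injury_effect_latency,
              cfg$injury_effect_amplitude, cfg$common_mode_sd,
              cfg$measurement_noise_sd, cfg$interaural_asym_sd,
              cfg$patient_scale_sd, cfg$audiometry$wrs_noise_sd,
              cfg$audiometry$pta_noise_sd, cfg$injury_max)
  if (any(!is.finite(scales)) || any(scales < 0))
    stop_config("all noise/effect scales must be finite and nonnegative")
  lat <- cfg$reference_latencies[BAEP_WAVES]
  if (anyNA(lat))
    stop_config("reference_latencies must name %s",
                paste(BAEP_WAVES, collapse = ", "))
  if (any(diff(lat) <= 0))
    stop_config("reference latencies must be strictly increasing I < II < III < IV < V")
  amp <- cfg$reference_amplitudes[BAEP_AMPLITUDES]
  if (anyNA(amp) || any(amp <= 0))
    stop_config("reference_amplitudes must be positive for am_i and am_v")
  for (nm in c("common_mode_sd", "measurement_noise_sd", "patient_scale_sd"))
    if (anyNA(cfg[[nm]][c("latency", "amplitude")]))
      stop_config("%s must name 'latency' and 'amplitude'", nm)
  rw <- cfg$resection_window
  if (length(rw) != 2 || rw[1] >= rw[2] || rw[1] <= 0 || rw[2] >= 1)
    stop_config("resection_window must be fractions 0 < start < end < 1")
  invisible(cfg)
}

#' @export
print.baep_sim_config <- function(x, ...) {
  cat("BAEP cohort simulation config\n")
  cat(sprintf("  patients: %d  seed: %d  surgery: %g min, epoch every %g s (offset %g s)\n",
              x$n_patients, x$seed, x$surgery_duration_min,
              x$epoch_interval_s, x$ear_offset_s))
  cat(sprintf("  common-mode sd (lat/amp): %g / %g   measurement sd: %g ms / %g uV\n",
              x$common_mode_sd[["latency"]], x$common_mode_sd[["amplitude"]],
              x$measurement_noise_sd[["latency"]],
              x$measurement_noise_sd[["amplitude"]]))
  cat(sprintf("  injury effects: +%g ms, -%g frac amplitude per unit function loss\n",
              x$injury_effect_latency, x$injury_effect_amplitude))
  cat(sprintf("  preop HP target: %g\n", x$p_preop_hp))
  invisible(x)
}

## Latent cochlear function value at which the noise-free WRS crosses 50%
## (the hearing-preservation boundary).
hp_function_threshold <- function(cfg) {
  au <- cfg$audiometry
  g_star <- (50 - au$wrs_min) / (au$wrs_max - au$wrs_min)
  s <- cfg$hp_link_slope
  m <- cfg$hp_link_intercept
  p0 <- stats::plogis(-s * m)
  p1 <- stats::plogis(s * (1 - m))
  p_star <- p0 + g_star * (p1 - p0)
  m + stats::qlogis(p_star) / s
}
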