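## Synthetic binaural BAEP cohort simulator.
##
## Every stochastic draw is made unconditionally and then scaled by its sd:
## two configurations that differ only in noise scales but share a seed
## therefore share every other draw, which makes the common-mode component
## separable by regeneration.

## Noise-free audiometry links. WRS is a logistic in latent cochlear function
## rescaled so that f = 0, 1 hit wrs_min, wrs_max exactly; PTA is affine
## decreasing in f.
wrs_clean <- function(f, cfg) {
  au <- cfg$audiometry
  s <- cfg$hp_link_slope
  m <- cfg$hp_link_intercept
  p0 <- stats::plogis(-s * m)
  p1 <- stats::plogis(s * (1 - m))
  g <- (stats::plogis(s * (f - m)) - p0) / (p1 - p0)
  au$wrs_min + (au$wrs_max - au$wrs_min) * g
}

pta_clean <- function(f, cfg) {
  au <- cfg$audiometry
  au$pta_min + (au$pta_max - au$pta_min) * (1 - f)
}

#' Simulate pre- and postoperative audiometry from latent cochlear function
#'
#' Maps a patient's latent cochlear-nerve function (a fraction in \[0, 1\],
#' 1 = intact) to pure tone average (PTA, dB) and word recognition score
#' (WRS, %) through a monotone link: WRS is a rescaled logistic increasing in
#' function, PTA is affine decreasing. Test-retest noise is added and results
#' are clamped to WRS in \[0, 100\] and PTA in \[0, 120\] dB.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param latent List with `cochlear_function_pre` and
#'   `cochlear_function_post`, both in \[0, 1\] with post <= pre.
#' @param config A [sim_config()] object.
#' @return Data frame with columns `stage` (`"pre"`, `"post"`), `pta_db`,
#'   `wrs_pct`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' set.seed(1)
#' simulate_hearing(list(cochlear_function_pre = 0.9,
#'                       cochlear_function_post = 0.4), cfg)
#' @export
simulate_hearing <- function(latent, config) {
  f <- c(latent$cochlear_function_pre, latent$cochlear_function_post)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop_config("cochlear_function values must lie in [0, 1]")
  au <- config$audiometry
  pta <- pta_clean(f, config) + stats::rnorm(2) * au$pta_noise_sd
  wrs <- wrs_clean(f, config) + stats::rnorm(2) * au$wrs_noise_sd
  data.frame(stage = c("pre", "post"),
             pta_db = pmin(pmax(pta, 0), 120),
             wrs_pct = pmin(pmax(wrs, 0), 100))
}

## Common-mode log random walk sampled on a fixed 60 s grid; total sd over the
## surgery equals `sd_total`. Returns the grid and the log-factor at the grid.
common_mode_walk <- function(duration_s, sd_total, step_s = 60) {
  grid <- seq(0, duration_s, by = step_s)
  if (grid[length(grid)] < duration_s) grid <- c(grid, duration_s)
  n <- length(grid) - 1L
  inc <- stats::rnorm(n) * sd_total * sqrt(diff(grid) / duration_s)
  list(time = grid, logf = c(0, cumsum(inc)))
}

cm_factor <- function(walk, t) {
  exp(stats::approx(walk$time, walk$logf, xout = t, rule = 2)$y)
}

## Latent cochlear function over time: pre-resection plateau, linear decline
## to the postoperative level during active resection.
function_trajectory <- function(t, f_pre, f_post, rs, re) {
  frac <- pmin(pmax((t - rs) / (re - rs), 0), 1)
  f_pre + (f_post - f_pre) * frac
}

epoch_features <- function(t, phase, f_t, cfg, lat_scale, amp_scale,
                           walk_lat, walk_amp) {
  n <- length(t)
  cmL <- cm_factor(walk_lat, t)
  cmA <- cm_factor(walk_amp, t)
  nl <- cfg$measurement_noise_sd[["latency"]]
  na <- cfg$measurement_noise_sd[["amplitude"]]
  df <- data.frame(timestamp_s = t, phase = phase)
  for (w in BAEP_WAVES) {
    base <- cfg$reference_latencies[[w]] * lat_scale * cmL
    if (w == "la_v") base <- base + cfg$injury_effect_latency * (1 - f_t)
    df[[w]] <- base + stats::rnorm(n) * nl
  }
  amp_drop <- pmax(1 - cfg$injury_effect_amplitude * (1 - f_t), 0)
  df$am_i <- pmax(cfg$reference_amplitudes[["am_i"]] * amp_scale * cmA +
                    stats::rnorm(n) * na, 0)
  df$am_v <- pmax(cfg$reference_amplitudes[["am_v"]] * amp_scale * cmA *
                    amp_drop + stats::rnorm(n) * na, 0)
  add_interpeaks(df)
}

simulate_patient <- function(id, cfg, f_star) {
  dur <- cfg$surgery_duration_min * 60
  rw <- cfg$resection_window
  jit <- min(0.1, (rw[2] - rw[1]) / 3)

  hp_pre <- stats::runif(1) < cfg$p_preop_hp
  f_pre <- if (hp_pre) stats::runif(1, f_star, 1) else stats::runif(1, 0, f_star)
  injury <- stats::runif(1, 0, cfg$injury_max)
  f_post <- max(0, f_pre - injury)
  f_healthy <- stats::runif(1, 0.9, 1)

  rs <- dur * stats::runif(1, rw[1], rw[1] + jit)
  re <- dur * stats::runif(1, rw[2] - jit, rw[2])

  age <- round(min(max(stats::rnorm(1, 48, 13), 15), 85))
  sex <- if (stats::runif(1) < 0.598) "female" else "male"
  affected_side <- if (stats::runif(1) < 0.512) "left" else "right"
  diameter <- round(min(max(stats::rnorm(1, 30.9, 9.7), 10), 80), 1)
  koos <- sample(c("II", "III", "IV"), 1, prob = c(12, 26, 89))

  walk_lat <- common_mode_walk(dur, cfg$common_mode_sd[["latency"]])
  walk_amp <- common_mode_walk(dur, cfg$common_mode_sd[["amplitude"]])

  lat_scale <- exp(stats::rnorm(1) * cfg$patient_scale_sd[["latency"]])
  amp_scale <- exp(stats::rnorm(1) * cfg$patient_scale_sd[["amplitude"]])
  asym <- exp(stats::rnorm(2) * cfg$interaural_asym_sd / sqrt(2))

  t_aff <- seq(0, dur, by = cfg$epoch_interval_s)
  t_hea <- seq(min(cfg$ear_offset_s, dur), dur, by = cfg$epoch_interval_s)
  keep_aff <- stats::runif(length(t_aff)) >= cfg$dropout_prob
  keep_hea <- stats::runif(length(t_hea)) >= cfg$dropout_prob

  phase_of <- function(t) ifelse(t < rs, "pre_resection",
                                 ifelse(t > re, "post_resection", "resection"))

  feats <- list()
  for (side in c("affected", "healthy")) {
    t <- if (side == "affected") t_aff[keep_aff] else t_hea[keep_hea]
    f_t <- if (side == "affected")
      function_trajectory(t, f_pre, f_post, rs, re) else rep(f_healthy, length(t))
    a <- amp_scale * asym[if (side == "affected") 1L else 2L]
    df <- epoch_features(t, phase_of(t), f_t, cfg, lat_scale, a,
                         walk_lat, walk_amp)
    df <- cbind(patient_id = id, side = side, df)
    feats[[side]] <- df
  }
  features <- rbind(feats$affected, feats$healthy)
  rownames(features) <- NULL

  aud_aff <- simulate_hearing(list(cochlear_function_pre = f_pre,
                                   cochlear_function_post = f_post), cfg)
  aud_hea <- simulate_hearing(list(cochlear_function_pre = f_healthy,
                                   cochlear_function_post = f_healthy), cfg)
  audiometry <- rbind(cbind(side = "affected", aud_aff),
                      cbind(side = "healthy", aud_hea))
  audiometry <- cbind(patient_id = id, audiometry)

  list(id = id, affected_side = affected_side, age = age, sex = sex,
       tumor_diameter_mm = diameter, koos_grade = koos,
       resection_start_s = rs, resection_end_s = re,
       latent = list(cochlear_function_pre = f_pre,
                     cochlear_function_post = f_post,
                     cochlear_function_healthy = f_healthy,
                     injury = injury,
                     walk_latency = walk_lat, walk_amplitude = walk_amp),
       audiometry = audiometry, features = features)
}

#' Simulate a synthetic binaural intraoperative BAEP cohort
#'
#' Generates `config$n_patients` patient records, each with: demographics and
#' tumour metadata; a latent cochlear-function trajectory (preoperative level,
#' linear decline during active resection to the postoperative level);
#' interleaved affected- and healthy-side feature streams (wave I-V latencies,
#' interpeak latencies, wave I/V amplitudes per averaged epoch) sharing a
#' common-mode multiplicative drift across both ears, with injury effects
#' (wave-V latency prolongation, amplitude reduction) on the affected side
#' only; and pre/post audiometry for both ears via [simulate_hearing()].
#'
#' @param config A [sim_config()] object.
#' @return Object of class `baep_cohort`: a list with `patients` (list of
#'   per-patient records) and `config`. Use [cohort_features()] and
#'   [cohort_hearing()] for flat tables.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 3, seed = 42))
#' head(cohort_features(coh))
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "baep_sim_config"))
    config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  f_star <- hp_function_threshold(config)
  patients <- lapply(seq_len(config$n_patients), function(i)
    simulate_patient(sprintf("P%03d", i), config, f_star))
  structure(list(patients = patients, config = config),
            class = "baep_cohort")
}

#' @export
print.baep_cohort <- function(x, ...) {
  nf <- sum(vapply(x$patients, function(p) nrow(p$features), 0L))
  cat(sprintf("BAEP cohort: %d patients, %d averaged epochs (seed %d)\n",
              length(x$patients), nf, x$config$seed))
  invisible(x)
}

#' Flat per-epoch feature table for a simulated cohort
#'
#' @param cohort A `baep_cohort`.
#' @return Data frame: `patient_id`, `side` (`affected`/`healthy`),
#'   `timestamp_s`, `phase`, and the ten indicator columns
#'   ([baep_indicators()]).
#' @export
cohort_features <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$patients, `[[`, "features"))
  rownames(out) <- NULL
  out
}

#' Flat audiometry table for a simulated cohort
#'
#' @param cohort A `baep_cohort`.
#' @return Data frame: `patient_id`, `side`, `stage` (`pre`/`post`),
#'   `pta_db`, `wrs_pct`.
#' @export
cohort_hearing <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$patients, `[[`, "audiometry"))
  rownames(out) <- NULL
  out
}

FEATURES_SCHEMA <- "# baepstd features v1"
HEARING_SCHEMA <- "# baepstd hearing v1"

write_schema_csv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(schema, con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_schema_csv <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  utils::read.csv(path, comment.char = "#")
}

#' Write a cohort to columnar text files
#'
#' Writes `features.csv` (per-epoch indicators, schema-versioned header
#' comment), `hearing.csv` (per-patient audiometry) and `manifest.json`
#' (configuration and seed) into `dir`.
#'
#' @param cohort A `baep_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "features.csv")
  hp <- file.path(dir, "hearing.csv")
  mp <- file.path(dir, "manifest.json")
  write_schema_csv(cohort_features(cohort), fp, FEATURES_SCHEMA)
  write_schema_csv(cohort_hearing(cohort), hp, HEARING_SCHEMA)
  jsonlite::write_json(list(schema_version = "1",
                            generator = "baepstd::simulate_cohort",
                            seed = cohort$config$seed,
                            config = unclass(cohort$config)),
                       mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(features = fp, hearing = hp, manifest = mp))
}

#' Read a features table written by [write_cohort()]
#' @param path Path to `features.csv`.
#' @return Data frame in the [cohort_features()] layout.
#' @export
read_features <- function(path) {
  df <- read_schema_csv(path)
  need <- c("patient_id", "side", "timestamp_s", "phase", baep_indicators())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config("features table %s lacks column(s): %s", path,
                paste(miss, collapse = ", "))
  df
}

#' Read a hearing table written by [write_cohort()]
#' @param path Path to `hearing.csv`.
#' @return Data frame in the [cohort_hearing()] layout.
#' @export
read_hearing <- function(path) {
  df <- read_schema_csv(path)
  need <- c("patient_id", "stage", "pta_db", "wrs_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config("hearing table %s lacks column(s): %s", path,
                paste(miss, collapse = ", "))
  if (is.null(df$side)) df$side <- "affected"
  df
}
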