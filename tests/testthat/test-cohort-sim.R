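test_that("cohorts are a deterministic function of config and seed", {
  cfg <- quick_config(seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(cohort_features(c1), cohort_features(c2))
  expect_identical(cohort_hearing(c1), cohort_hearing(c2))
  c3 <- simulate_cohort(quick_config(seed = 12))
  expect_false(identical(cohort_features(c1), cohort_features(c3)))
})

test_that("with all effects and noise off, affected phase means are identical pre vs post", {
  cfg <- silent_config(n_patients = 5, surgery_duration_min = 90,
                       injury_effect_latency = 0, injury_effect_amplitude = 0,
                       seed = 3)
  feats <- cohort_features(simulate_cohort(cfg))
  aff <- feats[feats$side == "affected", ]
  for (id in unique(aff$patient_id)) {
    pre <- aff[aff$patient_id == id & aff$phase == "pre_resection", ]
    post <- aff[aff$patient_id == id & aff$phase == "post_resection", ]
    expect_equal(colMeans(pre[baep_indicators()]),
                 colMeans(post[baep_indicators()]), tolerance = 1e-12)
  }
})

test_that("preoperative HP fraction matches its binomial law at n = 500", {
  cfg <- sim_config(n_patients = 500, p_preop_hp = 0.66, seed = 7,
                    surgery_duration_min = 60)
  hear <- cohort_hearing(simulate_cohort(cfg))
  pre <- hear[hear$side == "affected" & hear$stage == "pre", ]
  n_hp <- sum(classify_aao_hns(pre$pta_db, pre$wrs_pct)$hp)
  # exact binomial 99% interval around the target rate
  bounds <- qbinom(c(0.005, 0.995), 500, 0.66)
  expect_gte(n_hp, bounds[1])
  expect_lte(n_hp, bounds[2])
})

test_that("healthy-side audiometry is unaffected by surgery", {
  cfg <- silent_config(n_patients = 10, surgery_duration_min = 90, seed = 5)
  hear <- cohort_hearing(simulate_cohort(cfg))
  hea <- hear[hear$side == "healthy", ]
  pre <- hea[hea$stage == "pre", ]
  post <- hea[hea$stage == "post", ]
  ord <- order(pre$patient_id)
  expect_equal(pre$pta_db[ord], post$pta_db[order(post$patient_id)])
  expect_equal(pre$wrs_pct[ord], post$wrs_pct[order(post$patient_id)])
  # and with noise on, the mean change is null within Monte-Carlo error
  hear2 <- cohort_hearing(simulate_cohort(sim_config(
    n_patients = 200, surgery_duration_min = 60, seed = 5)))
  hea2 <- hear2[hear2$side == "healthy", ]
  d <- hea2$pta_db[hea2$stage == "post"][order(hea2$patient_id[hea2$stage == "post"])] -
    hea2$pta_db[hea2$stage == "pre"][order(hea2$patient_id[hea2$stage == "pre"])]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se + 1e-9)
})

test_that("the common-mode factor is shared by both ears and divides out", {
  base_args <- list(n_patients = 4, surgery_duration_min = 90, seed = 21,
                    measurement_noise_sd = c(latency = 0, amplitude = 0),
                    dropout_prob = 0.05)
  with_cm <- simulate_cohort(do.call(sim_config, c(base_args, list(
    common_mode_sd = c(latency = 0.05, amplitude = 0.4)))))
  no_cm <- simulate_cohort(do.call(sim_config, c(base_args, list(
    common_mode_sd = c(latency = 0, amplitude = 0)))))
  for (k in seq_along(with_cm$patients)) {
    p1 <- with_cm$patients[[k]]
    p0 <- no_cm$patients[[k]]
    expect_identical(p1$features$timestamp_s, p0$features$timestamp_s)
    ratio_lat <- p1$features[BAEP_WAVES_TEST] / p0$features[BAEP_WAVES_TEST]
    # one multiplicative factor per epoch across waves I-IV (V carries the
    # additive injury term), on both ears
    expect_equal(ratio_lat$la_ii, ratio_lat$la_i, tolerance = 1e-10)
    expect_equal(ratio_lat$la_iii, ratio_lat$la_i, tolerance = 1e-10)
    expect_equal(ratio_lat$la_iv, ratio_lat$la_i, tolerance = 1e-10)
    # the factor equals the stored latent walk for both ears
    walk <- p1$latent$walk_latency
    expected <- exp(approx(walk$time, walk$logf,
                           xout = p1$features$timestamp_s, rule = 2)$y)
    expect_equal(ratio_lat$la_i, expected, tolerance = 1e-10)
    # amplitude walk: injury acts multiplicatively, so it cancels in the ratio
    ratio_amp <- p1$features$am_v / p0$features$am_v
    walk_a <- p1$latent$walk_amplitude
    expected_a <- exp(approx(walk_a$time, walk_a$logf,
                             xout = p1$features$timestamp_s, rule = 2)$y)
    expect_equal(ratio_amp, expected_a, tolerance = 1e-10)
  }
})

test_that("audiometry link hits its configured boundaries and is monotone", {
  cfg <- silent_config(seed = 1)
  set.seed(1)
  healthy <- simulate_hearing(list(cochlear_function_pre = 1,
                                   cochlear_function_post = 1), cfg)
  expect_equal(healthy$wrs_pct, c(95, 95))
  expect_equal(healthy$pta_db, c(15, 15))
  deaf <- simulate_hearing(list(cochlear_function_pre = 0,
                                cochlear_function_post = 0), cfg)
  expect_equal(deaf$wrs_pct, c(20, 20))  # below 50: class D by construction
  expect_true(all(classify_aao_hns(deaf$pta_db, deaf$wrs_pct)$aao_class == "D"))
  # post <= pre function implies PTA(post) >= PTA(pre), WRS(post) <= WRS(pre)
  for (f in seq(0, 0.9, by = 0.3)) {
    h <- simulate_hearing(list(cochlear_function_pre = f + 0.1,
                               cochlear_function_post = f), cfg)
    expect_gte(h$pta_db[2], h$pta_db[1])
    expect_lte(h$wrs_pct[2], h$wrs_pct[1])
  }
  expect_error(simulate_hearing(list(cochlear_function_pre = 1.2,
                                     cochlear_function_post = 0.5), cfg),
               "\\[0, 1\\]")
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(epoch_interval_s = 0), "epoch_interval_s")
  expect_error(sim_config(p_preop_hp = 1.5), "p_preop_hp")
  expect_error(sim_config(measurement_noise_sd = c(latency = -1, amplitude = 0)),
               "nonnegative")
  expect_error(sim_config(reference_latencies = c(la_i = 1.7, la_ii = 2.8,
                                                  la_iii = 3.9, la_iv = 5.8,
                                                  la_v = 5.7)),
               "strictly increasing")
})

test_that("cohort files round-trip through the columnar text dialect", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(quick_config(n_patients = 3, seed = 2))
  write_cohort(coh, dir)
  feats <- read_features(file.path(dir, "features.csv"))
  hear <- read_hearing(file.path(dir, "hearing.csv"))
  expect_equal(nrow(feats), nrow(cohort_features(coh)))
  expect_equal(feats$la_v, cohort_features(coh)$la_v, tolerance = 1e-9)
  expect_equal(hear$pta_db, cohort_hearing(coh)$pta_db, tolerance = 1e-9)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 2)
})
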