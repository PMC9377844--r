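test_that("generate_beat renders Gaussian bumps at the stated amplitudes", {
  # all-zero amplitudes give a flat trace
  wp0 <- wave_params(amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_equal(generate_beat(wp0, 100), rep(0, 100))

  # a lone R bump peaks at exactly its amplitude at the R center sample
  wp_r <- wave_params(amplitudes = c(P = 0, Q = 0, R = 1, S = 0, T = 0))
  beat <- generate_beat(wp_r, 1000)
  expect_equal(max(beat), 1.0, tolerance = 1e-9)
  expect_equal(which.max(beat), round(0.35 * 1000) + 1)

  # beat length follows the heart rate
  expect_length(generate_beat(wave_params(heart_rate = 75), 100), 80)
})

test_that("default QRS duration at 5% of R amplitude lies in 0.05-0.10 s", {
  rate <- 2000 # fine grid so the measured width is not quantization-limited
  beat <- generate_beat(wave_params(), rate)
  w <- wave_params()$waves
  thresh <- 0.05 * w["R", "amplitude"]
  # restrict to the QRS neighbourhood, away from P and T
  win <- which((seq_along(beat) - 1) / rate >= w["Q", "center"] - 0.05 &
                 (seq_along(beat) - 1) / rate <= w["S", "center"] + 0.05)
  above <- win[abs(beat[win]) >= thresh]
  qrs_s <- (max(above) - min(above)) / rate
  expect_gte(qrs_s, 0.05)
  expect_lte(qrs_s, 0.10)
})

test_that("invalid wave parameters and rates are rejected", {
  expect_error(wave_params(durations = c(R = 0)), class = "mrfecg_invalid_parameter")
  expect_error(wave_params(heart_rate = -10))
  expect_error(wave_params(centers = c(P = 0.5, Q = 0.4)),
               class = "mrfecg_invalid_parameter")
  expect_error(generate_beat(wave_params(), rate = -100))
})

test_that("amplitude parameters act monotonically on the noise-free peak", {
  peaks <- vapply(c(0.5, 1.0, 1.5), function(a) {
    max(generate_beat(wave_params(amplitudes = c(R = a)), 500))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("class effects compose onto the record as specified", {
  base_cfg <- synth_config(1, noise_sd = 0, wander_amplitude = 0, seed = 3)

  # no labels: every lead is a scaled copy of the default beat train
  rec <- generate_record(base_cfg, character(), seed = 5)
  beat <- generate_beat(base_cfg$base_params, base_cfg$rate)
  train <- rep_len(beat, 1000)
  coefs <- rec$signal[, 36] / train[36] # sample 36 sits at the R peak
  for (l in c(1, 6, 12)) {
    expect_equal(rec$signal[l, ], coefs[l] * train, tolerance = 1e-9)
  }

  # heart-rate multiplier 2 doubles the count of detected R peaks
  cfg2 <- synth_config(1, classes = list(class_effect("fast", heart_rate = 2)),
                       prevalence = 1, noise_sd = 0, wander_amplitude = 0,
                       seed = 3)
  count_peaks <- function(x) {
    x <- x / max(x)
    sum(x[2:999] > 0.5 & x[2:999] > x[1:998] & x[2:999] >= x[3:1000])
  }
  lead_of <- function(r) r$signal[which.max(abs(lead_projection(base_cfg))), ] *
    sign(lead_projection(base_cfg)[which.max(abs(lead_projection(base_cfg)))])
  slow <- generate_record(cfg2, character(), seed = 5)
  fast <- generate_record(cfg2, "fast", seed = 5)
  expect_equal(count_peaks(lead_of(fast)), 2 * count_peaks(lead_of(slow)))

  # unknown label errors
  expect_error(generate_record(base_cfg, "no-such-class"), "Unknown label")
})

test_that("identical seeds give bit-identical records and datasets", {
  cfg <- synth_config(5, seed = 9)
  expect_identical(generate_record(cfg, "wide_qrs", seed = 4),
                   generate_record(cfg, "wide_qrs", seed = 4))
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("zeroing P amplitude suppresses the pre-QRS segment", {
  cfg <- synth_config(1, classes = list(class_effect("no_p", p_amp = 0)),
                      prevalence = 1, noise_sd = 0, wander_amplitude = 0,
                      seed = 6)
  params <- apply_effects(cfg$base_params, cfg$classes["no_p"])
  beat <- generate_beat(params, 1000)
  w <- cfg$base_params$waves
  pre_qrs <- beat[seq_len(round((w["Q", "center"] - 0.05) * 1000))]
  expect_lt(max(abs(pre_qrs)), 0.10 * w["R", "amplitude"])
})

test_that("effect strength scales deviations from identity monotonically", {
  ef <- class_effect("x", r_amp = 2, st_offset = -0.3)
  devs <- vapply(c(0.25, 0.5, 1), function(s) {
    p <- apply_effects(wave_params(), list(ef), strength = s)
    abs(p$waves["R", "amplitude"] - 1) + abs(p$st_offset)
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
  # identity effect leaves parameters untouched
  id <- apply_effects(wave_params(), list(class_effect("id")))
  expect_equal(id$waves, wave_params()$waves)
  expect_equal(id$heart_rate, 60)
})

test_that("generate_dataset honours prevalences, shapes and degenerate cases", {
  # degenerate prevalence 1 labels every record
  cfg1 <- synth_config(50, classes = list(class_effect("always")),
                       prevalence = 1, seed = 2)
  ds1 <- generate_dataset(cfg1)
  expect_equal(sum(ds1$labels), 50)

  # empirical prevalence within the 99% binomial interval of the target
  cfg <- synth_config(1000, classes = list(class_effect("a", r_amp = 1.5)),
                      prevalence = 0.2, seed = 8)
  k <- sum(generate_dataset(cfg)$labels)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])

  # multihot shape and domain
  ds <- generate_dataset(synth_config(40, seed = 3))
  expect_identical(dim(ds$labels), c(40L, 5L))
  expect_true(all(ds$labels %in% c(0, 1)))
  expect_identical(ds$classes, names(synth_class_effects()))
  expect_identical(dim(ds$records[[1]]$signal), c(12L, 1000L))

  expect_error(generate_dataset(synth_config(0)), "n_records")

  # manifest and record plotting surfaces
  man <- dataset_manifest(ds)
  expect_equal(nrow(man), 40)
  expect_true(all(man$n_samples == 1000))
  expect_s3_class(autoplot(ds$records[[1]]), "ggplot")
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(10, prevalence = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(10, classes = list()), "At least one class")
  expect_error(synth_config(10, rate = 100, duration = 10.005), "integer sample count")
})
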