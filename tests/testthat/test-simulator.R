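test_that("profiles are deterministic and phenotypes carry their tremor signatures", {
  a <- make_profile("experimental", "E", seed = 7)
  b <- make_profile("experimental", "E", seed = 7)
  expect_identical(a, b)
  # symmetric wrist + lower-limb shaking on both sides
  expect_length(a$tremors, 1)
  expect_setequal(a$tremors[[1]]$joints,
                  c("l_hand", "r_hand", "l_knee", "r_knee", "l_foot",
                    "r_foot"))
  expect_equal(a$tremors[[1]]$phase_mode, "symmetric")
  # controls have no tremor at all
  young <- make_profile("control", "stable_young", seed = 3)
  expect_length(young$tremors, 0)
  # group/phenotype consistency is enforced
  expect_error(make_profile("control", "E", seed = 1), "experimental")
  expect_error(make_profile("experimental", "stable_young", seed = 1),
               "control")
  expect_error(make_profile("experimental", "Z", seed = 1), "unknown")
})

test_that("tremor components enforce the Nyquist and amplitude bounds", {
  expect_error(tremor_component("l_hand", 15, 0.001), "Nyquist|\\(0, 15\\)")
  expect_error(tremor_component("l_hand", 0, 0.001), "Nyquist|\\(0, 15\\)")
  expect_error(tremor_component("l_hand", 5, -1), ">= 0")
  expect_error(tremor_component("wrist", 5, 0.001), "unknown joint")
})

test_that("zero-dynamics profile reproduces the static pose exactly", {
  rec <- simulate_recording(silent_profile(), session = 1, seed = 5)
  pose <- default_pose()
  for (t in c(1, 600, 1200))
    expect_equal(unname(rec$samples[t, , ]), unname(pose), tolerance = 0)
})

test_that("a configured tremor dominates the periodogram of its joint", {
  prof <- silent_profile()
  prof$tremors <- list(tremor_component("l_hand", 5, 0.005, axis = "x"))
  rec <- simulate_recording(prof, session = 1, seed = 2)
  pg <- periodogram(rec$samples[, "l_hand", "x"], rec$sample_rate)
  expect_equal(pg$freq[which.max(pg$power)], 5, tolerance = 0.026)
  # the y axis of the same joint stays silent
  expect_lt(max(abs(rec$samples[, "l_hand", "y"] - default_pose()["l_hand", "y"])),
            1e-12)
})

test_that("preset tremor frequencies are local periodogram maxima on target joints only", {
  for (ph in c("B", "E")) {
    prof <- make_profile("experimental", ph, seed = 21)
    rec <- simulate_recording(prof, session = 1, seed = 3)
    tc <- prof$tremors[[1]]
    amp_ok <- tc$amplitude >= 3 * prof$sensor_noise_sd
    for (j in tc$joints) {
      pg <- periodogram(rec$samples[, j, "x"], rec$sample_rate)
      bin <- which.min(abs(pg$freq - tc$frequency))
      window <- pg$power[max(1, bin - 1):min(length(pg$power), bin + 1)]
      # local maximum within +/- 1 bin of the configured frequency
      local <- pg$power[max(1, bin - 8):min(length(pg$power), bin + 8)]
      expect_equal(max(local), max(window), tolerance = 1e-9)
    }
    if (amp_ok) {
      # non-target joints show no concentrated power at the tremor bin
      off <- setdiff(jnp_joints(), tc$joints)[1:4]
      for (j in off) {
        pg <- periodogram(rec$samples[, j, "x"], rec$sample_rate)
        bin <- which.min(abs(pg$freq - tc$frequency))
        expect_lt(pg$power[bin], 10 * stats::median(pg$power))
      }
    }
  }
})

test_that("pelvis sway magnitude matches the profile RMS over replicate sessions", {
  prof <- make_profile("experimental", "generic_elderly", seed = 15,
                       jitter = FALSE)
  expect_equal(prof$sway_rms, 0.008)
  sq <- c()
  for (rep_i in 1:10) {
    rec <- simulate_recording(prof, session = ((rep_i - 1) %% 6) + 1,
                              seed = 100 + rep_i)
    pelvis <- rowMeans(rec$samples[, c("l_hip", "r_hip"), "x"])
    sq <- c(sq, (pelvis - mean(pelvis))^2)
  }
  pooled_rms <- sqrt(mean(sq))
  expect_lt(abs(pooled_rms - 0.008) / 0.008, 0.15)
})

test_that("pelvis sway power is concentrated in the configured band", {
  prof <- make_profile("experimental", "generic_elderly", seed = 33,
                       jitter = FALSE)
  prof$sensor_noise_sd <- 0
  prof$tremors <- list()
  rec <- simulate_recording(prof, session = 1, seed = 8)
  pelvis <- rowMeans(rec$samples[, c("l_hip", "r_hip"), "x"])
  pg <- periodogram(pelvis, rec$sample_rate)
  in_band <- pg$freq >= prof$sway_band[1] & pg$freq <= prof$sway_band[2]
  expect_gt(sum(pg$power[in_band]) / sum(pg$power), 0.90)
})

test_that("simulate_dataset reproduces the study bookkeeping and is deterministic", {
  ds <- simulate_dataset(20, 25, 6, seed = 1)
  expect_equal(nrow(ds$manifest), 270)
  expect_equal(sum(ds$manifest$group == "control"), 120)
  expect_equal(sum(ds$manifest$group == "experimental"), 150)
  expect_length(validate_manifest(ds$manifest), 0)
  tiny <- simulate_dataset(1, 1, 1, seed = 2)
  expect_equal(length(tiny$recordings), 2)
  a <- simulate_dataset(2, 2, 2, seed = 9)
  b <- simulate_dataset(2, 2, 2, seed = 9)
  expect_identical(a$recordings, b$recordings)
  expect_error(simulate_dataset(0, 5, 6, seed = 1), ">= 1")
  expect_error(
    simulate_dataset(2, 2, 2, seed = 1,
                     phenotype_mix = list(control = c(stable_young = 0.5),
                                          experimental = c(A = 1))),
    "sum to 1")
})

test_that("null cohort subjects share one identical profile", {
  ds <- simulate_null_dataset(3, 3, 2, seed = 5)
  expect_equal(nrow(ds$manifest), 12)
  pars <- lapply(ds$profiles, function(p)
    list(p$sway_rms, p$sensor_noise_sd, p$tremors))
  for (i in 2:length(pars)) expect_identical(pars[[i]], pars[[1]])
  expect_setequal(unique(ds$manifest$group), c("control", "experimental"))
})

test_that("seed derivation is stable, in range, and index sensitive", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
  expect_false(derive_seed(1, 2) == derive_seed(2, 2))
  s <- vapply(1:500, function(i) derive_seed(42, i), 1L)
  expect_true(all(s >= 1 & s <= 2^31 - 2))
  expect_gt(length(unique(s)), 495)
})
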