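# synthetic_knee: atlas, truth fields, echo simulation.

test_that("generate_atlas produces exactly the 6 labels, deterministically", {
  spec <- phantom_spec()
  a1 <- generate_atlas(spec)
  a2 <- generate_atlas(spec)
  expect_identical(sort(unique(as.vector(a1$labels))), 0:6)
  expect_identical(a1$labels, a2$labels)
  # all compartments nonempty and mutually exclusive by construction
  counts <- table(a1$labels)
  expect_true(all(counts[-1] > 0))
})

test_that("overlapping shells raise an error naming the pair", {
  geom <- default_knee_geometry(c(32L, 32L, 32L), c(1, 1, 1))
  geom$LT <- geom$LFC  # duplicate geometry: guaranteed overlap
  expect_error(generate_atlas(phantom_spec(compartment_geometry = geom)),
               "overlap.*LFC.*LT|overlap.*LT.*LFC")
})

test_that("truth fields honor the zero-variance case and the APD sign convention", {
  atlas <- tiny_atlas()
  cm <- default_compartment_means()
  cm$t1rho_ms[cm$compartment == "MT"] <- 40
  # reference subject (grade 0), zero SD: every MT voxel at the mean
  ef <- effect_spec(target_compartments = "MT", affected_fraction = 0.5,
                    true_percentage_difference = -10, between_subject_sd_pct = 0)
  subj_ref <- list(grade_patellar_tendinosis = 0L)
  tr <- generate_truth(atlas, cm, effect = ef, subject = subj_ref, seed = 1)
  mt <- atlas$labels == 4L
  expect_equal(unique(tr$t1rho_ms[mt]), 40)
  expect_true(all(tr$t1rho_ms[atlas$labels > 0] > 0))
  expect_true(all(tr$t1rho_ms[atlas$labels == 0] == 0))
  # affected subject, -10% difference (abnormal higher): region mean 44 ms
  subj_aff <- list(grade_patellar_tendinosis = 2L)
  ta <- generate_truth(atlas, cm, effect = ef, subject = subj_aff, seed = 1)
  aff_vals <- ta$t1rho_ms[mt]
  expect_equal(sort(unique(aff_vals)), c(40, 44))
  expect_equal(mean(aff_vals == 44), 0.5, tolerance = 0.01)
})

test_that("injected group difference is recovered by Monte-Carlo group means", {
  atlas <- tiny_atlas()
  ef <- effect_spec(target_compartments = "MT", affected_fraction = 1,
                    true_percentage_difference = -10, between_subject_sd_pct = 2)
  mt <- atlas$labels == 4L
  n <- 20
  ref_means <- aff_means <- numeric(n)
  for (i in seq_len(n)) {
    ref_means[i] <- mean(generate_truth(atlas, effect = ef,
                                        subject = list(grade_patellar_tendinosis = 0L),
                                        seed = i)$t1rho_ms[mt])
    aff_means[i] <- mean(generate_truth(atlas, effect = ef,
                                        subject = list(grade_patellar_tendinosis = 1L),
                                        seed = 1000 + i)$t1rho_ms[mt])
  }
  ref_mu <- default_compartment_means()$t1rho_ms[4]
  pct_diff <- 100 * (mean(ref_means) - mean(aff_means)) / mean(ref_means)
  se <- 100 * sqrt(var(ref_means) / n + var(aff_means) / n) / ref_mu
  expect_lt(abs(pct_diff - (-10)), 3 * se + 1e-9)
})

test_that("unknown compartment label in an effect errors", {
  expect_error(effect_spec(target_compartments = "XYZ"), "unknown compartment")
})

test_that("noiseless signals match the closed-form exponential", {
  atlas <- tiny_atlas()
  cm <- default_compartment_means()
  cm$t1rho_ms[] <- 40
  tr <- generate_truth(atlas, cm, seed = 1)
  es <- simulate_echo_series(tr, "T1rho", noise_sd = 0)
  vox <- which(atlas$labels > 0)[1]
  got <- sapply(1:4, function(e) es$data[, , , e][vox])
  expect_equal(got, c(100, 77.880, 36.788, 13.534), tolerance = 1e-3 / 13)
  # positivity + monotone non-increasing decay inside cartilage
  inside <- atlas$labels > 0
  prev <- es$data[, , , 1]
  for (e in 2:4) {
    cur <- es$data[, , , e]
    expect_true(all(cur[inside] > 0))
    expect_true(all(cur[inside] <= prev[inside] + 1e-12))
    prev <- cur
  }
})

test_that("default echo schedules match the acquisition protocol", {
  expect_equal(default_echo_times("T1rho"), c(0, 10, 40, 80))
  expect_equal(default_echo_times("T2"), c(0, 12.87, 25.69, 51.39))
})

test_that("rician background mean follows the Rayleigh law", {
  atlas <- tiny_atlas(24L)
  cm <- default_compartment_means()
  tr <- generate_truth(atlas, cm, seed = 1)
  es <- simulate_echo_series(tr, "T1rho", noise_model = "rician",
                             noise_sd = 1, seed = 99)
  bg <- atlas$labels == 0
  bg_vals <- es$data[, , , 1][bg]
  expect_gt(length(bg_vals), 5000)
  expect_equal(mean(bg_vals), sqrt(pi / 2), tolerance = 0.02)
})

test_that("fewer than 3 echoes is rejected", {
  atlas <- tiny_atlas()
  tr <- generate_truth(atlas, seed = 1)
  expect_error(simulate_echo_series(tr, "T1rho", echo_times_ms = c(0, 10)),
               ">= 3 echoes")
  expect_error(echo_series(array(1, c(2, 2, 2, 2)), c(0, 10)), ">= 3 echoes")
})

test_that("echo simulation is deterministic under the seed", {
  atlas <- tiny_atlas()
  tr <- generate_truth(atlas, seed = 5)
  e1 <- simulate_echo_series(tr, "T1rho", seed = 7)
  e2 <- simulate_echo_series(tr, "T1rho", seed = 7)
  expect_identical(e1$data, e2$data)
})
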