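test_that("Poisson spike simulation has the stated moments", {
  cfg <- barcode_config(k_spike = 0.2, K_offset = 0.2)
  expect_error(simulate_spikes(c(-1, 2), cfg), "nonnegative")
  set.seed(1)
  # rate 0 under the scaled parameterization: always zero
  expect_true(all(simulate_spikes(rep(0, 1000), cfg) == 0))
  # k = 0.2, rate 5: mean 1.0 within 3 standard errors over 1e5 draws
  s <- simulate_spikes(rep(5, 1e5), cfg)
  expect_lt(abs(mean(s) - 1), 3 * sqrt(1 / 1e5))
  # visualization variant: zero-rate unit has mean K = 0.2
  s2 <- simulate_spikes(rep(0, 1e5), cfg, parameterization = "offset")
  expect_lt(abs(mean(s2) - 0.2), 3 * sqrt(0.2 / 1e5))
})

test_that("site-distance calibration matches a brute-force scan", {
  # synthetic profile: correlation exp(-d/nu') over separations 0..50
  for (nu_p in c(0.08, 0.15, 0.3)) {
    prof <- data.frame(separation = 0:50,
                       value = exp(-(0:50) / 100 / nu_p))
    got <- calibrate_site_distance(prof, target = 0.75)
    brute <- prof$separation[which.min(abs(prof$value - 0.75))]
    expect_lte(abs(got - brute), 1)
  }
  # a constant profile never crosses the target
  flat <- data.frame(separation = 0:50, value = rep(1, 51))
  expect_error(calibrate_site_distance(flat, 0.75), "calibration failure")
})

test_that("rate-based visit profile is self-normalized and decays", {
  model <- build_model(small_config(), seed = 2)
  prof <- visit_correlation_profile(model)
  expect_identical(prof$value[prof$separation == 0], 1)
  expect_true(all(diff(prof$value[1:10]) < 0))
  mm <- visit_correlation_profile(model, normalization = "minmax")
  expect_equal(range(mm$value), c(0, 1))
})

test_that("projection references are orthogonalized exactly", {
  cfg <- tiny_config()
  model <- build_model(cfg, seed = 3, variant = "hybrid")
  dec <- code_projection(model, r_values = c(0, 0.5, 1))
  expect_s3_class(dec, "projection_decomposition")
  # each max-normalized curve peaks at exactly 1
  for (cd in unique(dec$code))
    expect_equal(max(dec$projection[dec$code == cd]), 1)
  expect_error(code_projection(model, r_values = c(0, 1.5)), "\\[0, 1\\]")
})

test_that("place projection is maximal at r = 0 by construction", {
  cfg <- small_config()
  model <- build_model(cfg, seed = 4, variant = "hybrid")
  dec <- code_projection(model, r_values = c(0, 0.5, 1))
  pl <- dec[dec$code == "place", ]
  expect_identical(pl$r[which.max(pl$projection)], 0)
  bc <- dec[dec$code == "barcode", ]
  expect_identical(bc$r[which.max(bc$projection)], 1)
})

test_that("rate-based correlation profile matches the closed-form input profile", {
  # without spikes, visit-visit correlations are exactly the Pearson
  # correlations of the exponential input bumps
  cfg <- scale_config(barcode_config(T_dyn = 20), 500)
  pr <- correlation_profile(cfg, n_experiments = 3, n_sites = 4,
                            seed = 5, use_spikes = FALSE)
  bank <- place_inputs(cfg)
  cin <- cor(t(bank$vectors))
  vv <- pr[pr$condition == "visit_visit", ]
  for (d in vv$distance) {
    sep <- as.integer(d * 8)
    idx <- cbind(seq_len(cfg$N_s), ((seq_len(cfg$N_s) - 1 + sep) %% cfg$N_s) + 1)
    expect_lt(abs(vv$value[vv$distance == d] - mean(cin[idx])), 1e-6)
  }
})
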