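test_that("predictive matrix entries follow the truncated discounted series", {
  cfg <- barcode_config(N_p = 500, N_x = 500, D = 300,
                        gamma = 0.99, rho = 0.075, delta_off = -0.015)
  M <- predictive_matrix(cfg)
  expect_equal(M[1, 1], 0.075 - 0.015)                    # 0.060
  expect_equal(M[1, 2], 0.075 * 0.99 - 0.015)             # 0.05925
  expect_equal(M[1, 303], -0.015)                         # beyond D
  expect_equal(M[5, 5 + 10], 0.075 * 0.99^10 - 0.015)
})

test_that("the predictive matrix is exactly circulant", {
  cfg <- barcode_config(N_p = 120, N_x = 120, D = 30)
  M <- predictive_matrix(cfg)
  for (i in 2:5) {
    shifted <- c(M[i, i:120], M[i, seq_len(i - 1)])
    expect_identical(shifted, M[1, ])
  }
})

test_that("hybrid weights reduce to the default model when rho = delta = 0", {
  cfg <- tiny_config(rho = 0, delta_off = 0)
  w <- hybrid_weights(cfg, seed = 3)
  expect_true(all(w$M == 0))
  expect_identical(effective_weights(w), w$B)
})

test_that("hybrid activity at intermediate gain shifts clockwise", {
  cfg <- accept_config(800)
  model <- build_model(cfg, seed = 5, variant = "hybrid")
  sched <- rep(0, n_steps(cfg))
  X0 <- run_mode(model, seq_len(cfg$N_s), "place")
  J <- effective_weights(model$weights)
  X3 <- barcodeRNN:::integrate_dynamics(t(model$bank$vectors), 0.3, sched,
                                        J, model$j_in, cfg)$x
  # circular cross-correlation between the r=0.3 activity map and the r=0
  # map peaks at a strictly positive (clockwise) state lag
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    sh <- ((seq_len(cfg$N_s) - 1 + l) %% cfg$N_s) + 1
    mean(diag(cor(X3[, sh], X0)))
  }, numeric(1))
  expect_gt(lags[which.max(cc)], 0)
})

test_that("feedforward hidden sparsity matches theta per pattern", {
  cfg <- tiny_config(theta = 0.1)
  bank <- place_inputs(cfg)
  ff <- feedforward_model(cfg, seed = 2)
  expect_identical(dim(ff$W_h), c(600L, 200L))
  bc <- feedforward_barcode(bank, ff, cfg, target_sparsity = 0.1)
  frac <- rowMeans(bc > 0)
  expect_true(all(abs(frac - 0.1) <= 1 / 200 + 1e-9))
  expect_error(feedforward_barcode(bank, ff, cfg, target_sparsity = 0),
               "sparsity")
})

test_that("feedforward decorrelation strengthens with hidden sparsity", {
  cfg <- barcode_config(N_p = 300, N_x = 300, N_s = 30, M_hidden = 3000)
  bank <- place_inputs(cfg)
  ff <- feedforward_model(cfg, seed = 7)
  adj_corr <- function(th) {
    cfg2 <- cfg; cfg2$theta <- th
    bc <- feedforward_barcode(bank, ff, cfg2, target_sparsity = 0.15)
    cc <- cor(t(bc))
    mean(cc[cbind(1:30, (1:30 %% 30) + 1)])
  }
  dense <- adj_corr(1)
  mid <- adj_corr(0.2)
  sparse <- adj_corr(0.02)
  # dense random projection roughly preserves the input correlation
  cin <- cor(t(bank$vectors))
  adj_in <- mean(cin[cbind(1:30, (1:30 %% 30) + 1)])
  expect_lt(abs(dense - adj_in), 0.25)
  expect_lt(mid, dense)
  expect_lt(sparse, mid)
})

test_that("gp-input model supports the full cache/recall loop", {
  cfg <- accept_config(600)
  model <- build_model(cfg, seed = 11, variant = "gp_inputs")
  model <- store_cache(model, 30)
  out <- recall_event(model, 30, s_strength = 0)
  xs <- model$traces[[1]]$x_stored
  cosine <- sum(out$x * xs) / sqrt(sum(out$x^2) * sum(xs^2))
  expect_gt(cosine, 0.7)
  far <- recall_event(model, 80, s_strength = 0)
  expect_lt(far$y_seed, out$y_seed)
})
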