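test_that("cache presence uses a strict threshold at kappa", {
  cfg <- tiny_config()
  expect_false(cache_presence_decision(0, cfg))
  expect_false(cache_presence_decision(0.5, cfg))   # exactly kappa: absent
  expect_true(cache_presence_decision(0.51, cfg))
})

test_that("cache location success is conjunctive and windowed", {
  cfg <- tiny_config()
  model <- build_model(cfg, seed = 1)
  yp <- numeric(cfg$N_p)
  # peak at the neuron preferring state 5's position
  yp[which.min(abs(model$bank$preferred_locations - 4 / cfg$N_s))] <- 1
  expect_error(cache_location_success(1, yp, 5, integer(0), model),
               "nonempty")
  # seed output below kappa fails regardless of the place output
  expect_false(cache_location_success(0.2, yp, 5, c(5L), model))
  # peak at the nearest cache succeeds
  expect_true(cache_location_success(1, yp, 5, c(5L, 15L), model))
  # peak far from the nearest cache fails
  expect_false(cache_location_success(1, yp, 15, c(5L, 15L), model,
                                      window = 2L))
  # nearest-cache ties accept either flanking cache
  expect_true(cache_location_success(1, yp, 10, c(5L, 15L), model))
})

test_that("ablation factories implement the stated modifications", {
  cfg <- tiny_config()
  expect_error(make_ablation("nonsense", cfg))
  m_po <- make_ablation("place_only", cfg)(1)
  expect_true(all(m_po$weights$B == 0))
  m_bo <- make_ablation("barcode_only", cfg)(1)
  expect_equal(m_bo$config$nu, 1e-3)
  # barcode-only inputs are uncorrelated across neighbouring states
  cc <- cor(t(m_bo$bank$vectors))
  expect_lt(mean(cc[cbind(1:20, (1:20 %% 20) + 1)]), 0.1)
  m_h <- make_ablation("hybrid", cfg)(1)
  expect_false(is.null(m_h$weights$M))
})

test_that("with zero caches every query is a correct reject", {
  cfg <- tiny_config()
  model <- build_model(cfg, seed = 4)
  y <- recall_curve(model, seq_len(cfg$N_s), s_strength = 0)$y_seed
  expect_identical(y, rep(0, cfg$N_s))
  expect_true(all(!cache_presence_decision(y, cfg)))
})

test_that("the task engine produces a complete tidy result", {
  cfg <- tiny_config()
  spec <- task_spec(cache_locations = c(3L, 9L, 15L), s_values = c(0, 1),
                    n_seeds = 2L, query_states = c(3L, 6L, 15L),
                    after_each_cache = TRUE)
  res <- run_three_cache_task(spec, cfg, seed = 1)
  d <- res$data
  expect_identical(nrow(d), 2L * 3L * 2L * 3L)  # seeds x caches x s x query
  expect_true(all(d$y_seed >= 0 | d$y_seed < 0))  # numeric, no NA
  expect_false(anyNA(d$present))
  expect_true(all(d$dist_nearest[d$state == 3 & d$n_caches >= 1] == 0))
  # deterministic: same spec and seed give identical tables
  res2 <- run_three_cache_task(spec, cfg, seed = 1)
  expect_identical(res$data, res2$data)
})

test_that("task spec validation rejects duplicate or out-of-range caches", {
  cfg <- tiny_config()
  expect_error(run_three_cache_task(
    task_spec(cache_locations = c(3L, 3L), n_seeds = 1L), cfg), "distinct")
  expect_error(run_three_cache_task(
    task_spec(cache_locations = c(3L, 99L), n_seeds = 1L), cfg), "N_s")
})

test_that("task metrics are robust to the order in which caches are made", {
  cfg <- accept_config(600)
  caches <- default_cache_locations(cfg)
  y_at_caches <- function(order) {
    spec <- task_spec(cache_locations = order, s_values = 0, n_seeds = 3L,
                      query_states = caches)
    d <- run_three_cache_task(spec, cfg, seed = 31)$data
    mean(d$y_seed[d$n_caches == 3])
  }
  a <- y_at_caches(caches)
  b <- y_at_caches(caches[c(3, 1, 2)])
  expect_gt(a, 0)
  expect_lt(abs(a - b), 0.35)
})

test_that("binomial confidence intervals behave at the boundaries", {
  ci <- binomial_ci(35, 35, 0.99)
  expect_identical(unname(ci["p"]), 1)
  expect_identical(unname(ci["hi"]), 1)
  ci2 <- binomial_ci(18, 35, 0.99)
  expect_lt(ci2["lo"], ci2["p"])
  expect_gt(ci2["hi"], ci2["p"])
})
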