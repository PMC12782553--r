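# Small configurations and lazily cached heavy computations shared across
# test files. Everything is generated in code; no fixture files.

tiny_config <- function(...) {
  barcode_config(N_p = 200, N_x = 200, N_y = 200, N_s = 20,
                 T_dyn = 15, D = 12, M_hidden = 600, ...)
}

small_config <- function(...) {
  barcode_config(N_p = 400, N_x = 400, N_y = 400, N_s = 50,
                 T_dyn = 30, D = 24, M_hidden = 1200, ...)
}

# Acceptance-scale configurations: reduced network sizes with the
# successor-representation parameters rescaled per size.
accept_config <- function(n = 1200, ...) {
  scale_config(barcode_config(...), n)
}

# Cache of expensive shared results (computed at most once per test run).
.accept_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .accept_cache)) {
    assign(key, force(expr), envir = .accept_cache)
  }
  get(key, envir = .accept_cache)
}

# Full-model three-cache task at acceptance scale, shared by the task and
# ablation criteria. Queries: the three caches, the two inter-cache
# midpoints, and a remote state two site distances from the nearest cache.
accept_task_queries <- function(cfg) {
  caches <- default_cache_locations(cfg)           # 21, 36, 71
  mids <- c(caches[1] + (caches[2] - caches[1]) %/% 2,
            caches[2] + (caches[3] - caches[2]) %/% 2)
  remote <- ((caches[3] - 1 + 16) %% cfg$N_s) + 1
  list(caches = caches, mids = mids, remote = remote,
       states = c(caches, mids, remote))
}

accept_full_task <- function() {
  cached("full_task", {
    cfg <- accept_config(1000)
    q <- accept_task_queries(cfg)
    spec <- task_spec(cache_locations = q$caches,
                      s_values = c(0, 0.4, 1.5), n_seeds = 35L,
                      query_states = q$states)
    run_three_cache_task(spec, cfg, seed = 100L)
  })
}
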