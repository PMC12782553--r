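#' Specification of a caching-task simulation
#'
#' The default protocol stores three caches at 20%, 35% and 70% of the
#' track, then probes recall at query states for each search strength,
#' across independent model replicates.
#'
#' @param cache_locations 1-based state indices of the caches, in storage
#'   order.
#' @param s_values Search strengths probed at recall.
#' @param n_seeds Number of model replicates.
#' @param query_states States probed at recall (default: all states).
#' @param window Half-width, in states, of the acceptance window around the
#'   nearest cache for the Cache Location task.
#' @param ci_level Confidence level for binomial intervals.
#' @param after_each_cache If TRUE, queries are run after every cache;
#'   otherwise only after the final cache.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(cache_locations = NULL,
                      s_values = c(0, 0.4, 1.5),
                      n_seeds = 35L,
                      query_states = NULL,
                      window = 4L,
                      ci_level = 0.99,
                      after_each_cache = FALSE) {
  spec <- list(cache_locations = cache_locations, s_values = s_values,
               n_seeds = as.integer(n_seeds), query_states = query_states,
               window = as.integer(window), ci_level = ci_level,
               after_each_cache = after_each_cache)
  class(spec) <- "task_spec"
  spec
}

#' Default cache locations of the three-cache protocol
#'
#' Caches at 20%, `m` (default 35%), and 70% of the track.
#'
#' @param cfg A [barcode_config()].
#' @param m Fractional position of the middle (sweepable) cache; must lie
#'   strictly between 0.2 and 0.7.
#' @return Integer vector of three 1-based state indices.
#' @export
default_cache_locations <- function(cfg, m = 0.35) {
  if (m <= 0.2 || m >= 0.7)
    stop("the middle cache must lie strictly between the outer caches")
  as.integer(round(cfg$N_s * c(0.2, m, 0.7))) + 1L
}

resolve_task_spec <- function(spec, cfg) {
  if (is.null(spec$cache_locations))
    spec$cache_locations <- default_cache_locations(cfg)
  if (is.null(spec$query_states))
    spec$query_states <- seq_len(cfg$N_s)
  cl <- spec$cache_locations
  if (anyDuplicated(cl)) stop("cache locations must be distinct")
  if (any(cl < 1L | cl > cfg$N_s)) stop("cache locations outside [1, N_s]")
  spec
}

#' Cache Presence decision
#'
#' A seed is reported present iff the seed output strictly exceeds the
#' threshold `kappa`.
#'
#' @param y_seed Scalar (or vector of) seed output.
#' @param cfg A [barcode_config()].
#' @return Logical.
#' @export
cache_presence_decision <- function(y_seed, cfg) {
  y_seed > cfg$kappa
}

#' Cache Location success
#'
#' A recall is successful iff the seed output exceeds `kappa` AND the peak
#' of the place output maps to a state within `window` states (circular
#' distance) of the cache nearest to the probed position (ties between
#' equally near caches accept either).
#'
#' @param y_seed Scalar seed output.
#' @param y_place Place output vector.
#' @param position Probed state (1-based).
#' @param caches Vector of cached states (must be nonempty).
#' @param model The `barcode_model` (for the preferred-location map).
#' @param window Acceptance half-width in states.
#' @return Logical.
#' @export
cache_location_success <- function(y_seed, y_place, position, caches,
                                   model, window = 4L) {
  if (!length(caches)) stop("cache list must be nonempty")
  if (!cache_presence_decision(y_seed, model$config)) return(FALSE)
  cfg <- model$config
  peak <- place_output_peak(y_place, model$bank, cfg$N_s)
  dists <- state_distance(position, caches, cfg$N_s)
  nearest <- caches[dists == min(dists)]
  any(state_distance(peak, nearest, cfg$N_s) <= window)
}

#' Model factory for the full model and its ablations
#'
#' `full` is the default model. `place_only` removes barcode generation by
#' initializing the random recurrent weights at zero (`mu = 0`,
#' `sigma = 0`); storage then binds place/seed content directly, without a
#' decorrelated index. `barcode_only` removes spatial correlations from the
#' inputs by shrinking the place spatial scale to `nu = 1e-3`, so inputs at
#' different states are uncorrelated and no proximity structure exists.
#'
#' @param kind One of `"full"`, `"place_only"`, `"barcode_only"`,
#'   `"hybrid"`, `"gp_inputs"`.
#' @param cfg A [barcode_config()].
#' @return A function `factory(seed)` returning a fresh `barcode_model`.
#' @export
make_ablation <- function(kind = c("full", "place_only", "barcode_only",
                                   "hybrid", "gp_inputs"),
                          cfg) {
  kind <- match.arg(kind)
  switch(kind,
         full = function(seed) build_model(cfg, seed = seed),
         place_only = function(seed)
           build_model(cfg, seed = seed, mu = 0, sigma = 0),
         barcode_only = {
           cfg2 <- cfg; cfg2$nu <- 1e-3
           function(seed) build_model(cfg2, seed = seed)
         },
         hybrid = function(seed)
           build_model(cfg, seed = seed, variant = "hybrid"),
         gp_inputs = function(seed)
           build_model(cfg, seed = seed, variant = "gp_inputs"))
}

#' Run the multi-cache caching task
#'
#' For each replicate seed a fresh model is built from the factory, the
#' caches are stored in order, and recall is probed at every query state
#' for every search strength (optionally after each cache). The tidy
#' per-query results carry the seed output, the presence decision, the
#' place-output peak state, and the Cache Location success flag.
#'
#' @param spec A [task_spec()].
#' @param cfg A [barcode_config()].
#' @param factory A model factory, e.g. from [make_ablation()] (default:
#'   the full model).
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @return An object of class `task_result`: list with `data` (one row per
#'   seed x cache-count x s x query), `spec`, and `cache_locations`.
#' @export
run_three_cache_task <- function(spec = task_spec(), cfg,
                                 factory = make_ablation("full", cfg),
                                 seed = cfg$rng_seed) {
  spec <- resolve_task_spec(spec, cfg)
  caches <- spec$cache_locations
  eval_points <- if (spec$after_each_cache) seq_along(caches)
                 else length(caches)
  rows <- list()
  for (i in seq_len(spec$n_seeds)) {
    model <- tryCatch(factory(seed + i),
                      error = function(e)
                        stop("model factory failed for replicate ", i, ": ",
                             conditionMessage(e)))
    stored <- integer(0)
    for (ci in seq_along(caches)) {
      model <- store_cache(model, caches[ci])
      stored <- c(stored, caches[ci])
      if (!ci %in% eval_points) next
      for (s in spec$s_values) {
        rc <- recall_curve(model, spec$query_states, s_strength = s)
        present <- cache_presence_decision(rc$y_seed, cfg)
        peaks <- apply(rc$y_place, 2, place_output_peak,
                       bank = model$bank, N_s = cfg$N_s)
        success <- vapply(seq_along(spec$query_states), function(qi) {
          cache_location_success(rc$y_seed[qi], rc$y_place[, qi],
                                 spec$query_states[qi], stored, model,
                                 spec$window)
        }, logical(1))
        dmin <- vapply(spec$query_states, function(q)
          min(state_distance(q, stored, cfg$N_s)), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = i, n_caches = ci, s = s, state = spec$query_states,
          y_seed = rc$y_seed, present = present, peak_state = peaks,
          success = success, dist_nearest = dmin)
      }
    }
  }
  out <- list(data = do.call(rbind, rows), spec = spec,
              cache_locations = caches)
  class(out) <- "task_result"
  out
}

#' Normal-approximation binomial confidence interval
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return Named vector with `p`, `lo`, `hi` (clamped to `[0, 1]`).
#' @export
binomial_ci <- function(k, n, level = 0.99) {
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  c(p = p, lo = max(0, p - z * se), hi = min(1, p + z * se))
}

#' Aggregate a task result into per-state probabilities
#'
#' @param result A `task_result`.
#' @param metric `"present"` (Cache Presence response rate) or
#'   `"success"` (Cache Location success rate).
#' @return Data frame with `n_caches`, `s`, `state`, `dist_nearest`, `p`,
#'   `lo`, `hi`.
#' @export
summarize_task <- function(result, metric = c("present", "success")) {
  metric <- match.arg(metric)
  d <- result$data
  level <- result$spec$ci_level
  agg <- stats::aggregate(d[[metric]],
                          by = list(n_caches = d$n_caches, s = d$s,
                                    state = d$state,
                                    dist_nearest = d$dist_nearest),
                          FUN = function(v) c(k = sum(v), n = length(v)))
  ci <- t(apply(agg$x, 1, function(kn) binomial_ci(kn["k"], kn["n"], level)))
  cbind(agg[c("n_caches", "s", "state", "dist_nearest")],
        as.data.frame(ci))
}

#' Midpoint correct-reject probability for a pair of flanking caches
#'
#' Stores caches at the given spacing (plus the fixed third cache at 70%
#' of the track), probes the midpoint between the first two, and returns
#' the probability that the network correctly reports no seed there.
#'
#' @param cfg A [barcode_config()].
#' @param spacing Distance in states between caches 1 and 2.
#' @param s_values Search strengths.
#' @param n_seeds Replicates.
#' @param factory Model factory.
#' @param seed Master seed.
#' @return Data frame with `spacing`, `s`, `midpoint`, `p`, `lo`, `hi`.
#' @export
midpoint_correct_reject <- function(cfg, spacing, s_values = 0,
                                    n_seeds = 35L,
                                    factory = make_ablation("full", cfg),
                                    seed = cfg$rng_seed) {
  c1 <- as.integer(round(cfg$N_s * 0.2)) + 1L
  c2 <- c1 + as.integer(spacing)
  c3 <- as.integer(round(cfg$N_s * 0.7)) + 1L
  mid <- c1 + as.integer(floor(spacing / 2))  # floor state when fractional
  spec <- task_spec(cache_locations = c(c1, c2, c3), s_values = s_values,
                    n_seeds = n_seeds, query_states = mid)
  res <- run_three_cache_task(spec, cfg, factory, seed = seed)
  d <- res$data[res$data$n_caches == 3L, ]
  out <- do.call(rbind, lapply(split(d, d$s), function(g) {
    ci <- binomial_ci(sum(!g$present), nrow(g), spec$ci_level)
    data.frame(spacing = spacing, s = g$s[1], midpoint = mid,
               p = ci["p"], lo = ci["lo"], hi = ci["hi"])
  }))
  rownames(out) <- NULL
  out
}

#' Width of the supra-threshold seed-output region around a single cache
#'
#' Stores one cache and measures, on each side, how far the contiguous
#' region with seed output above `kappa` extends (at `s = 0`).
#'
#' @param cfg A [barcode_config()].
#' @param n_seeds Replicates.
#' @param location Cache state (default: mid-track).
#' @param max_extent Half-width, in states, of the probed window.
#' @param seed Master seed.
#' @return Data frame with one row per seed: `y_cache`, `width_left`,
#'   `width_right` (NA when the cache state itself is below threshold).
#' @export
false_positive_width <- function(cfg, n_seeds = 35L,
                                 location = cfg$N_s %/% 2 + 1L,
                                 max_extent = 12L, seed = cfg$rng_seed) {
  offs <- -max_extent:max_extent
  states <- ((location - 1L + offs) %% cfg$N_s) + 1L
  rows <- lapply(seq_len(n_seeds), function(i) {
    model <- build_model(cfg, seed = seed + i)
    model <- store_cache(model, location)
    y <- recall_curve(model, states, s_strength = 0)$y_seed
    supra <- y > cfg$kappa
    centre <- which(offs == 0L)
    if (!supra[centre])
      return(data.frame(seed = i, y_cache = y[centre],
                        width_left = NA_real_, width_right = NA_real_))
    wl <- 0L
    while (centre - wl - 1L >= 1L && supra[centre - wl - 1L]) wl <- wl + 1L
    wr <- 0L
    while (centre + wr + 1L <= length(offs) && supra[centre + wr + 1L])
      wr <- wr + 1L
    data.frame(seed = i, y_cache = y[centre],
               width_left = wl, width_right = wr)
  })
  do.call(rbind, rows)
}
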