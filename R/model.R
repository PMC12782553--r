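#' Build a barcode memory model
#'
#' Assembles the place-input bank, recurrent weights, seed pathway and
#' zero-initialized readouts into one model object. Variants:
#' \describe{
#'   \item{`default`}{random recurrent weights, exponential place fields.}
#'   \item{`hybrid`}{adds the successor-representation predictive matrix to
#'     the random weights (see [predictive_matrix()]).}
#'   \item{`gp_inputs`}{replaces the stereotyped place fields with
#'     Gaussian-process spatial inputs (see [gp_inputs()]).}
#' }
#'
#' @param cfg A [barcode_config()].
#' @param seed Integer master seed for this model instance (defaults to the
#'   configured `rng_seed`).
#' @param variant One of `"default"`, `"hybrid"`, `"gp_inputs"`.
#' @param mu,sigma Optional overrides of the base weight scales (used by
#'   ablations).
#' @return An object of class `barcode_model`: list with `config`, `bank`,
#'   `weights`, `j_in`, `readout` (`w_seed`, `J_place`), `traces`, `seed`,
#'   and `variant`.
#' @export
#' @examples
#' cfg <- barcode_config(N_p = 300, N_x = 300, N_s = 20, T_dyn = 10)
#' m <- build_model(cfg, seed = 1)
#' m <- store_cache(m, 5)
#' out <- recall_event(m, 5, s_strength = 0)
#' out$y_seed
build_model <- function(cfg, seed = cfg$rng_seed,
                        variant = c("default", "hybrid", "gp_inputs"),
                        mu = cfg$mu, sigma = cfg$sigma) {
  variant <- match.arg(variant)
  validate_config(cfg)
  bank <- if (variant == "gp_inputs") gp_inputs(cfg, seed) else place_inputs(cfg)
  w <- init_weights(cfg, seed, mu = mu, sigma = sigma)
  if (variant == "hybrid") w$M <- predictive_matrix(cfg)
  model <- list(config = cfg,
                bank = bank,
                weights = w,
                j_in = seed_pathway(cfg, seed),
                readout = list(w_seed = numeric(cfg$N_x), J_place = NULL),
                traces = list(),
                seed = as.integer(seed),
                variant = variant)
  class(model) <- "barcode_model"
  model
}

#' @export
print.barcode_model <- function(x, ...) {
  cat(sprintf("<barcode_model> variant = %s, N_x = %d, %d stored cache(s)\n",
              x$variant, x$config$N_x, length(x$traces)))
  invisible(x)
}

# Normalize a storage snapshot to the configured mean-square amplitude so
# every cache engages plasticity with the same strength regardless of the
# (chaotic, seed-kicked) amplitude of the raw snapshot.
storage_snapshot <- function(x, cfg) {
  ms <- mean(x^2)
  if (ms <= 0) stop("cannot store an all-zero activity pattern")
  x * sqrt(cfg$storage_norm / ms)
}

#' Store a cache memory at a location
#'
#' Runs caching-mode dynamics at the location (recurrence on, seed input
#' pulsed over the final `t_s` steps), takes the final activity as the
#' storage snapshot, normalizes its amplitude, and binds it three ways:
#' into the recurrent weights through [hebbian_update()] (forming an
#' attractor), into the seed readout (`w_seed <- w_seed + x_stored`), and
#' into the place readout (`J_place <- J_place + p x_stored^T`). The trace
#' is recorded before the weight updates are applied.
#'
#' @param model A `barcode_model`.
#' @param location 1-based state index of the cache.
#' @param noise_seed Optional seed enabling the configured noise hooks.
#' @return The updated model; the episode trace is appended to
#'   `model$traces` (fields `location`, `x_stored`, `p_stored`, `s_used`).
#' @export
store_cache <- function(model, location, noise_seed = NULL) {
  cfg <- model$config
  x_raw <- run_mode(model, location, "caching", noise_seed = noise_seed)[, 1]
  x_st <- storage_snapshot(x_raw, cfg)
  trace <- list(location = as.integer(location),
                x_stored = x_st,
                p_stored = model$bank$vectors[location, ],
                s_used = cfg$lam)
  model$traces[[length(model$traces) + 1L]] <- trace
  model$weights <- hebbian_update(model$weights, x_st, cfg)
  model$readout$w_seed <- model$readout$w_seed + x_st
  inc <- tcrossprod(trace$p_stored, x_st)
  model$readout$J_place <-
    if (is.null(model$readout$J_place)) inc else model$readout$J_place + inc
  model
}

# Readouts from a matrix of final rates (columns = queries).
read_outputs <- function(model, X) {
  cfg <- model$config
  g <- cfg$readout_gain / cfg$N_x
  y_seed <- g * as.numeric(crossprod(model$readout$w_seed, X))
  y_place <- if (is.null(model$readout$J_place)) {
    matrix(0, cfg$N_p, ncol(X))
  } else {
    g * (model$readout$J_place %*% X)
  }
  list(y_seed = y_seed, y_place = y_place)
}

#' Recall at a location
#'
#' Runs recall-mode dynamics (recurrence on, seed input held at the search
#' strength) and evaluates both plastic readouts: the scalar seed output
#' `y_seed` (high when the network has converged onto a stored attractor)
#' and the place output vector `y_place` (reinstating the place field bound
#' at storage). With no caches stored both outputs are exactly zero.
#'
#' @param model A `barcode_model`.
#' @param location 1-based state index of the query.
#' @param s_strength Nonnegative search strength; larger values widen the
#'   spatial range over which stored memories are retrieved.
#' @param noise_seed Optional seed enabling the configured noise hooks.
#' @return List with `x` (final rates), `y_seed` (scalar), `y_place`
#'   (length-`N_p` vector).
#' @export
recall_event <- function(model, location, s_strength = 0, noise_seed = NULL) {
  if (s_strength < 0) stop("search strength must be nonnegative")
  X <- run_mode(model, location, "recall", s_strength = s_strength,
                noise_seed = noise_seed)
  out <- read_outputs(model, X)
  list(x = X[, 1], y_seed = out$y_seed[1], y_place = out$y_place[, 1])
}

#' Recall at many locations at once
#'
#' Batched version of [recall_event()]: one integration with one column per
#' query location.
#'
#' @inheritParams recall_event
#' @param locations Vector of 1-based state indices.
#' @return List with `x` (`N_x x n` rates), `y_seed` (length-`n` vector),
#'   `y_place` (`N_p x n` matrix).
#' @export
recall_curve <- function(model, locations = seq_len(model$config$N_s),
                         s_strength = 0, noise_seed = NULL) {
  if (s_strength < 0) stop("search strength must be nonnegative")
  X <- run_mode(model, locations, "recall", s_strength = s_strength,
                noise_seed = noise_seed)
  out <- read_outputs(model, X)
  list(x = X, y_seed = out$y_seed, y_place = out$y_place,
       locations = locations)
}

#' Visit-mode activity at one or more locations
#'
#' Feedforward-only dynamics (`r = 0`); the final rates are proportional to
#' the location's input vector.
#'
#' @param model A `barcode_model`.
#' @param locations Vector of 1-based state indices.
#' @return Matrix of final rates (`N_x` rows).
#' @export
visit_activity <- function(model, locations = seq_len(model$config$N_s)) {
  run_mode(model, locations, "place")
}

#' Map a place-output vector to its peak state
#'
#' The place readout indexes input neurons; the peak is mapped to the state
#' nearest the preferred location of the most active readout unit.
#'
#' @param y_place Numeric vector of place outputs (length `N_p`).
#' @param bank The model's `place_input_bank`.
#' @param N_s Number of states.
#' @return 1-based state index of the peak.
#' @export
place_output_peak <- function(y_place, bank, N_s) {
  pk <- which.max(y_place)
  (round(bank$preferred_locations[pk] * N_s) %% N_s) + 1L
}
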