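# Core integrator for the rate dynamics
#
#   dv/dt = -(alpha/N) * sum(x) * v + r * J %*% x + G * p + s * j_in
#   x     = max(v, 0)
#
# integrated by explicit Euler from v = 0. `P` holds one input column per
# simulated location so that queries at many states run as one BLAS-level
# batch; the leak is a per-column scalar. The seed drive s_t is a per-step
# scalar (shared across columns) or a per-column row of a schedule matrix.

integrate_dynamics <- function(P, r, s_steps, J, j_in, cfg,
                               noise_seed = NULL, return_trajectory = FALSE) {
  n <- nrow(P); b <- ncol(P)
  steps <- n_steps(cfg)
  dt <- cfg$dt
  G <- cfg$input_gain
  use_J <- (r != 0) && !is.null(J)
  s_mat <- if (is.matrix(s_steps)) s_steps else matrix(s_steps, steps, b)
  if (nrow(s_mat) != steps)
    stop("seed schedule must have one entry per integration step")

  static_p <- 0; V <- matrix(0, n, b)
  rng_state <- NULL
  if (!is.null(noise_seed) &&
      (cfg$noise_dynamic > 0 || cfg$noise_static > 0)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(stream_seed(noise_seed, "noise"))
    if (cfg$noise_static > 0) {
      static_p <- matrix(stats::rnorm(n * b, sd = cfg$noise_static), n, b)
      V <- V + matrix(stats::rnorm(n * b, sd = cfg$noise_static), n, b)
    }
    rng_state <- TRUE
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  drive0 <- G * P + static_p
  traj <- if (return_trajectory) array(NA_real_, c(n, b, steps)) else NULL

  for (t in seq_len(steps)) {
    X <- pmax(V, 0)
    leak <- (cfg$alpha / n) * colSums(X)
    dV <- drive0 - sweep(V, 2, leak, "*")
    if (use_J) dV <- dV + r * (J %*% X)
    st <- s_mat[t, ]
    if (any(st != 0)) dV <- dV + tcrossprod(j_in, st)
    if (!is.null(rng_state) && cfg$noise_dynamic > 0)
      dV <- dV + matrix(stats::rnorm(n * b, sd = cfg$noise_dynamic), n, b)
    V <- V + dt * dV
    if (anyNA(V) || any(is.infinite(V)))
      stop("dynamics diverged (non-finite voltage) at step ", t)
    if (return_trajectory) traj[, , t] <- pmax(V, 0)
  }
  out <- list(v = V, x = pmax(V, 0), step = steps)
  if (return_trajectory) out$trajectory <- traj
  out
}

#' One Euler update of the network state
#'
#' Advances voltages by a single step of the rate dynamics: the leak is
#' divisive (proportional to mean population rate times `alpha`), recurrence
#' enters with gain `r`, and feedforward drive is the place input (scaled by
#' the configured input gain) plus the scalar seed input through its fixed
#' pathway.
#'
#' @param state A list with numeric `v`, `x`, and integer `step` (as
#'   returned by [network_state()]).
#' @param p_vec Place input vector (length `N_x`).
#' @param s_val Scalar seed input.
#' @param r Recurrence gain.
#' @param w A `recurrent_weights` object (may be NULL when `r = 0`).
#' @param j_in Seed pathway vector.
#' @param cfg A [barcode_config()].
#' @return The updated state; rates satisfy `x == pmax(v, 0)`.
#' @export
step_dynamics <- function(state, p_vec, s_val, r, w, j_in, cfg) {
  n <- cfg$N_x
  if (length(state$v) != n || length(p_vec) != n)
    stop("state/input dimensions do not match the configuration")
  x <- pmax(state$v, 0)
  leak <- (cfg$alpha / n) * sum(x)
  dv <- -leak * state$v + cfg$input_gain * p_vec
  if (r != 0 && !is.null(w)) dv <- dv + r * as.numeric(effective_weights(w) %*% x)
  if (s_val != 0) dv <- dv + s_val * j_in
  v <- state$v + cfg$dt * dv
  if (anyNA(v) || any(is.infinite(v)))
    stop("dynamics diverged (non-finite voltage) at step ", state$step + 1L)
  list(v = v, x = pmax(v, 0), step = state$step + 1L)
}

#' Zero initial network state
#'
#' @param cfg A [barcode_config()].
#' @return A list with zero voltages `v`, zero rates `x`, and `step = 0`.
#' @export
network_state <- function(cfg) {
  list(v = numeric(cfg$N_x), x = numeric(cfg$N_x), step = 0L)
}

# Seed-input schedule for each protocol:
#   place:   r = 0, s = 0 throughout
#   caching: r = 1, s = lam during the final t_s steps
#   recall:  r = 1, s = s_strength throughout
mode_schedule <- function(mode, cfg, s_strength = 0) {
  steps <- n_steps(cfg)
  switch(mode,
         place = list(r = 0, s = rep(0, steps)),
         caching = list(r = 1,
                        s = c(rep(0, steps - cfg$t_s),
                              rep(cfg$lam, cfg$t_s))),
         recall = list(r = 1, s = rep(s_strength, steps)),
         stop("unknown mode: ", mode))
}

#' Run the network at one or more locations under a protocol
#'
#' Integrates the full dynamics from the zero state for the configured
#' number of steps. In `place` mode recurrence is off and activity converges
#' onto (a scalar multiple of) the location's input vector; in `caching`
#' mode recurrence is on and the seed input is pulsed at strength `lam`
#' over the final `t_s` steps; in `recall` mode recurrence is on and the
#' seed input is held at `s_strength` (the search strength) throughout.
#'
#' @param model A `barcode_model` (see [build_model()]).
#' @param locations 1-based state indices (one run per location, batched).
#' @param mode One of `"place"`, `"caching"`, `"recall"`.
#' @param s_strength Search strength for recall mode.
#' @param noise_seed Optional seed enabling the configured noise hooks for
#'   this run.
#' @return Matrix of final rates, `N_x` rows by `length(locations)` columns.
#' @export
run_mode <- function(model, locations, mode = c("place", "caching", "recall"),
                     s_strength = 0, noise_seed = NULL) {
  mode <- match.arg(mode)
  cfg <- model$config
  if (any(locations < 1L) || any(locations > cfg$N_s))
    stop("locations must be state indices in [1, N_s]")
  sched <- mode_schedule(mode, cfg, s_strength)
  P <- t(model$bank$vectors[locations, , drop = FALSE])
  J <- if (sched$r != 0) effective_weights(model$weights) else NULL
  integrate_dynamics(P, sched$r, sched$s, J, model$j_in, cfg,
                     noise_seed = noise_seed)$x
}
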