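#' Model configuration
#'
#' Builds the validated set of hyperparameters for the barcode network.
#' Defaults correspond to the full-size model: a circular track binned into
#' `N_s = 100` states, `N_p = N_x = 5000` input/recurrent neurons, random
#' recurrent weights with mean `mu/N_x` and variance `sigma^2/N_x`, and
#' recurrent dynamics integrated for `T_dyn` time units with Euler step `dt`.
#'
#' @param nu Spatial scale of place inputs, as a fraction of track
#'   circumference. The drive to a neuron whose preferred location is a
#'   circular distance `d` from the current state is `exp(-d/nu)`.
#' @param N_p,N_x,N_y Layer sizes (place inputs, recurrent units, place
#'   readout). The input pathway is one-to-one, so `N_p` must equal `N_x`.
#' @param N_s Number of discrete track states.
#' @param mu,sigma Scale of the mean and standard deviation of the random
#'   recurrent weights: entries are i.i.d. `N(mu/N_x, sigma^2/N_x)`.
#' @param dt Euler integration step.
#' @param alpha Strength of the activity-dependent (divisive-normalization)
#'   leak: the leak rate is `alpha * mean(x)`.
#' @param T_dyn Length of recurrent dynamics. Interpreted in the units given
#'   by `t_unit`: with `t_unit = "time"` (default) the network is integrated
#'   for `T_dyn/dt` Euler steps; with `t_unit = "steps"` for `T_dyn` steps.
#' @param t_s Duration of the seed input at the end of a caching run, in
#'   Euler steps.
#' @param lam Seed-input strength during caching.
#' @param eta Hebbian learning rate.
#' @param beta Inhibitory bias of the Hebbian update (negative).
#' @param kappa Decision threshold applied to the seed output.
#' @param k_spike Scale of Poisson spike generation for correlation
#'   analyses: counts are drawn as `Poisson(k_spike * rate)`. Calibrated so
#'   that expected per-unit counts match the study's spike statistics at
#'   this package's rate amplitudes (see the methods vignette).
#' @param K_offset Offset of the visualization spike variant: counts drawn
#'   as `Poisson(rate + K_offset)`.
#' @param gamma,rho,delta_off,D Successor-representation parameters of the
#'   predictive weight matrix: discount, scale, additive offset, and series
#'   truncation horizon (in neuron indices).
#' @param M_hidden,theta Hidden-layer size and active fraction of the
#'   feedforward barcode alternative.
#' @param input_gain Gain applied to the place input drive. This is the
#'   package's calibration of the feedforward-to-recurrent balance; see the
#'   methods vignette.
#' @param storage_norm Mean-square amplitude to which the activity snapshot
#'   is normalized before Hebbian binding, so that every stored pattern
#'   engages plasticity with the same strength.
#' @param readout_gain Fixed gain of the seed and place readouts.
#' @param t_unit Either `"time"` (T_dyn counts time units; default) or
#'   `"steps"` (T_dyn counts Euler updates).
#' @param noise_dynamic Standard deviation of per-step Gaussian noise added
#'   to the voltage derivative (0 disables).
#' @param noise_static Standard deviation of a static Gaussian offset added
#'   to the place input and the initial voltage (0 disables).
#' @param rng_seed Integer master seed; fans out to independent named
#'   streams (weights, seed pathway, noise, spikes, inputs).
#'
#' @return An object of class `barcode_config` (a validated named list).
#' @export
#' @examples
#' cfg <- barcode_config(N_x = 500, N_p = 500)
#' cfg$nu
barcode_config <- function(nu = 0.2,
                           N_p = 5000L, N_x = 5000L, N_y = 5000L,
                           N_s = 100L,
                           mu = -40, sigma = 7,
                           dt = 0.1, alpha = 20,
                           T_dyn = 100, t_s = 5L, lam = 3.0,
                           eta = 40, beta = -0.35, kappa = 0.5,
                           k_spike = 2, K_offset = 0.2,
                           gamma = 0.99, rho = 0.075,
                           delta_off = -0.015, D = 300L,
                           M_hidden = 20000L, theta = 0.05,
                           input_gain = 4,
                           storage_norm = 0.15,
                           readout_gain = 3,
                           t_unit = c("time", "steps"),
                           noise_dynamic = 0, noise_static = 0,
                           rng_seed = 1L) {
  cfg <- list(nu = nu, N_p = as.integer(N_p), N_x = as.integer(N_x),
              N_y = as.integer(N_y), N_s = as.integer(N_s),
              mu = mu, sigma = sigma, dt = dt, alpha = alpha,
              T_dyn = T_dyn, t_s = as.integer(t_s), lam = lam,
              eta = eta, beta = beta, kappa = kappa,
              k_spike = k_spike, K_offset = K_offset,
              gamma = gamma, rho = rho, delta_off = delta_off,
              D = as.integer(D),
              M_hidden = as.integer(M_hidden), theta = theta,
              input_gain = input_gain, storage_norm = storage_norm,
              readout_gain = readout_gain,
              t_unit = match.arg(t_unit),
              noise_dynamic = noise_dynamic, noise_static = noise_static,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "barcode_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "barcode_config"))
  sizes <- c(N_p = cfg$N_p, N_x = cfg$N_x, N_y = cfg$N_y, N_s = cfg$N_s)
  if (any(sizes < 1L)) stop("all layer sizes must be positive integers")
  if (cfg$N_p != cfg$N_x)
    stop("N_p must equal N_x: the input pathway is one-to-one")
  if (cfg$nu <= 0) stop("nu must be positive")
  if (cfg$dt <= 0) stop("dt must be positive")
  if (cfg$eta <= 0) stop("eta must be positive")
  if (cfg$beta >= 0) stop("beta must be negative")
  if (cfg$kappa <= 0 || cfg$kappa >= 1) stop("kappa must lie in (0, 1)")
  if (n_steps(cfg) < cfg$t_s)
    stop("dynamics must run at least t_s steps (T_dyn too short)")
  if (cfg$gamma <= 0 || cfg$gamma >= 1) stop("gamma must lie in (0, 1)")
  if (cfg$D < 1L) stop("D must be at least 1")
  if (cfg$theta <= 0 || cfg$theta > 1) stop("theta must lie in (0, 1]")
  if (cfg$noise_dynamic < 0 || cfg$noise_static < 0)
    stop("noise magnitudes must be nonnegative")
  invisible(cfg)
}

#' Number of Euler updates implied by a configuration
#'
#' @param cfg A `barcode_config`.
#' @return Integer number of integration steps.
#' @export
n_steps <- function(cfg) {
  if (cfg$t_unit == "time") as.integer(round(cfg$T_dyn / cfg$dt))
  else as.integer(cfg$T_dyn)
}

#' Rescale a configuration to a smaller network
#'
#' Produces a configuration with `N_x = N_p = N_y = n` while preserving the
#' dynamical regime. The recurrent weight statistics scale automatically
#' through the `mu/N_x`, `sigma^2/N_x` parameterization. The
#' successor-representation parameters are rescaled so that the predictive
#' matrix acts identically on smooth activity profiles: the discount per
#' neuron is raised to the power `N_ref/n`, the per-entry scale and offset
#' are multiplied by `N_ref/n`, and the truncation horizon shrinks by
#' `n/N_ref` (all relative to the reference size `N_ref`).
#'
#' @param cfg A `barcode_config`.
#' @param n Target number of recurrent neurons.
#' @param N_ref Reference size at which the printed parameters apply.
#' @return A rescaled `barcode_config`.
#' @export
scale_config <- function(cfg, n, N_ref = 5000L) {
  f <- N_ref / n
  cfg$N_p <- cfg$N_x <- cfg$N_y <- as.integer(n)
  cfg$gamma <- cfg$gamma^f
  cfg$rho <- cfg$rho * f
  cfg$delta_off <- cfg$delta_off * f
  cfg$D <- max(1L, as.integer(round(cfg$D / f)))
  cfg$M_hidden <- max(1L, as.integer(round(cfg$M_hidden / f)))
  validate_config(cfg)
  cfg
}

config_field_types <- function() {
  c(nu = "num", N_p = "int", N_x = "int", N_y = "int", N_s = "int",
    mu = "num", sigma = "num", dt = "num", alpha = "num", T_dyn = "num",
    t_s = "int", lam = "num", eta = "num", beta = "num", kappa = "num",
    k_spike = "num", K_offset = "num", gamma = "num", rho = "num",
    delta_off = "num", D = "int", M_hidden = "int", theta = "num",
    input_gain = "num", storage_norm = "num", readout_gain = "num",
    t_unit = "chr", noise_dynamic = "num", noise_static = "num",
    rng_seed = "int")
}

#' Read a configuration from a flat key/value text file
#'
#' The file holds one `key = value` pair per line; `#` starts a comment.
#' Keys must be `barcode_config` field names; unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @return A `barcode_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed config line (expected 'key = value'): ",
         lines[!grepl("=", lines, fixed = TRUE)][1L])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  types <- config_field_types()
  unknown <- setdiff(keys, names(types))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    switch(types[[keys[i]]],
           int = as.integer(vals[i]),
           num = as.numeric(vals[i]),
           chr = vals[i])
  })
  names(args) <- keys
  names(args)[names(args) == "T_dyn"] <- "T_dyn"
  do.call(barcode_config, args)
}

#' Write a configuration to a flat key/value text file
#'
#' @param cfg A `barcode_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  lines <- vapply(names(config_field_types()), function(k) {
    sprintf("%s = %s", k, format(cfg[[k]], digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.barcode_config <- function(x, ...) {
  cat("<barcode_config>\n")
  cat(sprintf("  network: N_x = %d, N_s = %d states, sigma = %g, mu = %g\n",
              x$N_x, x$N_s, x$sigma, x$mu))
  cat(sprintf("  dynamics: %d Euler steps of dt = %g (T = %g %s), alpha = %g\n",
              n_steps(x), x$dt, x$T_dyn, x$t_unit, x$alpha))
  cat(sprintf("  learning: eta = %g, beta = %g, kappa = %g\n",
              x$eta, x$beta, x$kappa))
  invisible(x)
}
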