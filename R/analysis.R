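#' Simulate Poisson spike counts from rates
#'
#' Two parameterizations are supported: `"scaled"` draws
#' `Poisson(k * rate)` (used for the correlation analyses, where `k`
#' matches the attenuation seen in experimental visit-visit profiles), and
#' `"offset"` draws `Poisson(rate + K)` (used for visualization, giving
#' every unit a baseline count).
#'
#' @param rates Nonnegative numeric vector (or matrix) of rates.
#' @param cfg A [barcode_config()] (uses `k_spike` or `K_offset`).
#' @param parameterization `"scaled"` or `"offset"`.
#' @return Integer spike counts with the same shape as `rates`.
#' @export
simulate_spikes <- function(rates, cfg,
                            parameterization = c("scaled", "offset")) {
  parameterization <- match.arg(parameterization)
  if (any(rates < 0)) stop("rates must be nonnegative")
  lambda <- if (parameterization == "scaled") cfg$k_spike * rates
            else rates + cfg$K_offset
  out <- stats::rpois(length(lambda), lambda)
  if (is.matrix(rates)) dim(out) <- dim(rates)
  out
}

#' Rate-based visit correlation profile across state separations
#'
#' Runs place-mode dynamics at every state and computes the population
#' Pearson correlation between final activity vectors as a function of
#' circular state separation, normalized by the zero-separation value.
#' Because place-mode activity is exactly proportional to the input
#' vectors, this equals the input-bank correlation profile (closed form:
#' Pearson correlation of circularly shifted exponential bumps).
#'
#' @param model A `barcode_model`.
#' @param separations Integer separations to evaluate (default 0 to
#'   `N_s/2`).
#' @param normalization `"max"` divides by the zero-separation value
#'   (which is 1 for rate-based profiles); `"minmax"` additionally rescales
#'   the profile to span `[0, 1]` over the evaluated separations.
#' @return Data frame with `separation` (states) and `value`.
#' @export
visit_correlation_profile <- function(model,
                                      separations = 0:(model$config$N_s %/% 2),
                                      normalization = c("max", "minmax")) {
  normalization <- match.arg(normalization)
  X <- visit_activity(model)
  cc <- stats::cor(X)
  N_s <- model$config$N_s
  vals <- vapply(separations, function(s) {
    idx <- cbind(seq_len(N_s), ((seq_len(N_s) - 1 + s) %% N_s) + 1)
    mean(cc[idx])
  }, numeric(1))
  vals <- vals / vals[separations == 0][1]
  if (normalization == "minmax")
    vals <- (vals - min(vals)) / (max(vals) - min(vals))
  data.frame(separation = separations, value = vals)
}

#' Calibrate the site distance from a correlation profile
#'
#' Returns the state separation at which the normalized visit-visit
#' correlation first crosses a target value (linear interpolation between
#' the bracketing separations, rounded to the nearest integer state). This
#' ties the simulation's spatial scale to the spacing of adjacent cache
#' sites in the arena, where the corresponding normalized correlation is
#' about 0.75.
#'
#' @param profile Data frame with `separation` and `value` (monotone
#'   decreasing over the probed range), as from
#'   [visit_correlation_profile()].
#' @param target Target normalized correlation (default 0.75).
#' @return Integer number of states.
#' @export
calibrate_site_distance <- function(profile, target = 0.75) {
  sep <- profile$separation
  val <- profile$value
  below <- which(val <= target)
  if (!length(below) || all(val <= target))
    stop("calibration failure: target ", target,
         " is outside the profile's range")
  i <- below[1]
  if (i == 1) return(as.integer(sep[1]))
  # linear interpolation between the bracketing separations
  frac <- (val[i - 1] - target) / (val[i - 1] - val[i])
  as.integer(round(sep[i - 1] + frac * (sep[i] - sep[i - 1])))
}

#' Spike-count correlation profile for visits, caches and retrievals
#'
#' Simulates in-silico experiments: in each experiment a fresh model is
#' built, several sites (chosen on the 8-state site grid) are cached in
#' sequence, and population activity is collected for two independent
#' visits (feedforward mode), the stored cache snapshots, and retrievals
#' (recall mode at the cached sites). Poisson spikes are drawn from all
#' activity vectors and population Pearson correlations between event
#' pairs are pooled across experiments, binned by site distance, and
#' normalized by the visit-visit value at distance zero.
#'
#' @param cfg A [barcode_config()].
#' @param n_experiments Number of simulated experiments.
#' @param n_sites Number of cached sites per experiment.
#' @param seed Master seed.
#' @param site_spacing States per site (distance unit).
#' @param variant Model variant passed to [build_model()].
#' @param use_spikes If FALSE, correlate rates directly (no Poisson draw).
#' @return An object of class `correlation_profile`: data frame with
#'   `condition` (`visit_visit` / `cache_retrieval`), `distance` (site
#'   units), `value` (normalized mean correlation), `lo`/`hi` (99% normal
#'   CI), and `n_pairs`; the visit-visit distance-0 normalizer is stored in
#'   `attr(, "normalization")`.
#' @export
correlation_profile <- function(cfg, n_experiments = 20, n_sites = 5,
                                seed = cfg$rng_seed, site_spacing = 8L,
                                variant = "default", use_spikes = TRUE) {
  if (n_sites < 2) stop("need at least two sites to form pairs")
  n_grid <- cfg$N_s %/% site_spacing
  rows <- list()
  for (e in seq_len(n_experiments)) {
    mseed <- stream_seed(seed + e, "task")
    sites <- with_stream(mseed, "task",
                         sort(sample.int(n_grid, n_sites)) - 1L) *
      site_spacing + 1L
    model <- build_model(cfg, seed = mseed, variant = variant)
    for (s in sites) model <- store_cache(model, s)
    Xv <- visit_activity(model, sites)
    Xr <- recall_curve(model, sites, s_strength = 0)$x
    Xc <- vapply(model$traces, `[[`, numeric(cfg$N_x), "x_stored")
    draw <- function(X, salt) {
      if (!use_spikes) return(X)
      with_stream(mseed + salt, "spikes", simulate_spikes(X, cfg, "scaled"))
    }
    Sv1 <- draw(Xv, 1L); Sv2 <- draw(Xv, 2L)
    Sc <- draw(Xc, 3L); Sr <- draw(Xr, 4L)
    for (i in seq_along(sites)) for (j in seq_along(sites)) {
      dist_sites <- state_distance(sites[i], sites[j], cfg$N_s) / site_spacing
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = e, condition = "visit_visit", distance = dist_sites,
        corr = suppressWarnings(stats::cor(Sv1[, i], Sv2[, j])))
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = e, condition = "cache_retrieval", distance = dist_sites,
        corr = suppressWarnings(stats::cor(Sc[, i], Sr[, j])))
    }
  }
  raw <- do.call(rbind, rows)
  raw <- raw[is.finite(raw$corr), ]
  norm0 <- mean(raw$corr[raw$condition == "visit_visit" & raw$distance == 0])
  agg <- stats::aggregate(corr ~ condition + distance, raw, function(v) {
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  z <- stats::qnorm(0.995)
  out <- data.frame(condition = agg$condition, distance = agg$distance,
                    value = agg$corr[, "mean"] / norm0,
                    lo = (agg$corr[, "mean"] - z * agg$corr[, "se"]) / norm0,
                    hi = (agg$corr[, "mean"] + z * agg$corr[, "se"]) / norm0,
                    n_pairs = agg$corr[, "n"])
  out <- out[order(out$condition, out$distance), ]
  rownames(out) <- NULL
  attr(out, "normalization") <- norm0
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Projection decomposition of hybrid-model activity over recurrence gain
#'
#' For each recurrence gain `r` the network is run at every location and
#' the final activity is projected onto three unit-normalized reference
#' vectors defined per location: the place code (activity at `r = 0`), the
#' predictive code (the place-code pattern of the next clockwise location,
#' orthogonalized against the local place code), and the barcode (activity
#' at `r = 1`, orthogonalized against the place code). Projection
#' magnitudes are averaged over locations and each curve is normalized by
#' its maximum.
#'
#' @param model A `barcode_model` (normally the `hybrid` variant).
#' @param r_values Recurrence gains to sweep (all in `[0, 1]`).
#' @param predictive_offset Forward offset, in states, of the place pattern
#'   used as the predictive reference (default 1, the next clockwise
#'   state).
#' @param normalize_activity If TRUE (default), each location's activity
#'   vector is normalized to unit length before projecting, so the curves
#'   reflect the *direction* of population activity; total activity grows
#'   with the recurrence gain and would otherwise confound the comparison
#'   across `r`.
#' @return An object of class `projection_decomposition`: data frame with
#'   `r`, `code` (`place` / `predictive` / `barcode`), and `projection`
#'   (max-normalized mean magnitude).
#' @export
code_projection <- function(model, r_values = seq(0, 1, by = 0.1),
                            predictive_offset = 1L,
                            normalize_activity = TRUE) {
  if (any(r_values < 0 | r_values > 1))
    stop("recurrence gains must lie in [0, 1]")
  cfg <- model$config
  locs <- seq_len(cfg$N_s)
  run_gain <- function(r) {
    sched <- rep(0, n_steps(cfg))
    J <- if (r == 0) NULL else effective_weights(model$weights)
    integrate_dynamics(t(model$bank$vectors), r, sched, J, model$j_in, cfg)$x
  }
  X0 <- run_gain(0)
  X1 <- run_gain(1)
  unitize <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  orth <- function(M, U) {
    # remove each column's projection onto the matching unit column of U
    M - sweep(U, 2, colSums(M * U), "*")
  }
  place_ref <- unitize(X0)
  nxt <- ((locs - 1L + predictive_offset) %% cfg$N_s) + 1L
  pred_ref <- unitize(orth(X0[, nxt, drop = FALSE], place_ref))
  barc_ref <- unitize(orth(X1, place_ref))
  proj <- function(X, R) {
    if (normalize_activity) {
      nrm <- sqrt(colSums(X^2))
      X <- sweep(X, 2, pmax(nrm, .Machine$double.eps), "/")
    }
    abs(colSums(X * R))
  }
  rows <- lapply(r_values, function(r) {
    X <- if (r == 0) X0 else if (r == 1) X1 else run_gain(r)
    data.frame(r = r,
               code = c("place", "predictive", "barcode"),
               projection = c(mean(proj(X, place_ref)),
                              mean(proj(X, pred_ref)),
                              mean(proj(X, barc_ref))))
  })
  out <- do.call(rbind, rows)
  for (cd in unique(out$code)) {
    i <- out$code == cd
    out$projection[i] <- out$projection[i] / max(out$projection[i])
  }
  rownames(out) <- NULL
  class(out) <- c("projection_decomposition", "data.frame")
  out
}
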