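#' Successor-representation predictive weight matrix
#'
#' Builds the discounted-transition matrix
#' `M = rho * sum_{d=0}^{D} gamma^d T^d + delta`, where `T` is the
#' deterministic clockwise transition operator in neuron-index space
#' (`T_ij = 1` iff `j = i + 1`, circularly). With neurons ordered by
#' preferred location the result is circulant: the entry at forward offset
#' `d` (from neuron `i` to neuron `i + d`) equals `rho * gamma^d + delta`
#' for `d <= D` and `delta` beyond the truncation horizon.
#'
#' @param cfg A [barcode_config()] (uses `gamma`, `rho`, `delta_off`, `D`).
#' @return Dense `N_x x N_x` circulant matrix.
#' @export
#' @examples
#' cfg <- barcode_config(N_p = 50, N_x = 50, D = 10)
#' M <- predictive_matrix(cfg)
#' M[1, 1]   # rho + delta
#' M[1, 2]   # rho * gamma + delta
predictive_matrix <- function(cfg) {
  n <- cfg$N_x
  idx <- seq_len(n) - 1L
  offset <- outer(idx, idx, function(i, j) (j - i) %% n)
  vals <- rep(cfg$delta_off, n)
  d <- 0:min(cfg$D, n - 1L)
  vals[d + 1L] <- cfg$rho * cfg$gamma^d + cfg$delta_off
  matrix(vals[offset + 1L], n, n)
}

#' Hybrid recurrent weights (random + predictive)
#'
#' The effective weight matrix is `J = B + M`: the random Gaussian base of
#' the default model plus the structured successor-representation matrix.
#' At low recurrence gain the structured part dominates the response
#' (predictive, forward-shifted activity); at full gain the random part
#' generates barcodes.
#'
#' @param cfg A [barcode_config()].
#' @param seed Integer seed for the random base.
#' @return A `recurrent_weights` object with non-null `M`.
#' @export
hybrid_weights <- function(cfg, seed) {
  w <- init_weights(cfg, seed)
  w$M <- predictive_matrix(cfg)
  w
}

#' Feedforward barcode model
#'
#' Alternative barcode generator without recurrence: place inputs are
#' projected into a large hidden expansion layer
#' (`x_h = ReLU(W_h p - C_theta)`), thresholded to an active fraction
#' `theta`, then compressed (`x = ReLU(W_o x_h - C)`) with the output
#' threshold chosen to reach a target output sparsity.
#'
#' @param cfg A [barcode_config()] (uses `M_hidden`, `N_p`, `N_x`).
#' @param seed Integer seed for the random projections.
#' @return List with `W_h` (`M_hidden x N_p`, entries `N(0, 1/N_p)`) and
#'   `W_o` (`N_x x M_hidden`, entries `N(0, 1/M_hidden)`).
#' @export
feedforward_model <- function(cfg, seed) {
  m <- cfg$M_hidden; np <- cfg$N_p; nx <- cfg$N_x
  with_stream(seed, "feedforward", {
    list(W_h = matrix(stats::rnorm(m * np, sd = sqrt(1 / np)), m, np),
         W_o = matrix(stats::rnorm(nx * m, sd = sqrt(1 / m)), nx, m))
  })
}

# Threshold a vector so that exactly ceiling(frac * n) entries stay active.
threshold_to_fraction <- function(h, frac) {
  n <- length(h)
  k <- max(1L, min(n, as.integer(ceiling(frac * n))))
  cut <- sort(h, decreasing = TRUE)[k]
  out <- h - cut
  out[out < 0] <- 0
  # entries tied with the cut stay at zero; at most one unit of rounding
  out
}

#' Generate feedforward barcodes for every state
#'
#' Thresholds are chosen per input pattern: `C_theta` so that the hidden
#' active fraction equals `theta` (within one unit's rounding) for each
#' state, and the output threshold so the barcode sparsity matches
#' `target_sparsity`.
#'
#' @param bank A `place_input_bank`.
#' @param ff A feedforward model from [feedforward_model()].
#' @param cfg A [barcode_config()] (uses `theta`).
#' @param target_sparsity Desired active fraction of the output barcodes.
#' @return Matrix of barcodes, `N_s` rows by `N_x` columns.
#' @export
feedforward_barcode <- function(bank, ff, cfg, target_sparsity) {
  if (target_sparsity <= 0 || target_sparsity > 1)
    stop("target sparsity must lie in (0, 1]")
  Hraw <- ff$W_h %*% t(bank$vectors)      # M_hidden x N_s
  Xh <- apply(Hraw, 2, threshold_to_fraction, frac = cfg$theta)
  if (all(Xh == 0))
    stop("target sparsity unreachable: hidden layer is all zero")
  Oraw <- ff$W_o %*% Xh                   # N_x x N_s
  Xo <- apply(Oraw, 2, threshold_to_fraction, frac = target_sparsity)
  t(Xo)
}
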