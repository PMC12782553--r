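#' Initialize recurrent weights
#'
#' Draws the base random matrix `B` with i.i.d. entries
#' `N(mu/N_x, sigma^2/N_x)`. The negative mean implements global
#' subtractive inhibition that sparsifies activity; the variance scale sets
#' the strength of chaotic recurrence. Hebbian increments `H` start at
#' exactly zero, and the predictive component `M` is absent unless supplied
#' by [hybrid_weights()].
#'
#' @param cfg A [barcode_config()].
#' @param seed Integer seed (fans into the `weights` stream).
#' @param mu,sigma Optional overrides of the configured scales (used by the
#'   "place code only" ablation, which sets both to zero).
#' @return An object of class `recurrent_weights`: list with dense `B`,
#'   optional `M` (NULL when absent), `H` (NULL until the first cache), and
#'   the dimension `n`.
#' @export
init_weights <- function(cfg, seed, mu = cfg$mu, sigma = cfg$sigma) {
  validate_config(cfg)
  n <- cfg$N_x
  B <- if (mu == 0 && sigma == 0) {
    matrix(0, n, n)
  } else {
    with_stream(seed, "weights",
                matrix(stats::rnorm(n * n, mean = mu / n, sd = sigma / sqrt(n)),
                       n, n))
  }
  w <- list(B = B, M = NULL, H = NULL, n = n)
  class(w) <- "recurrent_weights"
  w
}

#' Effective recurrent weight matrix
#'
#' @param w A `recurrent_weights` object.
#' @return The dense matrix `B + M + H` (absent components count as zero).
#' @export
effective_weights <- function(w) {
  J <- w$B
  if (!is.null(w$M)) J <- J + w$M
  if (!is.null(w$H)) J <- J + w$H
  J
}

#' Fixed input pathway of the scalar seed unit
#'
#' The seed unit projects onto every recurrent neuron through weights drawn
#' once from the standard normal distribution; these weights are never
#' modified by learning.
#'
#' @param cfg A [barcode_config()].
#' @param seed Integer seed (fans into the `seed_pathway` stream).
#' @return Numeric vector of length `N_x`.
#' @export
seed_pathway <- function(cfg, seed) {
  with_stream(seed, "seed_pathway", stats::rnorm(cfg$N_x))
}

#' Hebbian weight update
#'
#' Applies the storage rule
#' `Delta J = (eta/N_x) * (x x^T + beta * x 1^T)`,
#' i.e. `Delta J_ij = (eta/N_x) * (x_i x_j + beta x_i)`: an outer-product
#' Hebbian term plus an inhibitory bias that weakens the synapses of
#' neurons inactive during storage, preventing spurious convergence onto
#' stored attractors. Rows of the increment are nonzero only where
#' `x_i > 0` (postsynaptic gating).
#'
#' @param w A `recurrent_weights` object.
#' @param x Nonnegative activity vector of length `N_x`.
#' @param cfg A [barcode_config()].
#' @return The updated `recurrent_weights`.
#' @export
#' @examples
#' cfg <- barcode_config(N_p = 100, N_x = 100)
#' w <- init_weights(cfg, seed = 1, mu = 0, sigma = 0)
#' w <- hebbian_update(w, c(1, rep(0, 99)), cfg)
#' w$H[1, 1]    # (eta/N)*(1 + beta)
hebbian_update <- function(w, x, cfg) {
  if (length(x) != w$n)
    stop("activity vector length does not match network size")
  if (any(x < 0)) stop("Hebbian update requires nonnegative activity")
  inc <- (cfg$eta / w$n) * (tcrossprod(x, x + cfg$beta))
  # tcrossprod(x, x + beta) has entries x_i * (x_j + beta), which is
  # exactly x_i x_j + beta x_i
  w$H <- if (is.null(w$H)) inc else w$H + inc
  w
}
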