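#' Build the bank of place input vectors
#'
#' Every recurrent neuron has a preferred location; the `N_p` preferred
#' locations are evenly spaced on the circular track `[0, 1)`. When the
#' animal occupies state `k`, input neuron `l` is driven with
#' `exp(-d(k, l)/nu)`, where `d` is the minimum circular distance between
#' the state's position and the neuron's preferred location, expressed as a
#' fraction of the track circumference. Drives therefore lie in `(0, 1]`,
#' equal 1 exactly when a neuron's preferred location coincides with the
#' state, and the correlation between two states' input vectors depends
#' only on their circular separation.
#'
#' @param cfg A [barcode_config()].
#' @return An object of class `place_input_bank`: a list with `vectors`
#'   (`N_s x N_p` matrix, rows indexed by state), `preferred_locations`
#'   (length `N_p`, fractions in `[0, 1)`), and `positions` (length `N_s`,
#'   state positions in `[0, 1)`).
#' @export
#' @examples
#' bank <- place_inputs(barcode_config(N_p = 200, N_x = 200, N_s = 20))
#' range(bank$vectors)
place_inputs <- function(cfg) {
  validate_config(cfg)
  positions <- (seq_len(cfg$N_s) - 1) / cfg$N_s
  preferred <- (seq_len(cfg$N_p) - 1) / cfg$N_p
  d <- abs(outer(positions, preferred, "-"))
  d <- pmin(d, 1 - d)
  bank <- list(vectors = exp(-d / cfg$nu),
               preferred_locations = preferred,
               positions = positions,
               kind = "place")
  class(bank) <- "place_input_bank"
  bank
}

#' Circular distance between track positions
#'
#' @param a,b Positions as fractions of the circumference.
#' @return Minimum circular distance, in `[0, 0.5]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 1 - d)
}

#' Circular distance between state indices, in states
#'
#' @param i,j 1-based state indices.
#' @param N_s Number of states.
#' @return Distance in states, in `[0, N_s/2]`.
#' @export
state_distance <- function(i, j, N_s) {
  d <- abs(i - j)
  pmin(d, N_s - d)
}

#' Gaussian-process place inputs
#'
#' Alternative spatial input format: instead of stereotyped exponential
#' place fields, the input profile across neurons is one draw from a
#' zero-mean Gaussian process whose covariance between neurons `i` and `j`
#' is `exp(-d(i, j)/0.4)`, with `d` the minimum circular distance between
#' their preferred locations. The profile is circularly shifted with the
#' agent's state, so input correlation still decays smoothly with spatial
#' separation while individual tuning curves are random and irregular.
#'
#' @param cfg A [barcode_config()].
#' @param seed Integer seed for the process draw.
#' @param length_scale Covariance length scale (fraction of circumference).
#' @return A `place_input_bank` with `kind = "gp"`.
#' @export
gp_inputs <- function(cfg, seed, length_scale = 0.4) {
  validate_config(cfg)
  n <- cfg$N_p
  preferred <- (seq_len(n) - 1) / n
  d <- abs(outer(preferred, preferred, "-"))
  d <- pmin(d, 1 - d)
  Sigma <- exp(-d / length_scale)
  z <- with_stream(seed, "inputs", {
    L <- chol_with_jitter(Sigma)
    as.numeric(crossprod(L, stats::rnorm(n)))
  })
  positions <- (seq_len(cfg$N_s) - 1) / cfg$N_s
  shift_per_state <- n / cfg$N_s
  vectors <- t(vapply(seq_len(cfg$N_s), function(k) {
    sh <- round((k - 1) * shift_per_state)
    if (sh == 0) z else c(z[(sh + 1):n], z[1:sh])
  }, numeric(n)))
  bank <- list(vectors = vectors, preferred_locations = preferred,
               positions = positions, kind = "gp")
  class(bank) <- "place_input_bank"
  bank
}

# Cholesky with escalating diagonal jitter; errors if factorization keeps
# failing (the GP kernel is near-singular at large N).
chol_with_jitter <- function(Sigma, tries = 6L) {
  jit <- 0
  for (i in seq_len(tries)) {
    L <- tryCatch(chol(Sigma + diag(jit, nrow(Sigma))),
                  error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-10 else jit * 100
  }
  stop("covariance factorization failed even with jitter ", jit)
}
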