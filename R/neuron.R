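#' Neuron threshold configuration
#'
#' @param theta firing threshold in membrane-potential units.
#' @param u_reset reset baseline applied to neurons that fire; must lie below
#'   `theta`.
#' @export
neuron_config <- function(theta = 1, u_reset = 0) {
  if (!(theta > u_reset)) stop_config("theta must exceed u_reset")
  structure(list(theta = theta, u_reset = u_reset), class = "neuron_config")
}

#' Surrogate-derivative specification
#'
#' The binary spike nonlinearity has no useful derivative, so the backward
#' pass substitutes a smooth pseudo-derivative centred on the threshold.
#' Families:
#' \describe{
#'   \item{`exp`}{`exp(-scale * |u - theta|)` (SLAYER-style exponential).}
#'   \item{`fast_sigmoid`}{`1 / (1 + scale * |u - theta|)^2`.}
#' }
#' Both peak at 1 when `u = theta`, are symmetric in `u - theta`, and decay
#' to zero away from the threshold; `scale` sets the sharpness.
#'
#' @param shape surrogate family identifier.
#' @param scale sharpness (dimensionless, > 0).
#' @export
surrogate_spec <- function(shape = c("exp", "fast_sigmoid"), scale = 5) {
  shape <- match.arg(shape)
  if (scale <= 0) stop_config("surrogate scale must be > 0")
  structure(list(shape = shape, scale = scale), class = "surrogate_spec")
}

#' Threshold spike function
#'
#' Emits a binary spike wherever the membrane potential reaches the
#' threshold (`u >= theta`) and resets those entries to the baseline
#' `u_reset`; sub-threshold entries pass through unchanged.
#'
#' @param u membrane potential vector.
#' @param cfg a [neuron_config()].
#' @return list with `spikes` (binary vector) and `u_after`.
#' @export
spike_function <- function(u, cfg = neuron_config()) {
  fired <- u >= cfg$theta
  u_after <- u
  u_after[fired] <- cfg$u_reset
  list(spikes = as.numeric(fired), u_after = u_after)
}

#' Surrogate derivative of the spike function
#'
#' The pseudo-derivative used on the backward pass in place of the undefined
#' derivative of [spike_function()]. Forward passes still emit exact binary
#' spikes.
#'
#' @param u membrane potential (vector, matrix or array).
#' @param cfg a [neuron_config()].
#' @param sur a [surrogate_spec()].
#' @return array of the same shape as `u`, non-negative, maximal at
#'   `u = theta`.
#' @export
surrogate_derivative <- function(u, cfg = neuron_config(),
                                 sur = surrogate_spec()) {
  x <- u - cfg$theta
  switch(sur$shape,
    exp = exp(-sur$scale * abs(x)),
    fast_sigmoid = 1 / (1 + sur$scale * abs(x))^2
  )
}

# Smooth primitive of the surrogate: a sigmoid-shaped function whose exact
# derivative is surrogate_derivative(). Running the forward pass with this in
# place of the hard threshold ("smooth mode") makes the whole unrolled loss
# differentiable, so backpropagated gradients can be validated against
# central finite differences. Only used for gradient checking.
surrogate_primitive <- function(u, cfg, sur) {
  if (sur$shape != "exp") {
    stop_config("smooth mode is implemented for the 'exp' surrogate family")
  }
  x <- u - cfg$theta
  s <- sur$scale
  out <- x
  neg <- x < 0
  out[neg] <- exp(s * x[neg]) / s
  out[!neg] <- 2 / s - exp(-s * x[!neg]) / s
  out
}
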