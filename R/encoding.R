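# Conversions between continuous signals and spike populations.

#' Place-coded population encoding specification
#'
#' Each scalar observation is represented by `pop_size` neurons with Gaussian
#' tuning curves whose centers are equally spaced over the clip range. A
#' neuron's per-step firing probability is its tuning-curve value at the
#' (clipped) observation, floored at `theta_min` so every neuron keeps a
#' baseline stochastic rate.
#'
#' @param pop_size neurons per scalar input.
#' @param clip_lo,clip_hi observation clipping bounds.
#' @param theta_min floor spike probability per neuron per step.
#' @param peak tuning-curve maximum firing probability.
#' @param width tuning-curve width; defaults to 1.5 times the center spacing.
#' @param centers optional explicit centers (strictly increasing, spanning
#'   the clip range).
#' @export
population_code_spec <- function(pop_size = 50L, clip_lo = -1, clip_hi = 1,
                                 theta_min = 0.02, peak = 0.8,
                                 width = NULL, centers = NULL) {
  if (clip_hi <= clip_lo) stop_config("clip_hi must exceed clip_lo")
  if (theta_min < 0 || theta_min > 1) stop_config("theta_min must be in [0, 1]")
  if (peak < theta_min || peak > 1) stop_config("peak must be in [theta_min, 1]")
  if (is.null(centers)) centers <- seq(clip_lo, clip_hi, length.out = pop_size)
  if (any(diff(centers) <= 0)) stop_config("centers must be strictly increasing")
  spacing <- if (pop_size > 1L) diff(centers)[1L] else (clip_hi - clip_lo)
  if (is.null(width)) width <- 1.5 * spacing
  structure(list(pop_size = as.integer(pop_size), clip_lo = clip_lo,
                 clip_hi = clip_hi, theta_min = theta_min, peak = peak,
                 width = width, centers = centers),
            class = "population_code_spec")
}

#' Per-neuron firing probabilities for an observation vector
#'
#' @param x observation vector (clipped to the spec's range).
#' @param spec a [population_code_spec()].
#' @return matrix `[length(x), pop_size]` of per-step spike probabilities in
#'   `[theta_min, peak]`.
#' @export
encoding_probs <- function(x, spec) {
  x <- clamp_raw(x, spec$clip_lo, spec$clip_hi)
  p <- outer(x, spec$centers, function(xi, ci)
    spec$peak * exp(-(xi - ci)^2 / (2 * spec$width^2)))
  pmax(p, spec$theta_min)
}

#' Encode an observation as a population spike train
#'
#' Every neuron fires independently each step as a Bernoulli draw at its
#' tuning probability (floored at `theta_min`). Output neurons are laid out
#' observation-major: columns `1..pop_size` code `x[1]`, the next block
#' `x[2]`, and so on.
#'
#' @param x observation vector.
#' @param spec a [population_code_spec()].
#' @param steps number of time steps to draw.
#' @return binary spike matrix `[steps, length(x) * pop_size]`.
#' @export
encode_observation <- function(x, spec, steps) {
  p <- as.vector(t(encoding_probs(x, spec))) # obs-major layout
  n <- length(p)
  matrix(rbinom(steps * n, 1L, rep(p, each = steps)), steps, n)
}

#' Positive/negative action sub-population specification
#'
#' Each action dimension is read out from two sub-populations of
#' `subpop_size` neurons: the decoded value is the positive-minus-negative
#' spike count over the integration interval `T`, normalized by
#' `T * subpop_size` and scaled by `gain`, so it is bounded in
#' `[-gain, gain]` by construction.
#'
#' @param subpop_size neurons per sign per action dimension.
#' @param T_int integration interval in time steps.
#' @param gain scale from net spike fraction to action units.
#' @export
action_population_spec <- function(subpop_size = 100L, T_int = 50L, gain = 1) {
  structure(list(subpop_size = as.integer(subpop_size),
                 T_int = as.integer(T_int), gain = gain),
            class = "action_population_spec")
}

#' Decode actions from output spike populations
#'
#' @param spikes binary matrix `[T_int, n_action * 2 * subpop_size]`; for
#'   each action dimension the positive sub-population block precedes the
#'   negative one.
#' @param spec an [action_population_spec()].
#' @return numeric action vector of length `n_action`.
#' @export
decode_action <- function(spikes, spec) {
  spikes <- as.matrix(spikes)
  if (nrow(spikes) != spec$T_int) {
    stop_validation("spikes must cover exactly T_int = ", spec$T_int, " steps")
  }
  per_dim <- 2L * spec$subpop_size
  if (ncol(spikes) %% per_dim != 0L) {
    stop_validation("spike width must be a multiple of 2 * subpop_size")
  }
  n_action <- ncol(spikes) %/% per_dim
  counts <- colSums(spikes)
  vapply(seq_len(n_action), function(d) {
    off <- (d - 1L) * per_dim
    pos <- sum(counts[off + seq_len(spec$subpop_size)])
    neg <- sum(counts[off + spec$subpop_size + seq_len(spec$subpop_size)])
    spec$gain * (pos - neg) / (spec$T_int * spec$subpop_size)
  }, numeric(1L))
}

#' Binomial decision from two output-neuron spike counts
#'
#' The two per-neuron spike counts over the decision interval act as
#' log-odds: `P(left) = logistic(count_left - count_right)` (equal activity
#' gives 0.5 by symmetry; the difference form is a two-way softmax). A side
#' is sampled and its log-probability returned for the policy gradient.
#'
#' @param out_rates numeric length-2 vector of spike counts (left, right).
#' @param greedy if `TRUE`, pick the more likely side instead of sampling.
#' @return list with `side` (`"L"` or `"R"`), `p_left`, and `log_prob` of the
#'   sampled side.
#' @export
binomial_decision <- function(out_rates, greedy = FALSE) {
  if (length(out_rates) != 2L) stop_validation("out_rates must have length 2")
  delta <- out_rates[1L] - out_rates[2L]
  p_left <- plogis(delta)
  left <- if (greedy) p_left >= 0.5 else runif(1L) < p_left
  log_prob <- -softplus_raw(if (left) -delta else delta)
  list(side = if (left) "L" else "R", p_left = p_left, log_prob = log_prob)
}

#' Gaussian policy head
#'
#' A learned log-standard-deviation vector defining a diagonal Gaussian over
#' actions around a decoded mean.
#'
#' @param sigma_log numeric vector of log standard deviations.
#' @export
gaussian_head <- function(sigma_log = -0.5) {
  structure(list(sigma_log = sigma_log), class = "gaussian_head")
}

#' Sample an action from a diagonal Gaussian head
#'
#' @param mean action mean vector.
#' @param head a [gaussian_head()] (its `sigma_log` is recycled to the
#'   action length).
#' @return list with `action` and its exact `log_prob` under the diagonal
#'   Gaussian.
#' @export
gaussian_action <- function(mean, head = gaussian_head()) {
  n <- length(mean)
  sl <- rep_len(head$sigma_log, n)
  sigma <- exp(sl)
  action <- mean + sigma * rnorm(n)
  list(action = action, log_prob = gaussian_log_prob(action, mean, sl))
}

#' Log density of a diagonal Gaussian (and its gradient)
#'
#' `gaussian_log_prob()` evaluates the exact log density; at the mean it
#' equals `-sum(sigma_log) - n/2 * log(2*pi)`.
#' `gaussian_log_prob_grad()` returns analytic derivatives with respect to
#' the mean and `sigma_log`, used when the head is trained.
#'
#' @param action,mean numeric vectors.
#' @param sigma_log log standard deviations (recycled).
#' @export
gaussian_log_prob <- function(action, mean, sigma_log) {
  sl <- rep_len(sigma_log, length(mean))
  sum(dnorm(action, mean, exp(sl), log = TRUE))
}

#' @rdname gaussian_log_prob
#' @export
gaussian_log_prob_grad <- function(action, mean, sigma_log) {
  sl <- rep_len(sigma_log, length(mean))
  s2 <- exp(2 * sl)
  dev <- (action - mean) / s2
  list(d_mean = dev, d_sigma_log = (action - mean) * dev - 1)
}
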