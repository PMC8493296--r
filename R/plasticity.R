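# The trace calculus: differentiable synaptic-trace update operators.
#
# Every rule blends the previous trace with a new activity term,
#   E' = (1 - eta) E + eta * outer(post_term, pre_term),
# then clips elementwise to [-C, C]. Orientation throughout: E is
# [n_post, n_pre]; post activity indexes rows, pre activity columns.

clip_trace <- function(E, clip) {
  if (!is.finite(clip)) return(E)
  clamp_raw(E, -clip, clip)
}

#' Tumbling spike-rate window
#'
#' Accumulates pre- and post-synaptic spike counts over a non-overlapping
#' window of `delta_tau` steps; [compute_rates()] converts the counts to
#' per-neuron rates and opens the next window. Rates are spike averages in
#' `[0, 1]` per neuron per step.
#'
#' @param delta_tau window length in steps.
#' @param n_pre,n_post neuron counts for the two populations.
#' @return a mutable `rate_window` object.
#' @export
rate_window <- function(delta_tau, n_pre, n_post) {
  if (delta_tau < 1) stop_config("delta_tau must be >= 1")
  w <- new.env(parent = emptyenv())
  w$delta_tau <- as.integer(delta_tau)
  w$accum_pre <- numeric(n_pre)
  w$accum_post <- numeric(n_post)
  w$steps_seen <- 0L
  class(w) <- "rate_window"
  w
}

#' Feed one step of spikes into a rate window
#'
#' @param window a [rate_window()].
#' @param pre,post binary spike vectors for the current step.
#' @export
window_observe <- function(window, pre, post) {
  if (window$steps_seen >= window$delta_tau) {
    stop_validation("window already full; call compute_rates() first")
  }
  window$accum_pre <- window$accum_pre + pre
  window$accum_post <- window$accum_post + post
  window$steps_seen <- window$steps_seen + 1L
  invisible(window)
}

#' Close a rate window and return spike averages
#'
#' Must be called exactly when `delta_tau` steps have been observed; calling
#' mid-window is a contract violation. Accumulators reset on return.
#'
#' @param window a [rate_window()].
#' @return list with `r_pre` and `r_post`, each in `[0, 1]` per neuron.
#' @export
compute_rates <- function(window) {
  if (window$steps_seen != window$delta_tau) {
    stop_validation("compute_rates() called mid-window: saw ",
                    window$steps_seen, " of ", window$delta_tau, " steps")
  }
  out <- list(r_pre = window$accum_pre / window$delta_tau,
              r_post = window$accum_post / window$delta_tau)
  window$accum_pre[] <- 0
  window$accum_post[] <- 0
  window$steps_seen <- 0L
  out
}

#' Synaptic trace state
#'
#' Holds the trace matrix `E` and, for BCM-family rules, the sliding
#' threshold trace `phi`. Traces start at zero (and `phi` at `phi_init`) at
#' the beginning of every episode; every update clips `E` to
#' `[-clip_bound, clip_bound]`.
#'
#' @param n_post,n_pre trace dimensions.
#' @param clip_bound elementwise bound `C >= 0` on the trace.
#' @param phi_init initial sliding threshold (length `n_pre`).
#' @export
trace_state <- function(n_post, n_pre, clip_bound = 2,
                        phi_init = numeric(n_pre)) {
  structure(list(E = matrix(0, n_post, n_pre), phi = phi_init,
                 clip_bound = clip_bound, phi_init = phi_init),
            class = "trace_state")
}

#' Reset traces at episode start
#'
#' @param state a [trace_state()].
#' @param phi_init optional replacement initial threshold.
#' @return the state with `E = 0` and `phi = phi_init`.
#' @export
reset_traces <- function(state, phi_init = state$phi_init) {
  state$E[] <- 0
  state$phi <- phi_init
  state$phi_init <- phi_init
  state
}

#' Linear-decay trace update
#'
#' `E' = (1 - eta) E + eta * outer(rho_post, rho_pre)`, clipped. The simplest
#' differentiable rule: new pre/post activity products are blended in at rate
#' `eta` while prior activity is remembered at rate `1 - eta`.
#'
#' @param E trace matrix `[n_post, n_pre]`.
#' @param eta incorporation rate in (0, 1).
#' @param rho_post,rho_pre activity vectors (e.g. instantaneous spikes).
#' @param clip elementwise trace bound (default unbounded).
#' @return updated trace matrix.
#' @export
linear_decay_update <- function(E, eta, rho_post, rho_pre, clip = Inf) {
  clip_trace((1 - eta) * E + eta * outer(rho_post, rho_pre), clip)
}

#' Oja trace update
#'
#' `E' = (1 - eta) E + eta * outer(r_post - E %*% r_pre, r_pre)`, clipped.
#' The `E %*% r_pre` term penalizes unbounded growth: in the scalar case with
#' constant rates and no clipping the iteration converges geometrically to
#' the fixed point `E* = r_post / r_pre`.
#'
#' @inheritParams linear_decay_update
#' @param r_post,r_pre spike-rate vectors in `[0, 1]`.
#' @export
oja_update <- function(E, eta, r_post, r_pre, clip = Inf) {
  clip_trace((1 - eta) * E + eta * outer(r_post - as.vector(E %*% r_pre), r_pre),
             clip)
}

#' BCM sliding-threshold update
#'
#' `phi' = (1 - eta_phi) phi + eta_phi * omega(r_pre)`: the threshold slowly
#' tracks pre-synaptic activity through the function `omega` (identity by
#' default).
#'
#' @param phi threshold trace `[n_pre]`.
#' @param eta_phi threshold incorporation rate in (0, 1).
#' @param r_pre pre-synaptic rate vector.
#' @param omega pre-activity function (default identity).
#' @export
bcm_threshold_update <- function(phi, eta_phi, r_pre, omega = identity) {
  (1 - eta_phi) * phi + eta_phi * omega(r_pre)
}

#' BCM trace update
#'
#' Potentiation vs. depression is gated by the sliding boundary
#' `phi + psi`: `r_beta = r_pre * (r_pre - (phi + psi))` and
#' `E' = (1 - eta) E + eta * outer(r_post, r_beta)`, clipped. Pre-synaptic
#' activity above the boundary potentiates (with the sign of `r_post`),
#' below depresses, and exactly on it leaves only the decay term.
#'
#' @inheritParams oja_update
#' @param phi dynamic threshold trace `[n_pre]`.
#' @param psi static threshold bias `[n_pre]`.
#' @export
bcm_update <- function(E, eta, r_post, r_pre, phi, psi, clip = Inf) {
  r_beta <- r_pre * (r_pre - (phi + psi))
  clip_trace((1 - eta) * E + eta * outer(r_post, r_beta), clip)
}

#' Learned neuromodulatory signal
#'
#' `M = W_m %*% r_post`: a square learned matrix linearly weights the
#' post-synaptic activity to produce one modulatory value per post neuron.
#'
#' @param W_m square modulatory matrix `[n_post, n_post]`.
#' @param r_post post-synaptic rate vector.
#' @export
modulatory_signal <- function(W_m, r_post) {
  W_m <- as.matrix(W_m)
  if (nrow(W_m) != ncol(W_m) || ncol(W_m) != length(r_post)) {
    stop_validation("W_m must be square with side length(r_post)")
  }
  as.vector(W_m %*% r_post)
}

#' Neuromodulated Oja update
#'
#' Oja's rule with the post-synaptic term gated by a modulatory signal:
#' `E' = (1 - eta) E + eta * outer(M * r_post - E %*% r_pre, r_pre)`,
#' clipped. With `M = 1` everywhere this is exactly [oja_update()].
#'
#' @inheritParams oja_update
#' @param M modulatory signal `[n_post]` (see [modulatory_signal()]).
#' @export
ndp_oja_update <- function(E, eta, r_post, r_pre, M, clip = Inf) {
  if (length(M) != length(r_post)) stop_validation("length(M) must equal length(r_post)")
  clip_trace((1 - eta) * E +
               eta * outer(M * r_post - as.vector(E %*% r_pre), r_pre), clip)
}

#' Neuromodulated BCM update
#'
#' BCM with the post-synaptic term gated by a modulatory signal:
#' `E' = (1 - eta) E + eta * outer(M * r_post, r_beta)`, clipped, with
#' `r_beta` as in [bcm_update()]. With `M = 1` everywhere this is exactly
#' [bcm_update()].
#'
#' @inheritParams bcm_update
#' @param M modulatory signal `[n_post]`.
#' @export
ndp_bcm_update <- function(E, eta, r_post, r_pre, phi, psi, M, clip = Inf) {
  if (length(M) != length(r_post)) stop_validation("length(M) must equal length(r_post)")
  r_beta <- r_pre * (r_pre - (phi + psi))
  clip_trace((1 - eta) * E + eta * outer(M * r_post, r_beta), clip)
}

RULE_NAMES <- c("none", "dp_linear", "dp_oja", "dp_bcm", "ndp_oja", "ndp_bcm")

#' Plasticity rule specification
#'
#' Bundles a rule choice with its structural hyperparameters. Rate-based
#' rules (Oja/BCM families) update traces every `delta_tau` steps from spike
#' averages over a tumbling window; the linear-decay rule updates every step
#' from instantaneous spikes. The incorporation rates `eta` and `eta_phi`
#' are stored as unconstrained parameters and squashed through a sigmoid into
#' (0, 1), where the `(1 - eta)` memory term is a stable convex blend.
#'
#' @param name one of `"none"`, `"dp_linear"`, `"dp_oja"`, `"dp_bcm"`,
#'   `"ndp_oja"`, `"ndp_bcm"`.
#' @param delta_tau trace-update interval in steps; defaults to 10 for
#'   rate-based rules and 1 for linear decay.
#' @param clip elementwise trace bound `C` (default 2).
#' @param eta_init,eta_phi_init initial incorporation rates (on the (0,1)
#'   scale; stored through the inverse sigmoid).
#' @param omega pre-activity function for BCM thresholds (identity only, by
#'   registry).
#' @export
plasticity_rule <- function(name = RULE_NAMES, delta_tau = NULL, clip = 2,
                            eta_init = 0.1, eta_phi_init = 0.1,
                            omega = "identity") {
  name <- match.arg(name)
  if (!identical(omega, "identity")) {
    stop_config("omega registry currently holds only 'identity'")
  }
  if (is.null(delta_tau)) delta_tau <- if (name == "dp_linear") 1L else 10L
  if (eta_init <= 0 || eta_init >= 1) stop_config("eta_init must be in (0, 1)")
  structure(list(name = name, delta_tau = as.integer(delta_tau), clip = clip,
                 eta_init = eta_init, eta_phi_init = eta_phi_init,
                 omega = omega,
                 is_bcm = name %in% c("dp_bcm", "ndp_bcm"),
                 is_ndp = name %in% c("ndp_oja", "ndp_bcm")),
            class = "plasticity_rule")
}
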