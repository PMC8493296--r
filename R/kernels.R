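#' Spike-response kernel specification
#'
#' Discrete-time spike-response-model kernels: the post-synaptic kernel
#' `epsilon` turns incoming binary spikes into a decaying spike-response
#' signal, and the refractory kernel `nu` hyperpolarizes a neuron after its
#' own spikes. Both are exponentials truncated exactly at `K` taps, the point
#' past which their contribution is treated as zero.
#'
#' @param tau_s time constant of `epsilon` in steps; must be positive.
#' @param tau_r time constant of `nu` in steps; must be positive.
#' @param K truncation length in steps (`K >= 1`); taps beyond `K` are zero.
#' @param eps_amp amplitude of `epsilon` at lag zero (default 1).
#' @param nu_amp amplitude of the refractory kernel in units of the firing
#'   threshold; the network multiplies `nu` taps by `theta`. Set to 0 to
#'   disable the refractory effect.
#' @return an object of class `kernel_spec`.
#' @seealso [eval_kernel()], [spike_response()]
#' @export
kernel_spec <- function(tau_s = 2, tau_r = 2, K = 8L, eps_amp = 1, nu_amp = 1) {
  if (!is.numeric(tau_s) || tau_s <= 0) stop_config("tau_s must be > 0")
  if (!is.numeric(tau_r) || tau_r <= 0) stop_config("tau_r must be > 0")
  if (!is.numeric(K) || K < 1) stop_config("K must be >= 1")
  structure(list(tau_s = tau_s, tau_r = tau_r, K = as.integer(K),
                 eps_amp = eps_amp, nu_amp = nu_amp, dt = 1L),
            class = "kernel_spec")
}

#' Evaluate the discrete kernel taps
#'
#' Returns the `K` taps of the requested kernel at lags `0, 1, ..., K - 1`.
#' `epsilon` taps are non-negative and decreasing; `nu` taps are non-positive
#' (hyperpolarizing) and increase toward zero.
#'
#' @param spec a [kernel_spec()].
#' @param which `"epsilon"` (spike-response) or `"nu"` (refractory).
#' @return numeric vector of length `spec$K`.
#' @examples
#' eval_kernel(kernel_spec(tau_s = 2, K = 3), "epsilon")
#' @export
eval_kernel <- function(spec, which = c("epsilon", "nu")) {
  which <- match.arg(which)
  t <- seq_len(spec$K) - 1
  if (which == "epsilon") spec$eps_amp * exp(-t / spec$tau_s)
  else -spec$nu_amp * exp(-t / spec$tau_r)
}

#' Filter a spike train through the spike-response kernel
#'
#' Computes the truncated causal convolution
#' `a[t, j] = sum_{k=0}^{K-1} epsilon[k] * spikes[t - k, j]`
#' with zero padding before the first step. The operation is linear in its
#' input, and spikes older than `K` steps contribute exactly zero.
#'
#' @param spikes binary matrix `[time, n_neurons]` (a vector is treated as a
#'   single-neuron train).
#' @param spec a [kernel_spec()].
#' @param which which kernel to apply (the refractory kernel uses the same
#'   convolution with its own taps).
#' @return numeric matrix `[time, n_neurons]`.
#' @export
spike_response <- function(spikes, spec, which = "epsilon") {
  if (is.vector(spikes)) spikes <- matrix(spikes, ncol = 1L)
  assert_binary(spikes, "spike train")
  taps <- eval_kernel(spec, which)
  T_len <- nrow(spikes)
  out <- matrix(0, T_len, ncol(spikes))
  for (k in seq_along(taps)) {
    lag <- k - 1L
    if (lag >= T_len) break
    rows <- seq_len(T_len - lag)
    out[rows + lag, ] <- out[rows + lag, ] + taps[k] * spikes[rows, , drop = FALSE]
  }
  out
}

#' Plastic membrane potential
#'
#' One step of the plastic membrane equation
#' `u = (W + alpha * E) %*% a + refr`, where `*` is the elementwise
#' (Hadamard) product. With `alpha = 0` or `E = 0` this reduces to the
#' fixed-weight membrane update `u = W %*% a + refr`.
#'
#' @param W fixed weights `[n_post, n_pre]`.
#' @param alpha plasticity coefficients, same shape as `W`.
#' @param E synaptic trace, same shape as `W`.
#' @param a pre-synaptic spike-response vector `[n_pre]`.
#' @param refr refractory response vector `[n_post]`.
#' @return membrane potential vector `[n_post]`.
#' @export
membrane_update <- function(W, alpha, E, a, refr) {
  W <- as.matrix(W); alpha <- as.matrix(alpha); E <- as.matrix(E)
  if (!all(dim(alpha) == dim(W)) || !all(dim(E) == dim(W))) {
    stop_validation("W, alpha and E must share dimensions")
  }
  if (length(a) != ncol(W)) stop_validation("length(a) must equal ncol(W)")
  if (length(refr) != nrow(W)) stop_validation("length(refr) must equal nrow(W)")
  as.vector((W + alpha * E) %*% a) + refr
}
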