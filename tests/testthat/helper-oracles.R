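# Independent reference implementations used as oracles: explicit
# per-element loops, direct convolutions and finite differences, kept free
# of the package's vectorized code paths.

loop_linear_decay <- function(E, eta, rho_post, rho_pre, clip = Inf) {
  out <- E
  for (i in seq_along(rho_post)) {
    for (j in seq_along(rho_pre)) {
      v <- (1 - eta) * E[i, j] + eta * rho_post[i] * rho_pre[j]
      out[i, j] <- min(max(v, -clip), clip)
    }
  }
  out
}

loop_oja <- function(E, eta, r_post, r_pre, clip = Inf) {
  out <- E
  for (i in seq_along(r_post)) {
    er <- 0
    for (j in seq_along(r_pre)) er <- er + E[i, j] * r_pre[j]
    for (j in seq_along(r_pre)) {
      v <- (1 - eta) * E[i, j] + eta * (r_post[i] - er) * r_pre[j]
      out[i, j] <- min(max(v, -clip), clip)
    }
  }
  out
}

loop_bcm <- function(E, eta, r_post, r_pre, phi, psi, clip = Inf) {
  out <- E
  for (i in seq_along(r_post)) {
    for (j in seq_along(r_pre)) {
      rb <- r_pre[j] * (r_pre[j] - (phi[j] + psi[j]))
      v <- (1 - eta) * E[i, j] + eta * r_post[i] * rb
      out[i, j] <- min(max(v, -clip), clip)
    }
  }
  out
}

loop_ndp_oja <- function(E, eta, r_post, r_pre, M, clip = Inf) {
  out <- E
  for (i in seq_along(r_post)) {
    er <- 0
    for (j in seq_along(r_pre)) er <- er + E[i, j] * r_pre[j]
    for (j in seq_along(r_pre)) {
      v <- (1 - eta) * E[i, j] + eta * (M[i] * r_post[i] - er) * r_pre[j]
      out[i, j] <- min(max(v, -clip), clip)
    }
  }
  out
}

loop_ndp_bcm <- function(E, eta, r_post, r_pre, phi, psi, M, clip = Inf) {
  out <- E
  for (i in seq_along(r_post)) {
    for (j in seq_along(r_pre)) {
      rb <- r_pre[j] * (r_pre[j] - (phi[j] + psi[j]))
      v <- (1 - eta) * E[i, j] + eta * M[i] * r_post[i] * rb
      out[i, j] <- min(max(v, -clip), clip)
    }
  }
  out
}

# direct double-loop causal convolution of a spike train with kernel taps
loop_convolve <- function(spikes, taps) {
  T_len <- nrow(spikes)
  out <- matrix(0, T_len, ncol(spikes))
  for (t in seq_len(T_len)) {
    for (k in seq_along(taps)) {
      tp <- t - (k - 1)
      if (tp >= 1) out[t, ] <- out[t, ] + taps[k] * spikes[tp, ]
    }
  }
  out
}

# central finite difference of f at x (scalar coordinate bumps)
central_fd <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# small random plastic network shared by gradient tests
make_tiny_net <- function(rule, seed = 3, sizes = c(3, 3, 2)) {
  net <- snn_network(sizes, rule, kernel = kernel_spec(K = 4), seed = seed)
  for (l in seq_len(length(sizes) - 1)) {
    nm <- paste0("W", l)
    net$params[[nm]] <- net$params[[nm]] + 0.5
  }
  net$rule$delta_tau <- if (rule == "dp_linear") 1L else 3L
  net
}
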