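# Feedforward plastic SNN: construction and differentiable unrolling.
#
# Dynamics per layer l and step t (stateless-kernel formulation; membrane
# potential is recomputed from bounded spike buffers every step so the BPTT
# graph depth per potential is bounded by K):
#   a(t)    = sum_{k=0}^{K-1} eps[k] s_pre(t - k)         (spike response)
#   refr(t) = sum_{m=1}^{K}   theta * nu[m-1] s_l(t - m)  (own past spikes)
#   u(t)    = (W + alpha * E(t)) a(t) + refr(t)
#   s(t)    = 1[u(t) >= theta]
# The refractory kernel acts on spikes strictly before t (a spike at t - 1
# contributes the lag-0 tap), which implements reset-by-overwrite: nu's
# leading tap is -theta. Traces E update every delta_tau steps from spike
# averages over the elapsed window (every step, from instantaneous spikes,
# for the linear-decay rule) and apply from the next step onward.

#' Construct a feedforward plastic spiking network
#'
#' Builds layer weights, plasticity coefficients and rule parameters for a
#' fully connected feedforward SRM network. All feedforward layers share the
#' rule and are plastic (unless `rule = "none"`).
#'
#' Initialization: `W ~ N(0, (w_scale / sqrt(n_pre))^2)`,
#' `alpha ~ U(-0.01, 0.01)`, `psi = 0`, `W_m ~ U(-0.1, 0.1) / n_post`, and
#' incorporation rates start at `eta_init` via the sigmoid
#' reparameterization. Small-magnitude plastic starts keep early dynamics
#' near the fixed-weight regime.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param rule a rule name or [plasticity_rule()] object.
#' @param kernel a [kernel_spec()].
#' @param neuron a [neuron_config()].
#' @param surrogate a [surrogate_spec()].
#' @param seed integer seed for parameter initialization (drawn from the
#'   `"init"` sub-stream).
#' @param w_scale weight-initialization gain.
#' @param alpha_init half-width of the uniform initialization of the
#'   plasticity coefficients.
#' @param wm_scale half-width (before the `1 / n_post` normalization) of the
#'   uniform initialization of the modulatory matrix.
#' @param symmetric_output initialize all output-layer weight rows
#'   identically. A competitive decision head (e.g. the binomial head on the
#'   count difference of two output neurons) then starts exactly unbiased:
#'   with random rows the initial count difference can sit deep in the
#'   saturated tail of the logistic, where policy gradients vanish and
#'   training freezes. With identical rows the difference starts at zero —
#'   maximum gradient — and is broken by the (row-asymmetric) plasticity
#'   coefficients and modulatory weights.
#' @return an object of class `plastic_snn`.
#' @export
snn_network <- function(sizes, rule = "none", kernel = kernel_spec(),
                        neuron = neuron_config(), surrogate = surrogate_spec(),
                        seed = 1L, w_scale = 1.5, alpha_init = 0.01,
                        wm_scale = 0.1, symmetric_output = FALSE) {
  if (length(sizes) < 2L) stop_config("need at least input and output layers")
  if (is.character(rule)) rule <- plasticity_rule(rule)
  L <- length(sizes) - 1L
  plastic <- rule$name != "none"
  params <- list()
  with_seed(substream_seed(seed, "init"), {
    for (l in seq_len(L)) {
      P <- sizes[l + 1L]; Q <- sizes[l]
      W0 <- matrix(rnorm(P * Q, sd = w_scale / sqrt(Q)), P, Q)
      if (symmetric_output && l == L) {
        W0 <- matrix(W0[1L, ], P, Q, byrow = TRUE)
      }
      params[[paste0("W", l)]] <- W0
      if (plastic) {
        params[[paste0("alpha", l)]] <- matrix(runif(P * Q, -alpha_init, alpha_init), P, Q)
        params[[paste0("eta_raw", l)]] <- qlogis(rule$eta_init)
        if (rule$is_bcm) {
          params[[paste0("psi", l)]] <- numeric(Q)
          params[[paste0("eta_phi_raw", l)]] <- qlogis(rule$eta_phi_init)
        }
        if (rule$is_ndp) {
          params[[paste0("Wm", l)]] <- matrix(runif(P * P, -wm_scale, wm_scale) / P, P, P)
        }
      }
    }
  })
  structure(list(sizes = as.integer(sizes), rule = rule, kernel = kernel,
                 neuron = neuron, surrogate = surrogate, params = params,
                 init = list(w_scale = w_scale, alpha_init = alpha_init,
                             wm_scale = wm_scale,
                             symmetric_output = symmetric_output)),
            class = "plastic_snn")
}

#' @export
print.plastic_snn <- function(x, ...) {
  cat("<plastic_snn> layers", paste(x$sizes, collapse = "-"),
      "| rule:", x$rule$name,
      "| K =", x$kernel$K,
      "| delta_tau =", x$rule$delta_tau, "\n")
  invisible(x)
}

# Shared forward pass over a batch of same-length episodes.
# input: [B, T, n_in] binary array. Returns handles (taped) or values (raw).
# Dispatches to the chunk-fused path (one node per layer per rate window)
# whenever the chunk precondition holds and no per-step records are asked
# for; the per-step path below is the reference implementation.
snn_forward <- function(net, input, params = net$params, gradient = FALSE,
                        mode = c("spike", "smooth"), record_states = FALSE,
                        record_traces = FALSE, chunked = NULL) {
  mode <- match.arg(mode)
  if (!is.double(input)) storage.mode(input) <- "double"
  if (is.null(chunked)) {
    chunked <- !record_states && !record_traces &&
      net$surrogate$shape == "exp" &&
      (net$rule$name == "none" ||
         net$rule$delta_tau >= max(2L, net$kernel$K))
  }
  if (chunked) {
    return(snn_forward_chunked(net, input, params = params,
                               gradient = gradient, mode = mode))
  }
  snn_forward_stepwise(net, input, params = params, gradient = gradient,
                       mode = mode, record_states = record_states,
                       record_traces = record_traces)
}

snn_forward_stepwise <- function(net, input, params = net$params,
                                 gradient = FALSE,
                                 mode = c("spike", "smooth"),
                                 record_states = FALSE,
                                 record_traces = FALSE) {
  mode <- match.arg(mode)
  if (length(dim(input)) != 3L) stop_validation("input must be [batch, time, neurons]")
  B <- dim(input)[1L]; T_len <- dim(input)[2L]
  if (dim(input)[3L] != net$sizes[1L]) {
    stop_validation("input width ", dim(input)[3L], " does not match network input size ",
                    net$sizes[1L])
  }
  o <- if (gradient) ad_ops() else raw_ops()
  tp <- if (gradient) ad_tape(8192L) else NULL

  sizes <- net$sizes
  L <- length(sizes) - 1L
  rule <- net$rule
  plastic <- rule$name != "none"
  dtau <- rule$delta_tau
  K <- net$kernel$K
  eps <- eval_kernel(net$kernel, "epsilon")
  nu <- eval_kernel(net$kernel, "nu") * net$neuron$theta

  ph <- lapply(params, function(x) o$param(tp, x))
  sh <- lapply(seq_len(L), function(l) batch_shape(B, sizes[l + 1L], sizes[l]))

  # per-layer rule scalars, computed once
  if (plastic) {
    eta <- lapply(seq_len(L), function(l) o$sigmoid(tp, ph[[paste0("eta_raw", l)]]))
    m_eta <- lapply(eta, function(e) o$one_minus(tp, e))
    if (rule$is_bcm) {
      eta_phi <- lapply(seq_len(L), function(l)
        o$sigmoid(tp, ph[[paste0("eta_phi_raw", l)]]))
      m_eta_phi <- lapply(eta_phi, function(e) o$one_minus(tp, e))
    }
  }

  spk <- vector("list", L + 1L)
  for (l in seq_len(L + 1L)) spk[[l]] <- vector("list", T_len)
  E <- vector("list", L); alphaE <- vector("list", L); phi <- vector("list", L)
  if (plastic) {
    for (l in seq_len(L)) {
      E[[l]] <- o$const(tp, matrix(0, B * sizes[l + 1L], sizes[l]))
      alphaE[[l]] <- o$bscale(tp, E[[l]], ph[[paste0("alpha", l)]], sh[[l]])
      if (rule$is_bcm) phi[[l]] <- o$const(tp, matrix(0, B, sizes[l]))
    }
  }

  states <- if (record_states)
    lapply(seq_len(L), function(l) list(a = vector("list", T_len),
                                        u = vector("list", T_len),
                                        refr = vector("list", T_len)))
  traces <- if (record_traces)
    lapply(seq_len(L), function(l) list(E = list(), phi = list(), t = integer()))

  update_trace <- function(l, t) {
    # spike averages over the window ending at t
    win <- (t - dtau + 1L):t
    r_pre <- if (dtau == 1L) spk[[l]][[t]] else
      op_wsum(o, tp, spk[[l]][win], rep(1 / dtau, dtau))
    r_post <- if (dtau == 1L) spk[[l + 1L]][[t]] else
      op_wsum(o, tp, spk[[l + 1L]][win], rep(1 / dtau, dtau))
    post_term <- r_post
    if (rule$is_ndp) {
      M <- o$tmatmul(tp, r_post, ph[[paste0("Wm", l)]])
      post_term <- o$mul(tp, M, r_post)
    }
    inc <- switch(rule$name,
      dp_linear = o$bouter(tp, post_term, r_pre, sh[[l]]),
      dp_oja = ,
      ndp_oja = {
        Er <- o$bmm(tp, E[[l]], r_pre, sh[[l]])
        o$bouter(tp, o$sub(tp, post_term, Er), r_pre, sh[[l]])
      },
      dp_bcm = ,
      ndp_bcm = {
        thr <- o$add_rvec(tp, phi[[l]], ph[[paste0("psi", l)]])
        r_beta <- o$mul(tp, r_pre, o$sub(tp, r_pre, thr))
        o$bouter(tp, post_term, r_beta, sh[[l]])
      })
    Enew <- o$add(tp, o$smul(tp, m_eta[[l]], E[[l]]), o$smul(tp, eta[[l]], inc))
    E[[l]] <<- o$clamp(tp, Enew, -rule$clip, rule$clip)
    alphaE[[l]] <<- o$bscale(tp, E[[l]], ph[[paste0("alpha", l)]], sh[[l]])
    if (rule$is_bcm) {
      phi[[l]] <<- o$add(tp, o$smul(tp, m_eta_phi[[l]], phi[[l]]),
                         o$smul(tp, eta_phi[[l]], r_pre))
    }
    if (record_traces) {
      traces[[l]]$E[[length(traces[[l]]$E) + 1L]] <<- o$val(tp, E[[l]])
      if (rule$is_bcm)
        traces[[l]]$phi[[length(traces[[l]]$phi) + 1L]] <<- o$val(tp, phi[[l]])
      traces[[l]]$t <<- c(traces[[l]]$t, t)
    }
  }

  for (t in seq_len(T_len)) {
    x <- input[, t, , drop = FALSE]
    dim(x) <- c(B, sizes[1L])
    spk[[1L]][[t]] <- o$const(tp, x)
    for (l in seq_len(L)) {
      kk <- 0:(min(K, t) - 1L) # available epsilon lags
      mm <- if (t > 1L) 1:min(K, t - 1L) else integer(0) # refractory lags
      if (!record_states) {
        # fused layer step keeps the tape short in the training loop
        spk[[l + 1L]][[t]] <- o$step_spike(
          tp, spk[[l]][t - kk], eps[kk + 1L], spk[[l + 1L]][t - mm], nu[mm],
          ph[[paste0("W", l)]], if (plastic) alphaE[[l]] else NULL,
          sh[[l]], net$neuron, net$surrogate, mode)
      } else {
        a <- op_wsum(o, tp, spk[[l]][t - kk], eps[kk + 1L])
        u <- o$tmatmul(tp, a, ph[[paste0("W", l)]])
        if (plastic) u <- o$add(tp, u, o$bmm(tp, alphaE[[l]], a, sh[[l]]))
        refr <- NULL
        if (length(mm)) {
          refr <- op_wsum(o, tp, spk[[l + 1L]][t - mm], nu[mm])
          u <- o$add(tp, u, refr)
        }
        spk[[l + 1L]][[t]] <- o$spike(tp, u, net$neuron, net$surrogate, mode)
        states[[l]]$a[[t]] <- o$val(tp, a)
        states[[l]]$u[[t]] <- o$val(tp, u)
        states[[l]]$refr[[t]] <- if (is.null(refr)) matrix(0, B, sizes[l + 1L])
                                 else o$val(tp, refr)
      }
    }
    if (plastic && t %% dtau == 0L) {
      for (l in seq_len(L)) update_trace(l, t)
    }
  }

  list(o = o, tp = tp, ph = ph, sh = sh, spk = spk, E = E, phi = phi,
       states = states, traces = traces, B = B, T_len = T_len, net = net,
       mode = mode)
}

# Values of one layer's spikes as a [B, T, n] array (layer 0 = input).
fw_spikes <- function(fw, layer) {
  if (isTRUE(fw$chunked)) return(fw_spikes_chunked(fw, layer))
  hs <- fw$spk[[layer + 1L]]
  n <- fw$net$sizes[layer + 1L]
  out <- array(0, c(fw$B, fw$T_len, n))
  for (t in seq_len(fw$T_len)) out[, t, ] <- fw$o$val(fw$tp, hs[[t]])
  out
}

#' Unroll a plastic network over one input episode
#'
#' Runs the full differentiable dynamics on a single episode: spike-response
#' filtering, plastic membrane updates, thresholding, refractory feedback and
#' periodic trace updates (traces reset at the start of the call). Returns
#' the complete per-step record.
#'
#' @param net a [snn_network()].
#' @param input binary spike matrix `[time, n_in]`.
#' @param mode `"spike"` for exact binary dynamics; `"smooth"` replaces the
#'   threshold with the smooth surrogate primitive (used for gradient
#'   checking).
#' @return list with `output` (binary `[time, n_out]`), `spikes` (per layer),
#'   `states` (per layer time series of `a`, `u`, `refr`) and `traces` (per
#'   layer series of `E`, `phi` and update times).
#' @export
unroll_episode <- function(net, input, mode = "spike") {
  input <- as.matrix(input)
  arr <- array(0, c(1L, nrow(input), ncol(input)))
  arr[1L, , ] <- input
  fw <- snn_forward(net, arr, mode = mode, record_states = TRUE,
                    record_traces = TRUE)
  L <- length(net$sizes) - 1L
  squeeze <- function(lst) do.call(rbind, lapply(lst, function(m) as.vector(m)))
  spikes <- lapply(0:L, function(l) {
    m <- fw_spikes(fw, l)[1L, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    m
  })
  states <- if (!is.null(fw$states))
    lapply(fw$states, function(s) list(a = squeeze(s$a), u = squeeze(s$u),
                                       refr = squeeze(s$refr)))
  traces <- lapply(seq_len(L), function(l) {
    tr <- fw$traces[[l]]
    P <- net$sizes[l + 1L]; Q <- net$sizes[l]
    Es <- lapply(tr$E, function(e) matrix(e, P, Q))
    phis <- lapply(tr$phi, function(p) as.vector(p))
    list(E = Es, phi = phis, t = tr$t)
  })
  list(output = spikes[[L + 1L]], spikes = spikes, states = states,
       traces = traces)
}

#' Fixed-weight reference forward pass
#'
#' Independent implementation of the non-plastic SRM dynamics: each layer's
#' spike response is computed by whole-train convolution through
#' [spike_response()], then membrane potentials and spikes are stepped in
#' time with the refractory kernel on the layer's own past spikes. Used as
#' the reduction oracle for the unrolled network with plasticity disabled.
#'
#' @param net a [snn_network()] (its rule is ignored; only `W` is used).
#' @param input binary spike matrix `[time, n_in]`.
#' @return list of per-layer binary spike matrices, input first.
#' @export
snn_forward_fixed <- function(net, input) {
  input <- as.matrix(input)
  sizes <- net$sizes
  L <- length(sizes) - 1L
  K <- net$kernel$K
  nu <- eval_kernel(net$kernel, "nu") * net$neuron$theta
  theta <- net$neuron$theta
  spikes <- vector("list", L + 1L)
  spikes[[1L]] <- input
  T_len <- nrow(input)
  for (l in seq_len(L)) {
    W <- net$params[[paste0("W", l)]]
    a_full <- spike_response(spikes[[l]], net$kernel)
    s <- matrix(0, T_len, sizes[l + 1L])
    for (t in seq_len(T_len)) {
      u <- as.vector(W %*% a_full[t, ])
      if (t > 1L) {
        for (m in 1:min(K, t - 1L)) u <- u + nu[m] * s[t - m, ]
      }
      s[t, ] <- (u >= theta) * 1
    }
    spikes[[l + 1L]] <- s
  }
  spikes
}

#' Stateful stepping controller for continuous-control use
#'
#' Wraps a network in an object that consumes input spike chunks (one
#' integration interval at a time) while carrying membrane buffers, traces
#' and rate windows across chunks, so an episode can be driven step by step
#' by an environment loop. Chunked stepping is exactly equivalent to a
#' single [snn_forward()] call on the concatenated input.
#'
#' @param net a [snn_network()].
#' @param params optional parameter override.
#' @return object with `$step(spikes)` (binary `[steps, n_in]` in, binary
#'   `[steps, n_out]` out), `$reset()`, and `$hidden_rate()` (mean hidden
#'   spikes per neuron per step since reset).
#' @export
snn_controller <- function(net, params = net$params) {
  sizes <- net$sizes
  L <- length(sizes) - 1L
  rule <- net$rule
  plastic <- rule$name != "none"
  K <- net$kernel$K
  eps <- eval_kernel(net$kernel, "epsilon")
  nu <- eval_kernel(net$kernel, "nu") * net$neuron$theta
  theta <- net$neuron$theta
  dtau <- rule$delta_tau

  st <- new.env(parent = emptyenv())
  reset <- function() {
    st$hist <- lapply(seq_len(L + 1L), function(l) matrix(0, K, sizes[l]))
    st$E <- lapply(seq_len(L), function(l) matrix(0, sizes[l + 1L], sizes[l]))
    st$phi <- lapply(seq_len(L), function(l) numeric(sizes[l]))
    st$acc <- lapply(seq_len(L + 1L), function(l) numeric(sizes[l]))
    st$in_window <- 0L
    st$t <- 0L
    st$hidden_spikes <- 0
    st$hidden_steps <- 0L
    invisible(NULL)
  }
  reset()

  eta <- if (plastic) lapply(seq_len(L), function(l)
    plogis(params[[paste0("eta_raw", l)]]))
  eta_phi <- if (plastic && rule$is_bcm) lapply(seq_len(L), function(l)
    plogis(params[[paste0("eta_phi_raw", l)]]))

  step <- function(spikes_in) {
    spikes_in <- as.matrix(spikes_in)
    if (ncol(spikes_in) != sizes[1L]) stop_validation("input width mismatch")
    out <- matrix(0, nrow(spikes_in), sizes[L + 1L])
    for (row in seq_len(nrow(spikes_in))) {
      st$t <- st$t + 1L
      new_spk <- vector("list", L + 1L)
      new_spk[[1L]] <- spikes_in[row, ]
      for (l in seq_len(L)) {
        hist_pre <- st$hist[[l]]
        a <- eps[1L] * new_spk[[l]]
        if (K > 1L) for (k in 2:K) a <- a + eps[k] * hist_pre[k - 1L, ]
        W <- params[[paste0("W", l)]]
        u <- as.vector(W %*% a)
        if (plastic) {
          u <- u + as.vector((params[[paste0("alpha", l)]] * st$E[[l]]) %*% a)
        }
        hist_self <- st$hist[[l + 1L]]
        for (m in 1:K) u <- u + nu[m] * hist_self[m, ]
        new_spk[[l + 1L]] <- (u >= theta) * 1
      }
      for (l in seq_len(L + 1L)) {
        h <- st$hist[[l]]
        st$hist[[l]] <- rbind(new_spk[[l]], h[-K, , drop = FALSE])
        st$acc[[l]] <- st$acc[[l]] + new_spk[[l]]
      }
      if (L > 1L) {
        st$hidden_spikes <- st$hidden_spikes +
          sum(unlist(new_spk[2:L]))
        st$hidden_steps <- st$hidden_steps + sum(sizes[2:L])
      }
      st$in_window <- st$in_window + 1L
      if (plastic && st$in_window == dtau) {
        for (l in seq_len(L)) {
          r_pre <- st$acc[[l]] / dtau
          r_post <- st$acc[[l + 1L]] / dtau
          e <- eta[[l]]
          st$E[[l]] <- switch(rule$name,
            dp_linear = linear_decay_update(st$E[[l]], e, r_post, r_pre, rule$clip),
            dp_oja = oja_update(st$E[[l]], e, r_post, r_pre, rule$clip),
            ndp_oja = ndp_oja_update(st$E[[l]], e, r_post, r_pre,
              modulatory_signal(params[[paste0("Wm", l)]], r_post), rule$clip),
            dp_bcm = bcm_update(st$E[[l]], e, r_post, r_pre, st$phi[[l]],
              params[[paste0("psi", l)]], rule$clip),
            ndp_bcm = ndp_bcm_update(st$E[[l]], e, r_post, r_pre, st$phi[[l]],
              params[[paste0("psi", l)]],
              modulatory_signal(params[[paste0("Wm", l)]], r_post), rule$clip))
          if (rule$is_bcm) {
            st$phi[[l]] <- bcm_threshold_update(st$phi[[l]], eta_phi[[l]], r_pre)
          }
        }
        for (l in seq_len(L + 1L)) st$acc[[l]][] <- 0
        st$in_window <- 0L
      }
      out[row, ] <- new_spk[[L + 1L]]
    }
    out
  }

  hidden_rate <- function() {
    if (st$hidden_steps == 0L) 0 else st$hidden_spikes / st$hidden_steps
  }

  structure(list(step = step, reset = reset, hidden_rate = hidden_rate,
                 state = st, net = net),
            class = "snn_controller")
}
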