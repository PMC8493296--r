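# Chunk-fused forward pass.
#
# The per-step tape is exact but carries one node per layer per time step.
# Because the trace matrices only change at rate-window boundaries, the
# dynamics between two boundaries form a block whose forward and backward
# passes can be computed in one go: this path emits one tape node per layer
# per chunk (chunk length = the trace-update interval delta_tau, plus a
# short tail), stores the within-chunk intermediates in the node closure,
# and walks the in-chunk time loop backward inside the pullback. The plastic
# membrane term and its adjoints become one small BLAS product per episode
# per chunk. Results are identical to the per-step path (tested), which
# remains the reference implementation and the only path that records
# per-step state buffers.
#
# Chunk nodes hold binary spikes as [B, S, n] arrays. A consumer chunk needs
# at most the last K steps of the previous chunk (refractory lags run to K),
# so the path requires delta_tau >= K and falls back to the per-step path
# otherwise.

chunk_plan <- function(T_len, dtau) {
  starts <- seq(1L, T_len, by = dtau)
  ends <- pmin(starts + dtau - 1L, T_len)
  list(starts = starts, ends = ends, n = length(starts))
}

# One layer-chunk: steps t0..t1 of layer l given the pre-layer chunk (and
# tails of the previous pre/own chunks), emitting [B, S, P] spikes.
ops_chunk_step <- function(taped) {
  if (taped) {
    function(tp, pre_cur, pre_hist, own_hist, W, alphaE, sh, eps, nu, cfg,
             sur, mode, ep_rows) {
      force(pre_cur); force(pre_hist); force(own_hist)
      force(W); force(alphaE)
      force(sh); force(eps); force(nu); force(cfg); force(sur); force(ep_rows)
      K <- length(eps)
      pv <- tp$v[[as.character(pre_cur)]]
      ph_v <- if (!is.null(pre_hist)) tp$v[[as.character(pre_hist)]]
      oh_v <- if (!is.null(own_hist)) tp$v[[as.character(own_hist)]]
      Wv <- tp$v[[as.character(W)]]
      AEv <- if (!is.null(alphaE)) tp$v[[as.character(alphaE)]]
      fwd <- chunk_forward(pv, ph_v, oh_v, Wv, AEv, sh, eps, nu, cfg, sur,
                           mode, ep_rows)
      parents <- c(pre_cur, pre_hist, own_hist, W, alphaE)
      has_ph <- !is.null(pre_hist); has_oh <- !is.null(own_hist)
      plastic <- !is.null(alphaE)
      ad_emit(tp, fwd$s, parents, function(g) {
        bk <- chunk_backward(g, fwd, pv, ph_v, oh_v, Wv, AEv, sh, eps, nu,
                             ep_rows)
        out <- list(bk$d_pre_cur)
        if (has_ph) out <- c(out, list(bk$d_pre_hist))
        if (has_oh) out <- c(out, list(bk$d_own_hist))
        out <- c(out, list(bk$dW))
        if (plastic) out <- c(out, list(bk$dAE))
        out
      })
    }
  } else {
    function(tp, pre_cur, pre_hist, own_hist, W, alphaE, sh, eps, nu, cfg,
             sur, mode, ep_rows) {
      chunk_forward(pre_cur, pre_hist, own_hist, W, alphaE, sh, eps, nu,
                    cfg, sur, mode, ep_rows)$s
    }
  }
}

chunk_forward <- function(pv, ph_v, oh_v, Wv, AEv, sh, eps, nu, cfg, sur,
                          mode, ep_rows) {
  if (!is.double(pv)) storage.mode(pv) <- "double"
  dims <- c(sh$B, dim(pv)[2L],
            if (is.null(ph_v)) 0L else dim(ph_v)[2L],
            if (is.null(oh_v)) 0L else dim(oh_v)[2L],
            sh$P, sh$Q)
  res <- chunk_forward_cpp(pv, ph_v, oh_v, Wv, AEv, eps, nu, cfg$theta,
                           sur$scale, mode == "smooth", dims)
  res$dims <- dims
  res
}

chunk_backward <- function(g, fwd, pv, ph_v, oh_v, Wv, AEv, sh, eps, nu,
                           ep_rows) {
  chunk_backward_cpp(g, fwd$sg, fwd$A, Wv, AEv, eps, nu, fwd$dims)
}

# mean over the step dimension of a chunk node: [B, S, n] -> [B, n]
op_chunk_mean <- function(o, tp, h, S) {
  # force S now: the pullback closure is invoked long after the caller's
  # loop variables have moved on, so a lazy promise would read stale values
  force(S)
  if (o$taped) {
    force(h)
    xv <- tp$v[[as.character(h)]]
    v <- matrix(colMeans(aperm(xv, c(2L, 1L, 3L))), dim(xv)[1L], dim(xv)[3L])
    ad_emit(tp, v, h, function(g) {
      gg <- array(0, dim(xv))
      for (s in seq_len(S)) gg[, s, ] <- g / S
      list(gg)
    })
  } else {
    matrix(colMeans(aperm(h, c(2L, 1L, 3L))), dim(h)[1L], dim(h)[3L])
  }
}

# sum over a subset of steps of a chunk node: [B, S, n] -> [B, n]
op_chunk_count <- function(o, tp, h, steps) {
  force(steps)
  if (o$taped) {
    force(h)
    xv <- tp$v[[as.character(h)]]
    v <- matrix(0, dim(xv)[1L], dim(xv)[3L])
    for (s in steps) v <- v + matrix(xv[, s, ], dim(xv)[1L], dim(xv)[3L])
    ad_emit(tp, v, h, function(g) {
      gg <- array(0, dim(xv))
      for (s in steps) gg[, s, ] <- g
      list(gg)
    })
  } else {
    v <- matrix(0, dim(h)[1L], dim(h)[3L])
    for (s in steps) v <- v + matrix(h[, s, ], dim(h)[1L], dim(h)[3L])
    v
  }
}

# Chunked forward over a batch of episodes; same contract as snn_forward
# but spikes are held as per-chunk nodes. Requires delta_tau >= K - 1.
snn_forward_chunked <- function(net, input, params = net$params,
                                gradient = FALSE, mode = c("spike", "smooth")) {
  mode <- match.arg(mode)
  B <- dim(input)[1L]; T_len <- dim(input)[2L]
  if (dim(input)[3L] != net$sizes[1L]) {
    stop_validation("input width ", dim(input)[3L],
                    " does not match network input size ", net$sizes[1L])
  }
  o <- if (gradient) ad_ops() else raw_ops()
  tp <- if (gradient) ad_tape(2048L) else NULL
  sizes <- net$sizes
  L <- length(sizes) - 1L
  rule <- net$rule
  plastic <- rule$name != "none"
  dtau <- if (plastic) rule$delta_tau else max(net$kernel$K, 10L)
  eps <- eval_kernel(net$kernel, "epsilon")
  nu <- eval_kernel(net$kernel, "nu") * net$neuron$theta
  plan <- chunk_plan(T_len, dtau)
  step_op <- ops_chunk_step(gradient)

  ph <- lapply(params, function(x) o$param(tp, x))
  sh <- lapply(seq_len(L), function(l) batch_shape(B, sizes[l + 1L], sizes[l]))
  ep_rows <- lapply(seq_len(L), function(l)
    lapply(seq_len(B), function(b) b + B * (seq_len(sizes[l + 1L]) - 1L)))

  if (plastic) {
    eta <- lapply(seq_len(L), function(l) o$sigmoid(tp, ph[[paste0("eta_raw", l)]]))
    m_eta <- lapply(eta, function(e) o$one_minus(tp, e))
    if (rule$is_bcm) {
      eta_phi <- lapply(seq_len(L), function(l)
        o$sigmoid(tp, ph[[paste0("eta_phi_raw", l)]]))
      m_eta_phi <- lapply(eta_phi, function(e) o$one_minus(tp, e))
    }
  }
  E <- vector("list", L); alphaE <- vector("list", L); phi <- vector("list", L)
  if (plastic) {
    for (l in seq_len(L)) {
      E[[l]] <- o$const(tp, matrix(0, B * sizes[l + 1L], sizes[l]))
      alphaE[[l]] <- o$bscale(tp, E[[l]], ph[[paste0("alpha", l)]], sh[[l]])
      if (rule$is_bcm) phi[[l]] <- o$const(tp, matrix(0, B, sizes[l]))
    }
  }

  chunks <- lapply(seq_len(L + 1L), function(l) vector("list", plan$n))
  for (w in seq_len(plan$n)) {
    t0 <- plan$starts[w]; t1 <- plan$ends[w]
    xin <- input[, t0:t1, , drop = FALSE]
    chunks[[1L]][[w]] <- o$const(tp, xin)
    for (l in seq_len(L)) {
      chunks[[l + 1L]][[w]] <- step_op(
        tp, chunks[[l]][[w]],
        if (w > 1L) chunks[[l]][[w - 1L]],
        if (w > 1L) chunks[[l + 1L]][[w - 1L]],
        ph[[paste0("W", l)]], if (plastic) alphaE[[l]] else NULL,
        sh[[l]], eps, nu, net$neuron, net$surrogate, mode, ep_rows[[l]])
    }
    S <- t1 - t0 + 1L
    if (plastic && S == dtau) {
      for (l in seq_len(L)) {
        r_pre <- op_chunk_mean(o, tp, chunks[[l]][[w]], S)
        r_post <- op_chunk_mean(o, tp, chunks[[l + 1L]][[w]], S)
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
        Enew <- o$add(tp, o$smul(tp, m_eta[[l]], E[[l]]),
                      o$smul(tp, eta[[l]], inc))
        E[[l]] <- o$clamp(tp, Enew, -rule$clip, rule$clip)
        alphaE[[l]] <- o$bscale(tp, E[[l]], ph[[paste0("alpha", l)]], sh[[l]])
        if (rule$is_bcm) {
          phi[[l]] <- o$add(tp, o$smul(tp, m_eta_phi[[l]], phi[[l]]),
                            o$smul(tp, eta_phi[[l]], r_pre))
        }
      }
    }
  }

  fw <- list(o = o, tp = tp, ph = ph, sh = sh, chunks = chunks, plan = plan,
             E = E, phi = phi, B = B, T_len = T_len, net = net, mode = mode,
             chunked = TRUE)
  fw
}

# Sum of a layer's spikes over an arbitrary step window, as a handle.
fw_window_counts <- function(fw, layer, steps) {
  o <- fw$o; tp <- fw$tp
  if (is.null(fw$chunked)) {
    return(op_wsum(o, tp, fw$spk[[layer + 1L]][steps], rep(1, length(steps))))
  }
  plan <- fw$plan
  parts <- list()
  for (w in seq_len(plan$n)) {
    sel <- steps[steps >= plan$starts[w] & steps <= plan$ends[w]]
    if (length(sel)) {
      parts[[length(parts) + 1L]] <-
        op_chunk_count(o, tp, fw$chunks[[layer + 1L]][[w]],
                       sel - plan$starts[w] + 1L)
    }
  }
  if (length(parts) == 1L) parts[[1L]]
  else op_wsum(o, tp, parts, rep(1, length(parts)))
}

# Values of a layer's spikes from a chunked forward as [B, T, n].
fw_spikes_chunked <- function(fw, layer) {
  n <- fw$net$sizes[layer + 1L]
  out <- array(0, c(fw$B, fw$T_len, n))
  for (w in seq_len(fw$plan$n)) {
    v <- fw$o$val(fw$tp, fw$chunks[[layer + 1L]][[w]])
    out[, fw$plan$starts[w]:fw$plan$ends[w], ] <- v
  }
  out
}
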