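# Minimal reverse-mode automatic differentiation on a linear tape.
#
# The unrolled network is built from a small fixed set of array operations,
# so a general graph engine is unnecessary: every op appends one node (value,
# parent ids, pullback closure) to a tape, and the backward sweep walks the
# tape in reverse creation order, which is already a topological order.
#
# Ops come in two interchangeable vtables with identical signatures:
# `ad_ops()` records onto a tape and returns integer node handles, while
# `raw_ops()` computes plain arrays with no recording. Forward code written
# against the vtable therefore serves both training (gradients needed) and
# evaluation (values only), and agreement between the two modes is itself a
# testable property.
#
# Batched traces E with per-episode dynamics are stored as [B*P, Q] matrices
# (row index = episode b fastest, then post-neuron i), so elementwise ops stay
# plain matrix arithmetic and the two contractions that need the batch
# structure (bmm, bouter) use precomputed row-index maps.

ad_tape <- function(capacity = 4096L) {
  # node fields live in hashed environments keyed by node id: assignment is
  # in place, whereas growing env-bound lists copies their spine every emit
  tp <- new.env(parent = emptyenv())
  tp$v <- new.env(parent = emptyenv(), size = capacity)
  tp$pb <- new.env(parent = emptyenv(), size = capacity)
  tp$pa <- new.env(parent = emptyenv(), size = capacity)
  tp$n <- 0L
  tp
}

ad_emit <- function(tp, val, parents = NULL, pb = NULL) {
  # force args before reading the counter: argument expressions may emit
  # their own nodes (nested op calls), which advances tp$n
  force(val); force(parents); force(pb)
  n <- tp$n + 1L
  k <- as.character(n)
  assign(k, val, envir = tp$v)
  if (!is.null(pb)) {
    assign(k, pb, envir = tp$pb)
    assign(k, parents, envir = tp$pa)
  }
  tp$n <- n
  n
}

ad_val <- function(tp, h) tp$v[[as.character(h)]]

# Reverse sweep; returns a list of gradients indexed by node id (NULL where
# no gradient reached a node).
ad_backward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss]] <- 1
  for (i in seq.int(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    pb <- tp$pb[[as.character(i)]]
    if (is.null(pb)) next
    pg <- pb(g)
    ps <- tp$pa[[as.character(i)]]
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

# Row-index maps for batched [B*P, Q] trace algebra, cached per shape by the
# network object.
batch_shape <- function(B, P, Q) {
  list(B = B, P = P, Q = Q,
       b_of_row = rep.int(seq_len(B), P),
       i_of_row = rep(seq_len(P), each = B))
}

# Contractions over the batched [B*P, Q] layout: sum over the post index
# (rows with the same episode) or over the batch index, via reshaped
# colSums, which is considerably faster than rowsum() grouping.
sum_over_post <- function(x, sh) {
  dim(x) <- c(sh$B, sh$P, ncol(x))
  colSums(aperm(x, c(2L, 1L, 3L)), dims = 1L)
}

sum_over_batch <- function(x, sh) {
  dim(x) <- c(sh$B, sh$P, ncol(x))
  colSums(x, dims = 1L)
}

clamp_raw <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

softplus_raw <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Taped vtable -----------------------------------------------------------

ad_ops <- function() {
  list(
    taped = TRUE,
    val = function(tp, h) tp$v[[as.character(h)]],
    const = function(tp, x) ad_emit(tp, x),
    # leaf with gradient tracking; caller keeps the handle
    param = function(tp, x) ad_emit(tp, x),

    add = function(tp, a, b) {
      force(a); force(b)
      ad_emit(tp, tp$v[[as.character(a)]] + tp$v[[as.character(b)]], c(a, b),
              function(g) list(g, g))
    },
    sub = function(tp, a, b) {
      force(a); force(b)
      ad_emit(tp, tp$v[[as.character(a)]] - tp$v[[as.character(b)]], c(a, b),
              function(g) list(g, -g))
    },
    mul = function(tp, a, b) {
      force(a); force(b)
      av <- tp$v[[as.character(a)]]; bv <- tp$v[[as.character(b)]]
      ad_emit(tp, av * bv, c(a, b), function(g) list(g * bv, g * av))
    },
    neg = function(tp, a) {
      force(a)
      ad_emit(tp, -tp$v[[as.character(a)]], a, function(g) list(-g))
    },
    # multiply by a constant scalar/array (not differentiated through)
    cmul = function(tp, a, cst) {
      force(a); force(cst)
      ad_emit(tp, tp$v[[as.character(a)]] * cst, a, function(g) list(g * cst))
    },
    # scalar node times array node
    smul = function(tp, s, x) {
      force(s); force(x)
      sv <- tp$v[[as.character(s)]]; xv <- tp$v[[as.character(x)]]
      ad_emit(tp, sv * xv, c(s, x),
              function(g) list(sum(g * xv), sv * g))
    },
    one_minus = function(tp, s) {
      force(s)
      ad_emit(tp, 1 - tp$v[[as.character(s)]], s, function(g) list(-g))
    },
    # weighted sum of same-shaped nodes: sum_k w[k] * hs[k]
    wsum = function(tp, hs, w) {
      force(w)
      hs <- as.integer(unlist(hs))
      v <- tp$v[[as.character(hs[1L])]] * w[1L]
      if (length(hs) > 1L) {
        for (k in 2L:length(hs)) v <- v + tp$v[[as.character(hs[k])]] * w[k]
      }
      ad_emit(tp, v, hs, function(g) lapply(w, function(wk) g * wk))
    },
    # a [B,Q] times t(W) [Q,P] -> [B,P]
    tmatmul = function(tp, a, W) {
      force(a); force(W)
      av <- tp$v[[as.character(a)]]; Wv <- tp$v[[as.character(W)]]
      ad_emit(tp, tcrossprod(av, Wv), c(a, W),
              function(g) list(g %*% Wv, crossprod(g, av)))
    },
    sigmoid = function(tp, a) {
      force(a)
      v <- plogis(tp$v[[as.character(a)]])
      ad_emit(tp, v, a, function(g) list(g * v * (1 - v)))
    },
    clamp = function(tp, a, lo, hi) {
      force(a)
      xv <- tp$v[[as.character(a)]]
      mask <- (xv >= lo) & (xv <= hi)
      ad_emit(tp, clamp_raw(xv, lo, hi), a, function(g) list(g * mask))
    },
    softplus = function(tp, a) {
      force(a)
      xv <- tp$v[[as.character(a)]]
      ad_emit(tp, softplus_raw(xv), a, function(g) list(g * plogis(xv)))
    },
    # X [B,Q] minus/plus a length-Q vector node, broadcast over rows
    sub_rvec = function(tp, X, v) {
      force(X); force(v)
      ad_emit(tp, sweep(tp$v[[as.character(X)]], 2L, tp$v[[as.character(v)]], "-"), c(X, v),
              function(g) list(g, -colSums(g)))
    },
    add_rvec = function(tp, X, v) {
      force(X); force(v)
      ad_emit(tp, sweep(tp$v[[as.character(X)]], 2L, tp$v[[as.character(v)]], "+"), c(X, v),
              function(g) list(g, colSums(g)))
    },
    # forward spike: binary threshold (or its smooth primitive in mode
    # "smooth"); backward: surrogate derivative
    spike = function(tp, u, cfg, sur, mode) {
      force(u)
      uv <- tp$v[[as.character(u)]]
      v <- if (mode == "smooth") surrogate_primitive(uv, cfg, sur)
           else (uv >= cfg$theta) * 1
      sg <- surrogate_derivative(uv, cfg, sur)
      ad_emit(tp, v, u, function(g) list(g * sg))
    },
    # E [B*P,Q] scaled elementwise by alpha [P,Q] broadcast over episodes
    bscale = function(tp, E, alpha, sh) {
      force(E); force(alpha); force(sh)
      Ev <- tp$v[[as.character(E)]]
      a_exp <- tp$v[[as.character(alpha)]][sh$i_of_row, , drop = FALSE]
      ad_emit(tp, Ev * a_exp, c(E, alpha), function(g) {
        list(g * a_exp, sum_over_batch(g * Ev, sh))
      })
    },
    # u[b,i] = sum_j E[b,i,j] a[b,j]; E as [B*P,Q], a as [B,Q] -> [B,P]
    bmm = function(tp, E, a, sh) {
      force(E); force(a); force(sh)
      Ev <- tp$v[[as.character(E)]]
      av <- tp$v[[as.character(a)]]
      a_exp <- av[sh$b_of_row, , drop = FALSE]
      v <- matrix(rowSums(Ev * a_exp), sh$B, sh$P)
      ad_emit(tp, v, c(E, a), function(g) {
        gvec <- as.vector(g)
        list(gvec * a_exp, sum_over_post(Ev * gvec, sh))
      })
    },
    # per-episode outer product: out[b,i,j] = x[b,i] y[b,j] as [B*P,Q]
    bouter = function(tp, x, y, sh) {
      force(x); force(y); force(sh)
      xv <- tp$v[[as.character(x)]]; yv <- tp$v[[as.character(y)]]
      xvec <- as.vector(xv)
      y_exp <- yv[sh$b_of_row, , drop = FALSE]
      ad_emit(tp, xvec * y_exp, c(x, y), function(g) {
        list(matrix(rowSums(g * y_exp), sh$B, sh$P),
             sum_over_post(g * xvec, sh))
      })
    },
    # first column minus second column of a [B,2] node
    coldiff = function(tp, X) {
      force(X)
      ad_emit(tp, tp$v[[as.character(X)]][, 1L] - tp$v[[as.character(X)]][, 2L], X,
              function(g) list(cbind(g, -g)))
    },
    # elementwise product with a constant vector (e.g. sampled signs)
    mulc = function(tp, x, cst) {
      force(x); force(cst)
      ad_emit(tp, tp$v[[as.character(x)]] * cst, x, function(g) list(g * cst))
    },
    # scalar = sum(x * cst)
    dotc = function(tp, x, cst) {
      force(x); force(cst)
      xv <- tp$v[[as.character(x)]]
      ad_emit(tp, sum(xv * cst), x, function(g) list(g * cst))
    },
    sum = function(tp, x) {
      force(x)
      xv <- tp$v[[as.character(x)]]
      ad_emit(tp, sum(xv), x, function(g) list(g + 0 * xv))
    },
    # fused SRM layer step: spike response (weighted sum of pre-spike
    # history), membrane potential with optional plastic term, refractory
    # feedback and thresholding in one node. Equivalent to the chain
    # wsum/tmatmul/bmm/add/spike; fused to keep the tape short in the
    # training hot loop.
    step_spike = function(tp, pre_hs, eps_w, own_hs, nu_w, W, alphaE, sh,
                          cfg, sur, mode) {
      pre_hs <- as.integer(unlist(pre_hs))
      own_hs <- as.integer(unlist(own_hs))
      force(W); force(alphaE)
      force(eps_w); force(nu_w); force(sh); force(cfg); force(sur)
      av <- tp$v[[as.character(pre_hs[1L])]] * eps_w[1L]
      if (length(pre_hs) > 1L) {
        for (k in 2L:length(pre_hs)) av <- av + tp$v[[as.character(pre_hs[k])]] * eps_w[k]
      }
      Wv <- tp$v[[as.character(W)]]
      uv <- tcrossprod(av, Wv)
      plastic <- !is.null(alphaE)
      if (plastic) {
        AEv <- tp$v[[as.character(alphaE)]]
        a_exp <- av[sh$b_of_row, , drop = FALSE]
        uv <- uv + matrix(rowSums(AEv * a_exp), sh$B, sh$P)
      }
      for (m in seq_along(own_hs)) uv <- uv + tp$v[[as.character(own_hs[m])]] * nu_w[m]
      sv <- if (mode == "smooth") surrogate_primitive(uv, cfg, sur)
            else (uv >= cfg$theta) * 1
      sg <- surrogate_derivative(uv, cfg, sur)
      parents <- c(pre_hs, own_hs, W, if (plastic) alphaE)
      np <- length(pre_hs); no <- length(own_hs)
      ad_emit(tp, sv, parents, function(g) {
        gu <- g * sg
        da <- gu %*% Wv
        out <- vector("list", length(parents))
        if (plastic) {
          gvec <- as.vector(gu)
          da <- da + sum_over_post(AEv * gvec, sh)
          out[[np + no + 2L]] <- gvec * a_exp
        }
        for (k in seq_len(np)) out[[k]] <- eps_w[k] * da
        for (m in seq_len(no)) out[[np + m]] <- nu_w[m] * gu
        out[[np + no + 1L]] <- crossprod(gu, av)
        out
      })
    },
    # diagonal-Gaussian log density of a constant action given mean node and
    # log-sd node; returns one log-prob per row of mu
    gauss_logp = function(tp, mu, sig_log, action) {
      force(mu); force(sig_log); force(action)
      muv <- tp$v[[as.character(mu)]]; slv <- tp$v[[as.character(sig_log)]]
      muv <- rbind(muv)
      n <- ncol(muv)
      s2 <- exp(2 * slv)
      dev <- sweep(action - muv, 2L, s2, "/") # (a - mu)/sigma^2
      v <- -sum(slv) - n / 2 * log(2 * pi) -
        rowSums((action - muv) * dev) / 2
      ad_emit(tp, v, c(mu, sig_log), function(g) {
        list(g * dev, colSums(g * ((action - muv) * dev - 1)))
      })
    }
  )
}

# Raw vtable: handles are the values themselves ---------------------------

raw_ops <- function() {
  list(
    taped = FALSE,
    val = function(tp, h) h,
    const = function(tp, x) x,
    param = function(tp, x) x,
    add = function(tp, a, b) a + b,
    sub = function(tp, a, b) a - b,
    mul = function(tp, a, b) a * b,
    neg = function(tp, a) -a,
    cmul = function(tp, a, cst) a * cst,
    smul = function(tp, s, x) s * x,
    one_minus = function(tp, s) 1 - s,
    wsum = function(tp, hs, w) {
      v <- hs[[1L]] * w[1L]
      if (length(hs) > 1L) for (k in 2L:length(hs)) v <- v + hs[[k]] * w[k]
      v
    },
    tmatmul = function(tp, a, W) tcrossprod(a, W),
    sigmoid = function(tp, a) plogis(a),
    clamp = function(tp, a, lo, hi) clamp_raw(a, lo, hi),
    softplus = function(tp, a) softplus_raw(a),
    sub_rvec = function(tp, X, v) sweep(X, 2L, v, "-"),
    add_rvec = function(tp, X, v) sweep(X, 2L, v, "+"),
    spike = function(tp, u, cfg, sur, mode) {
      if (mode == "smooth") surrogate_primitive(u, cfg, sur)
      else (u >= cfg$theta) * 1
    },
    bscale = function(tp, E, alpha, sh) E * alpha[sh$i_of_row, , drop = FALSE],
    bmm = function(tp, E, a, sh) {
      matrix(rowSums(E * a[sh$b_of_row, , drop = FALSE]), sh$B, sh$P)
    },
    bouter = function(tp, x, y, sh) {
      as.vector(x) * y[sh$b_of_row, , drop = FALSE]
    },
    step_spike = function(tp, pre_hs, eps_w, own_hs, nu_w, W, alphaE, sh,
                          cfg, sur, mode) {
      av <- pre_hs[[1L]] * eps_w[1L]
      if (length(pre_hs) > 1L) {
        for (k in 2L:length(pre_hs)) av <- av + pre_hs[[k]] * eps_w[k]
      }
      uv <- tcrossprod(av, W)
      if (!is.null(alphaE)) {
        uv <- uv + matrix(rowSums(alphaE * av[sh$b_of_row, , drop = FALSE]),
                          sh$B, sh$P)
      }
      for (m in seq_along(own_hs)) uv <- uv + own_hs[[m]] * nu_w[m]
      if (mode == "smooth") surrogate_primitive(uv, cfg, sur)
      else (uv >= cfg$theta) * 1
    },
    coldiff = function(tp, X) X[, 1L] - X[, 2L],
    mulc = function(tp, x, cst) x * cst,
    dotc = function(tp, x, cst) sum(x * cst),
    sum = function(tp, x) sum(x),
    gauss_logp = function(tp, mu, sig_log, action) {
      force(mu); force(sig_log); force(action)
      muv <- rbind(mu)
      n <- ncol(muv)
      s2 <- exp(2 * sig_log)
      -sum(sig_log) - n / 2 * log(2 * pi) -
        rowSums(sweep((action - muv)^2, 2L, s2, "/")) / 2
    }
  )
}

# Raw wsum takes a list of matrices in raw mode but an integer vector of
# handles in taped mode; forward code always passes a list and taped wsum
# coerces. Keep a helper so call sites stay uniform.
op_wsum <- function(o, tp, hs, w) {
  if (o$taped) o$wsum(tp, unlist(hs), w) else o$wsum(tp, hs, w)
}
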