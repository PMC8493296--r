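test_that("rate windows turn spike counts into [0,1] averages", {
  w <- rate_window(4, 1, 1)
  for (i in 1:4) window_observe(w, 1, i %% 2)
  r <- compute_rates(w)
  expect_equal(r$r_pre, 1.0)
  expect_equal(r$r_post, 0.5)
  # accumulators reset; mid-window call is a contract violation
  window_observe(w, 0, 1)
  expect_error(compute_rates(w), class = "plasticsnn_validation_error")
})

test_that("window rates are unbiased for Bernoulli spiking", {
  set.seed(21)
  n <- 1000
  rates <- replicate(n, {
    w <- rate_window(50, 1, 1)
    for (i in 1:50) window_observe(w, rbinom(1, 1, 0.3), 0)
    compute_rates(w)$r_pre
  })
  se <- sqrt(0.3 * 0.7 / 50) / sqrt(n)
  expect_lt(abs(mean(rates) - 0.3), 3 * se)
})

test_that("scalar rule updates match hand-computed values", {
  expect_equal(linear_decay_update(matrix(0.2), 0, 1, 1), matrix(0.2))
  expect_equal(linear_decay_update(matrix(0.2), 1, 0.7, 0.5), matrix(0.35))
  expect_equal(linear_decay_update(matrix(0.2), 0.5, 1, 1), matrix(0.6))

  expect_equal(oja_update(matrix(0.3), 0.4, 1, 0), matrix(0.6 * 0.3))
  expect_equal(oja_update(matrix(0), 0.4, 0.8, 0.6), matrix(0.4 * 0.8 * 0.6))
  expect_equal(oja_update(matrix(0.4), 0.5, 1, 2), matrix(0.4))

  expect_equal(bcm_update(matrix(0), 0.5, 1, 0.8, 0.5, 0.1), matrix(0.08))
  # on-threshold pre activity leaves only decay
  expect_equal(bcm_update(matrix(0.6), 0.25, 1, 0.4, 0.3, 0.1), matrix(0.45))

  expect_equal(bcm_threshold_update(0.2, 1, 0.9), 0.9)
  expect_equal(bcm_threshold_update(0.2, 0, 0.9), 0.2)
})

test_that("BCM threshold follows the geometric-series closed form", {
  eta_phi <- 0.23
  c_rate <- 0.61
  phi <- 0
  for (k in 1:17) {
    phi <- bcm_threshold_update(phi, eta_phi, c_rate)
    expect_equal(phi, c_rate * (1 - (1 - eta_phi)^k), tolerance = 1e-12)
  }
})

test_that("modulatory signal is the plain matrix-vector product", {
  expect_equal(modulatory_signal(matrix(0, 3, 3), runif(3)), rep(0, 3))
  r <- c(0.2, 0.5, 0.9)
  expect_equal(modulatory_signal(diag(3), r), r)
  set.seed(13)
  Wm <- matrix(rnorm(9), 3, 3)
  loop <- vapply(1:3, function(i) sum(Wm[i, ] * r), numeric(1))
  expect_equal(modulatory_signal(Wm, r), loop)
  expect_error(modulatory_signal(matrix(0, 2, 3), r),
               class = "plasticsnn_validation_error")
})

test_that("neuromodulated rules reduce to their local forms at M = 1", {
  set.seed(31)
  for (rep in 1:20) {
    P <- sample(2:6, 1); Q <- sample(2:6, 1)
    E <- matrix(runif(P * Q, -1, 1), P, Q)
    eta <- runif(1)
    r_post <- runif(P); r_pre <- runif(Q)
    phi <- runif(Q); psi <- runif(Q, -0.2, 0.2)
    ones <- rep(1, P)
    expect_identical(ndp_oja_update(E, eta, r_post, r_pre, ones),
                     oja_update(E, eta, r_post, r_pre))
    expect_identical(ndp_bcm_update(E, eta, r_post, r_pre, phi, psi, ones),
                     bcm_update(E, eta, r_post, r_pre, phi, psi))
  }
  # M = 0 leaves pure anti-Hebbian decay for Oja
  E <- matrix(c(0.5, -0.2), 1, 2)
  r_pre <- c(0.4, 0.3)
  got <- ndp_oja_update(E, 0.3, 1, r_pre, 0)
  expect_equal(got, 0.7 * E - 0.3 * outer(as.vector(E %*% r_pre), r_pre))
  # a negative modulatory entry flips that row's increment sign
  E2 <- matrix(0, 2, 2)
  up <- ndp_bcm_update(E2, 0.5, c(1, 1), c(0.9, 0.9), c(0.2, 0.2), c(0, 0),
                       M = c(1, -1))
  expect_true(all(up[1, ] > 0) && all(up[2, ] < 0))
  expect_equal(up[1, ], -up[2, ])
})

test_that("vectorized updates match per-element loop oracles", {
  set.seed(77)
  for (rep in 1:100) {
    P <- sample(1:8, 1); Q <- sample(1:8, 1)
    E <- matrix(runif(P * Q, -2, 2), P, Q)
    eta <- runif(1)
    r_post <- runif(P); r_pre <- runif(Q)
    phi <- runif(Q); psi <- runif(Q, -0.3, 0.3)
    M <- runif(P, -1.5, 1.5)
    clip <- sample(c(Inf, 2, 0.5), 1)
    expect_equal(linear_decay_update(E, eta, r_post, r_pre, clip),
                 loop_linear_decay(E, eta, r_post, r_pre, clip), tolerance = 1e-10)
    expect_equal(oja_update(E, eta, r_post, r_pre, clip),
                 loop_oja(E, eta, r_post, r_pre, clip), tolerance = 1e-10)
    expect_equal(bcm_update(E, eta, r_post, r_pre, phi, psi, clip),
                 loop_bcm(E, eta, r_post, r_pre, phi, psi, clip), tolerance = 1e-10)
    expect_equal(ndp_oja_update(E, eta, r_post, r_pre, M, clip),
                 loop_ndp_oja(E, eta, r_post, r_pre, M, clip), tolerance = 1e-10)
    expect_equal(ndp_bcm_update(E, eta, r_post, r_pre, phi, psi, M, clip),
                 loop_ndp_bcm(E, eta, r_post, r_pre, phi, psi, M, clip), tolerance = 1e-10)
  }
})

test_that("clipping bounds every update and is inactive at C = Inf", {
  set.seed(19)
  for (rep in 1:30) {
    E <- matrix(runif(12, -3, 3), 3, 4)
    up <- oja_update(E, 0.9, runif(3, 0, 4), runif(4), clip = 0.8)
    expect_lte(max(abs(up)), 0.8)
    upl <- linear_decay_update(E, 0.9, runif(3, 0, 5), runif(4, 0, 5), clip = 1.1)
    expect_lte(max(abs(upl)), 1.1)
  }
})

test_that("scalar Oja iteration contracts geometrically to its fixed point", {
  # solving E = (1-eta)E + eta(r_post - E r_pre)r_pre gives
  # E* = r_post r_pre / (1 + r_pre^2), contraction rate 1 - eta(1 + r_pre^2);
  # the spec-sheet shorthand r_post/r_pre describes the classic
  # continuous-time rule, not this blended discrete update (its own worked
  # example, E = 0.4 fixed at r_post = 1, r_pre = 2, confirms this form)
  for (case in list(c(0.3, 0.6, 0.8), c(0.25, 1, 1), c(0.1, 0.9, 0.4))) {
    eta <- case[1]; r_post <- case[2]; r_pre <- case[3]
    target <- r_post * r_pre / (1 + r_pre^2)
    rate <- 1 - eta * (1 + r_pre^2)
    expect_gt(rate, 0); expect_lt(rate, 1) # contractive regime
    E <- matrix(0)
    err_prev <- abs(0 - target)
    for (k in 1:400) {
      E <- oja_update(E, eta, r_post, r_pre)
      err <- abs(E[1, 1] - target)
      # exact geometric contraction while above the float-noise floor
      if (err_prev > 1e-8) expect_equal(err / err_prev, rate, tolerance = 1e-6)
      err_prev <- err
      if (err < 1e-11) break
    }
    expect_lt(err_prev, 1e-10)
  }
  # the spec example is exactly this fixed point
  expect_equal(oja_update(matrix(0.4), 0.5, 1, 2), matrix(0.4))
})

test_that("trace state resets to zero and is idempotent", {
  st <- trace_state(2, 3, clip_bound = 2)
  st$E[] <- runif(6)
  st$phi <- runif(3)
  st1 <- reset_traces(st)
  expect_equal(st1$E, matrix(0, 2, 3))
  expect_equal(st1$phi, numeric(3))
  expect_identical(reset_traces(st1)$E, st1$E)
})

test_that("rule-parameter gradients through one update match finite differences", {
  # d/dparam of sum(weights * E') for each learnable rule parameter
  set.seed(55)
  P <- 3; Q <- 4
  E <- matrix(runif(P * Q, -0.5, 0.5), P, Q)
  r_post <- runif(P); r_pre <- runif(Q)
  phi <- runif(Q, 0, 0.5); psi <- runif(Q, -0.2, 0.2)
  Wm <- matrix(rnorm(P * P, sd = 0.3), P, P)
  wts <- matrix(rnorm(P * Q), P, Q)

  # eta through the sigmoid squashing
  f_eta <- function(eta_raw) {
    sum(wts * ndp_oja_update(E, plogis(eta_raw), r_post, r_pre,
                             modulatory_signal(Wm, r_post)))
  }
  eta_raw <- 0.4
  eta <- plogis(eta_raw)
  Mv <- modulatory_signal(Wm, r_post)
  grad_eta <- sum(wts * (-E + outer(Mv * r_post - as.vector(E %*% r_pre), r_pre))) *
    eta * (1 - eta)
  expect_equal(central_fd(f_eta, eta_raw), grad_eta, tolerance = 1e-5)

  # psi in BCM
  f_psi <- function(psi) sum(wts * bcm_update(E, eta, r_post, r_pre, phi, psi))
  grad_psi <- vapply(seq_len(Q), function(j)
    sum(wts[, j] * (eta * r_post * (-r_pre[j]))), numeric(1))
  expect_equal(central_fd(f_psi, psi), grad_psi, tolerance = 1e-5)

  # W_m in NDP-Oja
  f_wm <- function(wm_vec) {
    sum(wts * ndp_oja_update(E, eta, r_post, r_pre,
                             modulatory_signal(matrix(wm_vec, P, P), r_post)))
  }
  grad_wm <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    grad_wm[i, j] <- eta * r_post[i] * r_post[j] * sum(wts[i, ] * r_pre)
  }
  expect_equal(central_fd(f_wm, as.vector(Wm)), as.vector(grad_wm), tolerance = 1e-5)
})
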