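test_that("reinforce loss implements reward-weighted log-probabilities", {
  # identical rewards cancel against the batch-mean baseline
  expect_equal(reinforce_loss(c(1, 1, 1), c(-0.2, -3, -1)), 0)
  # single trajectory with explicit zero baseline
  expect_equal(reinforce_loss(1, -1.7, baseline = 0), 1.7)
  expect_equal(reinforce_loss(c(1, -1), c(-0.5, -2)),
               -mean(c(1, -1) * c(-0.5, -2)))
  expect_error(reinforce_loss(numeric(0), numeric(0)),
               class = "plasticsnn_validation_error")
  expect_error(reinforce_loss(1, c(-1, -2)),
               class = "plasticsnn_validation_error")
})

test_that("reinforce gradient on a two-parameter toy policy matches finite differences", {
  # Bernoulli policy p(a = 1 | x) = logistic(th1 + th2 * x), fixed sampled
  # actions; the analytic gradient of the loss must match central FD
  set.seed(71)
  x <- rnorm(40)
  th <- c(0.3, -0.5)
  p <- plogis(th[1] + th[2] * x)
  a <- rbinom(40, 1, p)
  R <- ifelse(a == (x > 0), 1, -1)
  loss_of <- function(th) {
    eta <- th[1] + th[2] * x
    logp <- ifelse(a == 1, -log1p(exp(-eta)), -log1p(exp(eta)))
    reinforce_loss(R, logp)
  }
  adv <- R - mean(R)
  gl <- adv * (a - plogis(th[1] + th[2] * x)) # d logp / d eta
  grad <- -c(mean(gl), mean(gl * x))
  expect_equal(central_fd(loss_of, th), grad, tolerance = 1e-6)
})

test_that("ppo loss clips the probability ratio exactly where it should", {
  # ratio = 1 reduces to the unclipped objective
  adv <- c(2, -1, 0.5)
  lp <- c(-1, -2, -0.3)
  expect_equal(ppo_loss(lp, lp, adv, normalize = FALSE), -mean(adv))
  # zero advantages give zero loss
  expect_equal(ppo_loss(lp, lp + 0.3, rep(0, 3)), 0)
  # per-element clipping against a loop oracle
  set.seed(6)
  for (rep in 1:20) {
    n <- 12
    lp_new <- rnorm(n); lp_old <- rnorm(n); adv <- rnorm(n); eps <- 0.2
    got <- ppo_loss(lp_new, lp_old, adv, clip_eps = eps, normalize = FALSE)
    acc <- 0
    for (i in 1:n) {
      r <- exp(lp_new[i] - lp_old[i])
      rc <- min(max(r, 1 - eps), 1 + eps)
      acc <- acc + min(r * adv[i], rc * adv[i])
      if (abs(r - 1) <= eps) expect_equal(rc, r)
    }
    expect_equal(got, -acc / n, tolerance = 1e-12)
  }
  expect_error(ppo_loss(lp, lp[1:2], adv),
               class = "plasticsnn_validation_error")
})

test_that("hidden rate statistics count spikes per neuron per step", {
  m <- matrix(0, 4, 2); m[1, 1] <- 1; m[2, 2] <- 1; m[4, 1] <- 1
  expect_equal(unname(hidden_rate_stats(m)), 0.375)
  expect_equal(unname(hidden_rate_stats(matrix(0, 5, 3))), 0)
  expect_equal(unname(hidden_rate_stats(matrix(1, 5, 3))), 1)
  # multiple episodes and layers average independently per layer
  eps <- list(list(matrix(1, 2, 2), matrix(0, 2, 2)),
              list(matrix(0, 2, 2), matrix(1, 2, 2)))
  expect_equal(hidden_rate_stats(eps), c(layer1 = 0.5, layer2 = 0.5))
})

test_that("an untrained network performs at chance on the symmetric task", {
  task <- cue_task_spec("low", "scaled")
  net <- snn_network(c(task$n_input, task$n_hidden, 2), "ndp_oja", seed = 4,
                     w_scale = 4, alpha_init = 0.3, wm_scale = 1)
  ev <- plasticsnn:::eval_cue_accuracy(net, net$params, task, 1000, 17)
  expect_lt(abs(ev$accuracy - 0.5), 3 * sqrt(0.25 / 1000) + 0.02)
})

test_that("training is reproducible and reports loss = -accuracy", {
  task <- cue_task_spec("low", "scaled")
  cfg <- train_config(seed = 11, max_iterations = 3, batch_episodes = 8,
                      eval_episodes = 30)
  f1 <- train_cue_task(cfg, task, "dp_oja")
  f2 <- train_cue_task(cfg, task, "dp_oja")
  expect_identical(f1$metrics, f2$metrics)
  expect_equal(f1$metrics$loss, -f1$metrics$accuracy)
  expect_true(all(f1$metrics$accuracy >= 0 & f1$metrics$accuracy <= 1))
  expect_s3_class(tidy(f1), "tbl_df")
  g <- glance(f1)
  expect_equal(g$iterations, 3)
  expect_false(g$halted)
  p <- autoplot(f1)
  expect_s3_class(p, "ggplot")
})

test_that("one training step moves every learnable parameter group", {
  task <- cue_task_spec("low", "scaled")
  for (rule in c("ndp_oja", "ndp_bcm")) {
    net <- snn_network(c(task$n_input, task$n_hidden, 2), rule, seed = 2,
                       w_scale = 4, alpha_init = 0.3, wm_scale = 1)
    before <- net$params
    cfg <- train_config(seed = 2, max_iterations = 1, batch_episodes = 10,
                        eval_episodes = 10)
    fit <- train_cue_task(cfg, task, rule, net = net)
    after <- fit$net$params
    for (nm in names(before)) {
      expect_gt(max(abs(after[[nm]] - before[[nm]])), 0)
    }
  }
})

test_that("noise-response evaluation is exact at sigma zero and degrades with action noise", {
  env <- toy_env(n_act = 1, damping = 0.2, action_cost = 0.2, horizon = 40)
  policy <- function(obs) 1.5 # constant near-optimal action
  r0 <- evaluate_under_noise(policy, env, noise_spec("action", 0), n_eval = 5)
  expect_identical(r0$ratio, 1)
  expect_identical(evaluate_under_noise(policy, env, noise_spec("friction", 0),
                                        n_eval = 5)$ratio, 1)
  expect_identical(evaluate_under_noise(policy, env,
                                        noise_spec("observation", 0),
                                        n_eval = 5)$ratio, 1)
  # a policy that ignores observations is invariant to observation noise
  robs <- evaluate_under_noise(policy, env, noise_spec("observation", 2),
                               n_eval = 5)
  expect_equal(robs$ratio, 1)
  # multiplicative action noise costs energy: ratio decreases with sigma
  set.seed(30)
  ratios <- vapply(c(0, 0.4, 0.8), function(s) {
    evaluate_under_noise(policy, env, noise_spec("action", s),
                         n_eval = 60, seed = 5)$ratio
  }, numeric(1))
  expect_equal(ratios[1], 1)
  expect_true(all(diff(ratios) < 0.01)) # non-increasing up to MC slack
})

test_that("a spiking controller policy drives the toy environment", {
  obs_code <- population_code_spec(pop_size = 8, clip_lo = -2, clip_hi = 2)
  act_pop <- action_population_spec(subpop_size = 5, T_int = 8, gain = 2)
  net <- snn_network(c(8, 10, 10), "dp_oja", seed = 3, w_scale = 4)
  pol <- snn_policy(net, obs_code, act_pop)
  env <- toy_env(n_act = 1, horizon = 10)
  set.seed(40)
  r <- env_reset(env)
  state <- r$state; obs <- r$observation
  for (i in 1:10) {
    a <- pol$act(obs)
    expect_true(abs(a) <= act_pop$gain)
    s <- env_step(env, state, a)
    state <- s$state; obs <- s$observation
  }
  expect_gte(pol$controller$hidden_rate(), 0)
})
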