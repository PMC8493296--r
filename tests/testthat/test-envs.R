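test_that("episode layout follows the cue/gap/delay/decision structure", {
  spec <- cue_task_spec("low", "scaled")
  expect_equal(cue_episode_length(spec), 3 * 15 + 30 + 20)
  expect_equal(cue_decision_window(spec), 76:95)
  full <- cue_task_spec("low", "full")
  expect_equal(cue_episode_length(full), 7 * 30 + 120 + 40)
  expect_error(cue_task_spec(n_cues = 4), class = "plasticsnn_config_error")

  # high-noise preset: more stray spiking, weaker cues
  lo <- cue_task_spec("low"); hi <- cue_task_spec("high")
  expect_gt(hi$p_background, lo$p_background)
  expect_gt(hi$p_noise_group, lo$p_noise_group)
  expect_lt(hi$p_active, lo$p_active)
})

test_that("noiseless all-left episodes activate only left and decision groups", {
  spec <- cue_task_spec("low", "scaled", p_background = 0, p_noise_group = 0)
  set.seed(2)
  found <- FALSE
  for (i in 1:100) {
    ep <- make_cue_episode(spec)
    if (all(ep$cue_sides == "L")) {
      found <- TRUE
      expect_equal(ep$correct_side, "L")
      # right-cue and noise groups completely silent
      expect_equal(sum(ep$input[, 11:20]), 0)
      expect_equal(sum(ep$input[, 31:40]), 0)
      # decision group silent outside its window
      expect_equal(sum(ep$input[1:75, 21:30]), 0)
      # left group silent outside cue intervals
      cue_steps <- c(1:10, 16:25, 31:40)
      expect_equal(sum(ep$input[setdiff(1:95, cue_steps), 1:10]), 0)
      expect_gt(sum(ep$input[cue_steps, 1:10]), 0)
      break
    }
  }
  expect_true(found)
})

test_that("episode statistics match the generative description", {
  spec <- cue_task_spec("low", "scaled")
  set.seed(10)
  b <- plasticsnn:::make_cue_batch(spec, 400)
  # majority recount equals the label
  recount <- ifelse(rowSums(b$sides == 1) > spec$n_cues / 2, "L", "R")
  expect_identical(recount, b$correct)
  # left/right symmetric
  p <- mean(b$correct == "L")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 400))
  # firing rate of a cue group during its cue interval ~ p_active
  left1 <- b$sides[, 1] == 1
  r <- mean(b$input[left1, 1:10, 1:10])
  n_obs <- sum(left1) * 10 * 10
  expect_lt(abs(r - spec$p_active), 3 * sqrt(spec$p_active * 0.5 / n_obs))
  # noise group spikes everywhere at its own rate
  rn <- mean(b$input[, , 31:40])
  expect_lt(abs(rn - spec$p_noise_group), 3 * sqrt(0.05 * 0.95 / (400 * 95 * 10)))
  # decision group active only in the window (background elsewhere)
  rd_out <- mean(b$input[, 1:75, 21:30])
  expect_lt(rd_out, 3 * spec$p_background)
  rd_in <- mean(b$input[, 76:95, 21:30])
  expect_gt(rd_in, 0.4)
})

test_that("episodes are deterministic given a seed", {
  spec <- cue_task_spec("high", "scaled")
  set.seed(123); e1 <- make_cue_episode(spec)
  set.seed(123); e2 <- make_cue_episode(spec)
  expect_identical(e1$input, e2$input)
  expect_identical(e1$cue_sides, e2$cue_sides)
  expect_identical(e1$correct_side, e2$correct_side)
})

test_that("cue reward is +1/-1 with zero mean under a random policy", {
  ep <- list(correct_side = "L")
  expect_equal(cue_reward("L", ep), 1)
  expect_equal(cue_reward("R", ep), -1)
  # symmetry: expectation under uniform decisions is exactly 0
  expect_equal(cue_reward("L", ep) + cue_reward("R", ep), 0)
})

test_that("noise operators implement their exact formulas", {
  # sigma = 0 are identities (bitwise)
  x <- c(0.3, -1.2, 5)
  expect_identical(apply_observation_noise(x, noise_spec("observation", 0)), x)
  expect_identical(apply_action_noise(x, noise_spec("action", 0)), x)
  f0 <- apply_friction_noise(x, noise_spec("friction", 0))
  expect_equal(as.vector(f0), x)

  # zero action is invariant under multiplicative action noise
  set.seed(5)
  expect_identical(apply_action_noise(numeric(3), noise_spec("action", 2)),
                   numeric(3))

  # observation noise: mean 0, variance sigma^2
  set.seed(6)
  n <- 1e5; sig <- 0.7
  z <- replicate(n, apply_observation_noise(0, noise_spec("observation", sig)))
  expect_lt(abs(mean(z)), 3 * sig / sqrt(n))
  expect_lt(abs(var(z) - sig^2), 3 * sig^2 * sqrt(2 / (n - 1)))

  # action noise is unbiased
  a <- 2
  az <- replicate(n, apply_action_noise(a, noise_spec("action", 0.5)))
  expect_lt(abs(mean(az) - a), 3 * a * 0.5 / sqrt(n))

  # friction noise held constant within an episode via its z draw
  set.seed(7)
  fz <- apply_friction_noise(c(1, 1), noise_spec("friction", 0.3))
  again <- apply_friction_noise(c(1, 1), noise_spec("friction", 0.3),
                                z = attr(fz, "z"))
  expect_identical(as.vector(fz), as.vector(again))
  # and unbiased across episodes
  fs <- replicate(n / 10, apply_friction_noise(1, noise_spec("friction", 0.2))[1])
  expect_lt(abs(mean(fs) - 1), 3 * 0.2 / sqrt(n / 10))
})

test_that("toy environment follows its damping recurrence closed forms", {
  env <- toy_env(n_act = 1, damping = 0.1, action_cost = 0.05, horizon = 60)
  r <- env_reset(env)
  # zero action from rest: zero reward forever
  st <- r$state
  for (i in 1:10) {
    s <- env_step(env, st, 0)
    expect_equal(s$reward, 0)
    st <- s$state
  }
  # constant unit action: v_t = v*(1 - (1-d)^t), v* = 1/d
  st <- env_reset(env)$state
  vs <- numeric(30)
  for (t in 1:30) { s <- env_step(env, st, 1); st <- s$state; vs[t] <- s$observation }
  expect_equal(vs, (1 / 0.1) * (1 - 0.9^(1:30)), tolerance = 1e-12)
  # analytic optimal constant action matches a numeric grid search
  steady_reward <- function(a) a / (0.1 * 1) - 0.05 * a^2
  grid <- seq(0, 300, by = 0.05)
  a_star_grid <- grid[which.max(steady_reward(grid))]
  expect_equal(1 / (2 * 0.05 * 0.1), a_star_grid, tolerance = 0.05)
  # friction scales the effective damping
  rf <- env_reset(env, friction_z = 1) # f doubled
  s <- env_step(env, rf$state, 1)
  expect_equal(s$observation, 1) # (1 - 0.2)*0 + 1
  s2 <- env_step(env, s$state, 1)
  expect_equal(s2$observation, 0.8 * 1 + 1)
})
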