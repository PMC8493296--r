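# Policy-gradient training over unrolled plastic SNNs.

#' Training configuration
#'
#' @param lr,beta1,beta2,eps Adam optimizer settings.
#' @param batch_episodes episodes per training iteration.
#' @param max_iterations iteration budget.
#' @param halt_loss stopping threshold on the evaluation loss
#'   (`loss = -accuracy`, so the default -0.97 halts at 97% accuracy);
#'   must lie in `[-1, 0]` for the cue task.
#' @param grad_clip global-norm gradient bound.
#' @param eval_episodes fresh evaluation episodes per iteration.
#' @param seed master seed; environment, initialization, policy-sampling and
#'   evaluation randomness are drawn from named sub-streams of it.
#' @param restart_after restart interval in iterations (`NULL` disables).
#'   REINFORCE on the cue task has a characteristic take-off: runs stay at
#'   chance until the plastic readout pathway aligns, then converge within a
#'   few dozen iterations. The waiting time is close to memoryless across
#'   initializations, so if no learning signal has appeared after this many
#'   iterations (best accuracy below `restart_threshold`), the network is
#'   re-initialized from a seed derived deterministically from the master
#'   seed and training continues, all within the same total iteration
#'   budget.
#' @param restart_threshold best-accuracy level counted as a learning
#'   signal; must clear the extreme-value range of chance evaluations
#'   (the running maximum of Binomial(100, 1/2)/100 over hundreds of
#'   iterations reaches ~0.68, so 0.75 separates noise from take-off).
#' @export
train_config <- function(lr = 1e-2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         batch_episodes = 50L, max_iterations = 300L,
                         halt_loss = -0.97, grad_clip = 1.0,
                         eval_episodes = 100L, seed = 1L,
                         restart_after = 200L, restart_threshold = 0.75) {
  if (halt_loss < -1 || halt_loss > 0) stop_config("halt_loss must be in [-1, 0]")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_episodes = as.integer(batch_episodes),
                 max_iterations = as.integer(max_iterations),
                 halt_loss = halt_loss, grad_clip = grad_clip,
                 eval_episodes = as.integer(eval_episodes),
                 seed = as.integer(seed),
                 restart_after = restart_after,
                 restart_threshold = restart_threshold),
            class = "train_config")
}

# Adam with global-norm gradient clipping -------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1, beta2, eps, grad_clip) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (is.finite(grad_clip) && gnorm > grad_clip) {
    grads <- lapply(grads, function(g) g * (grad_clip / gnorm))
  }
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(opt = opt, params = params)
}


#' Calibrate the output-layer gain for a balanced decision head
#'
#' Scales the final weight matrix so that the mean output firing rate over
#' the decision window of probe episodes lands at `target` spikes per neuron
#' per step (mid-range). With threshold neurons the random initialization
#' leaves some seeds with silent output layers (no surrogate gradient) and
#' others with ceiling-rate outputs whose count-difference log-odds saturate
#' the policy; either way training freezes at chance. A short bisection on a
#' probe batch removes this seed lottery.
#'
#' @param net a [snn_network()].
#' @param task a [cue_task_spec()] providing probe episodes and the decision
#'   window.
#' @param target desired mean output spikes per neuron per step in (0, 1).
#' @param probe_episodes probe batch size.
#' @param seed seed for the probe sub-stream.
#' @return the network with its output weights rescaled.
#' @export
calibrate_decision_scale <- function(net, task, target = 0.2,
                                     probe_episodes = 16L, seed = 1L) {
  L <- length(net$sizes) - 1L
  nm <- paste0("W", L)
  win <- cue_decision_window(task)
  b <- with_seed(substream_seed(seed, "calibrate"),
                 make_cue_batch(task, probe_episodes))
  rate_at <- function(s) {
    p <- net$params
    p[[nm]] <- p[[nm]] * s
    fw <- snn_forward(net, b$input, params = p, gradient = FALSE)
    mean(fw_window_counts(fw, L, win)) / length(win)
  }
  lo <- 0.1; hi <- 8
  if (rate_at(hi) < target) {
    s_star <- hi
  } else if (rate_at(lo) > target) {
    s_star <- lo
  } else {
    for (i in 1:18) {
      mid <- sqrt(lo * hi)
      if (rate_at(mid) < target) lo <- mid else hi <- mid
    }
    s_star <- sqrt(lo * hi)
  }
  net$params[[nm]] <- net$params[[nm]] * s_star
  net
}

# Losses ------------------------------------------------------------------

#' REINFORCE loss for terminal-reward episodes
#'
#' `loss = -mean((reward - baseline) * log_prob)`. The default baseline is
#' the batch mean reward, a standard variance-reduction choice under which a
#' batch of identical rewards contributes zero gradient.
#'
#' @param rewards numeric vector, one terminal reward per trajectory.
#' @param log_probs log-probability of each trajectory's sampled decision.
#' @param baseline scalar baseline (default: batch mean of `rewards`).
#' @export
reinforce_loss <- function(rewards, log_probs, baseline = mean(rewards)) {
  if (length(rewards) == 0L) stop_validation("empty trajectory batch")
  if (length(rewards) != length(log_probs)) {
    stop_validation("rewards and log_probs must have equal length")
  }
  -mean((rewards - baseline) * log_probs)
}

#' Clipped-ratio (PPO) surrogate loss
#'
#' `loss = -mean(min(ratio * A, clip(ratio, 1 - eps, 1 + eps) * A))` with
#' `ratio = exp(log_probs - old_log_probs)`. Advantages may be normalized to
#' zero mean and unit variance across the batch.
#'
#' @param log_probs,old_log_probs per-step action log-probabilities under
#'   the current and behavior policies.
#' @param advantages per-step advantage estimates.
#' @param clip_eps clipping radius on the probability ratio.
#' @param normalize center and scale the advantages first.
#' @export
ppo_loss <- function(log_probs, old_log_probs, advantages, clip_eps = 0.2,
                     normalize = TRUE) {
  n <- length(log_probs)
  if (length(old_log_probs) != n || length(advantages) != n) {
    stop_validation("log_probs, old_log_probs and advantages must have equal length")
  }
  if (n == 0L) stop_validation("empty batch")
  a <- advantages
  if (normalize) {
    a <- a - mean(a)
    s <- if (n > 1L) sd(a) else 0
    if (is.finite(s) && s > 0) a <- a / s
  }
  ratio <- exp(log_probs - old_log_probs)
  -mean(pmin(ratio * a, clamp_raw(ratio, 1 - clip_eps, 1 + clip_eps) * a))
}

# Decision head over an unrolled forward pass (taped or raw) --------------
# Spike counts of the two output neurons over the decision window act as
# log-odds; a side is sampled from the provided uniform draws.
cue_decide_fw <- function(fw, window, u_draws) {
  o <- fw$o; tp <- fw$tp
  L <- length(fw$net$sizes) - 1L
  counts_h <- fw_window_counts(fw, L, window)
  delta_h <- o$coldiff(tp, counts_h)
  delta <- o$val(tp, delta_h)
  p_left <- plogis(delta)
  left <- u_draws < p_left
  sgn <- ifelse(left, 1, -1)
  logp_h <- o$neg(tp, o$softplus(tp, o$neg(tp, o$mulc(tp, delta_h, sgn))))
  list(side = ifelse(left, "L", "R"), p_left = p_left, logp_h = logp_h,
       delta = delta)
}

# Accuracy of the current parameters on freshly generated episodes.
eval_cue_accuracy <- function(net, params, task, n, seed) {
  batch <- with_seed(substream_seed(seed, "episodes"), make_cue_batch(task, n))
  fw <- snn_forward(net, batch$input, params = params, gradient = FALSE)
  u <- with_seed(substream_seed(seed, "decide"), runif(n))
  dec <- cue_decide_fw(fw, cue_decision_window(task), u)
  hidden <- vapply(seq_len(length(net$sizes) - 2L), function(l)
    mean(fw_spikes(fw, l)), numeric(1L))
  list(accuracy = mean(dec$side == batch$correct), hidden_rate = hidden)
}

#' Train a plastic SNN on the cue-association task with REINFORCE + BPTT
#'
#' Each iteration samples a batch of episodes, unrolls the plastic network
#' over every episode (traces reset per episode), samples a decision from
#' the binomial head, backpropagates the REINFORCE loss through time with
#' surrogate spike derivatives, and applies one Adam step. After each step
#' the policy is evaluated on fresh episodes; training halts when the
#' evaluation loss (`-accuracy`) reaches `cfg$halt_loss` or the iteration
#' budget is exhausted. All randomness derives from `cfg$seed` through named
#' sub-streams, so a repeated run reproduces the metric history exactly.
#'
#' @param cfg a [train_config()].
#' @param task a [cue_task_spec()].
#' @param rule rule name or [plasticity_rule()].
#' @param net optional pre-built [snn_network()] (defaults to
#'   `input-n_hidden-2` with the task's hidden width and a symmetric
#'   output head).
#' @param verbose print per-iteration progress.
#' @param calibrate_output rescale the output-layer weights before training
#'   so the initial decision-window firing rate sits mid-range (see
#'   [calibrate_decision_scale()]). Threshold units give the random
#'   initialization a wide output-activity spread across seeds; both tails
#'   are pathological for the policy gradient (silent outputs have vanishing
#'   surrogate derivatives, ceiling-rate outputs saturate the decision
#'   log-odds), so the gain is set from a small probe batch.
#' @return an object of class `cue_training`; see [tidy.cue_training()].
#' @export
train_cue_task <- function(cfg = train_config(), task = cue_task_spec(),
                           rule = "ndp_oja", net = NULL, verbose = FALSE,
                           calibrate_output = TRUE) {
  if (is.character(rule)) rule <- plasticity_rule(rule)
  if (is.null(net)) {
    # benchmark configuration: initialization gains sized so the plastic
    # pathway carries usable gradient signal from the start (see the
    # methods vignette)
    net <- snn_network(c(task$n_input, task$n_hidden, 2L), rule,
                       seed = cfg$seed, w_scale = 4, alpha_init = 0.3,
                       wm_scale = 1, symmetric_output = TRUE)
  }
  if (calibrate_output) net <- calibrate_decision_scale(net, task, seed = cfg$seed)
  params <- net$params
  opt <- adam_init(params)
  restarts <- 0L
  reinit <- function(r) {
    seed_r <- substream_seed(cfg$seed, paste0("restart", r))
    net_r <- snn_network(net$sizes, net$rule, kernel = net$kernel,
                         neuron = net$neuron, surrogate = net$surrogate,
                         seed = seed_r, w_scale = net$init$w_scale,
                         alpha_init = net$init$alpha_init,
                         wm_scale = net$init$wm_scale,
                         symmetric_output = net$init$symmetric_output)
    if (calibrate_output) {
      net_r <- calibrate_decision_scale(net_r, task, seed = seed_r)
    }
    net_r
  }
  env_seed <- substream_seed(cfg$seed, "env")
  pol_seed <- substream_seed(cfg$seed, "policy")
  evl_seed <- substream_seed(cfg$seed, "eval")
  window <- cue_decision_window(task)
  B <- cfg$batch_episodes
  rows <- vector("list", cfg$max_iterations)
  halted <- FALSE
  n_hidden_layers <- length(net$sizes) - 2L
  ev <- NULL

  for (it in seq_len(cfg$max_iterations)) {
    batch <- with_seed((env_seed + it) %% 2147483647, make_cue_batch(task, B))
    fw <- snn_forward(net, batch$input, params = params, gradient = TRUE)
    u <- with_seed((pol_seed + it) %% 2147483647, runif(B))
    dec <- cue_decide_fw(fw, window, u)
    rewards <- ifelse(dec$side == batch$correct, 1, -1)
    w <- (rewards - mean(rewards)) / B
    loss_h <- fw$o$dotc(fw$tp, dec$logp_h, -w)
    pg_loss <- fw$o$val(fw$tp, loss_h)
    if (!is.finite(pg_loss)) {
      stop("training diverged at iteration ", it, ": non-finite policy loss")
    }
    grads <- ad_backward(fw$tp, loss_h)
    gp <- lapply(fw$ph, function(h) grads[[h]])
    for (nm in names(gp)) if (is.null(gp[[nm]])) gp[[nm]] <- params[[nm]] * 0
    stepped <- adam_step(opt, params, gp, cfg$lr, cfg$beta1, cfg$beta2,
                         cfg$eps, cfg$grad_clip)
    opt <- stepped$opt
    params <- stepped$params
    if (any(!vapply(params, function(p) all(is.finite(p)), logical(1L)))) {
      stop("training diverged at iteration ", it, ": non-finite parameters")
    }
    train_hidden <- vapply(seq_len(n_hidden_layers), function(l)
      mean(fw_spikes(fw, l)), numeric(1L))
    ev <- eval_cue_accuracy(net, params, task, cfg$eval_episodes,
                            (evl_seed + it) %% 2147483647)
    loss <- -ev$accuracy
    rows[[it]] <- c(iteration = it, accuracy = ev$accuracy, loss = loss,
                    train_accuracy = mean(rewards == 1),
                    mean_reward = mean(rewards), pg_loss = pg_loss,
                    hidden_rate = mean(ev$hidden_rate),
                    train_hidden_rate = mean(train_hidden))
    if (verbose) {
      message(sprintf("iter %3d  acc %.3f  loss %+.3f  hidden %.3f",
                      it, ev$accuracy, loss, mean(ev$hidden_rate)))
    }
    if (loss <= cfg$halt_loss) { halted <- TRUE; break }
    if (!is.null(cfg$restart_after) && it %% cfg$restart_after == 0L &&
        it < cfg$max_iterations) {
      best_so_far <- max(vapply(rows[!vapply(rows, is.null, TRUE)],
                                function(r) r[["accuracy"]], numeric(1L)))
      if (best_so_far < cfg$restart_threshold) {
        restarts <- restarts + 1L
        if (verbose) message("no learning signal; restart ", restarts)
        net_r <- reinit(restarts)
        params <- net_r$params
        opt <- adam_init(params)
      }
    }
  }

  metrics <- tibble::as_tibble(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
  net$params <- params
  structure(list(metrics = metrics, net = net, task = task,
                 rule = rule$name, cfg = cfg, halted = halted,
                 restarts = restarts,
                 iterations = nrow(metrics),
                 best_loss = min(metrics$loss),
                 best_accuracy = max(metrics$accuracy),
                 final_accuracy = metrics$accuracy[nrow(metrics)],
                 hidden_rate_final = ev$hidden_rate),
            class = "cue_training")
}

#' @export
print.cue_training <- function(x, ...) {
  cat("<cue_training>", x$rule, "|", x$iterations, "iterations |",
      if (x$halted) "halted (criterion met)" else "budget exhausted",
      sprintf("| best accuracy %.3f", x$best_accuracy), "\n")
  invisible(x)
}

#' Tidy methods for cue-task training results
#'
#' `tidy()` returns the per-iteration metric history (accuracy, loss
#' `= -accuracy`, training-batch statistics, hidden-layer firing rates);
#' `glance()` returns a one-row summary.
#'
#' @param x a `cue_training` object.
#' @param ... unused.
#' @method tidy cue_training
#' @export
tidy.cue_training <- function(x, ...) x$metrics

#' @rdname tidy.cue_training
#' @method glance cue_training
#' @export
glance.cue_training <- function(x, ...) {
  tibble::tibble(rule = x$rule, iterations = x$iterations, halted = x$halted,
                 best_loss = x$best_loss, best_accuracy = x$best_accuracy,
                 final_accuracy = x$final_accuracy,
                 hidden_rate = mean(x$hidden_rate_final))
}

#' Plot a training history
#'
#' Evaluation accuracy and mean hidden firing rate against training
#' iteration.
#'
#' @param object a `cue_training` object.
#' @param ... unused.
#' @method autoplot cue_training
#' @export
autoplot.cue_training <- function(object, ...) {
  m <- object$metrics
  long <- rbind(
    data.frame(iteration = m$iteration, value = m$accuracy, metric = "accuracy"),
    data.frame(iteration = m$iteration, value = m$hidden_rate,
               metric = "hidden rate"))
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "training iteration", y = NULL,
                  title = paste("cue-association training:", object$rule))
}

#' Mean hidden-layer firing rates of recorded trajectories
#'
#' Spikes per neuron per step, averaged over neurons, steps and episodes,
#' reported per hidden layer.
#'
#' @param trajectories a list of episodes, each a list of per-layer binary
#'   spike matrices `[time, n_neurons]` (a bare matrix is treated as one
#'   episode with one layer).
#' @return named numeric vector, one mean rate per layer.
#' @export
hidden_rate_stats <- function(trajectories) {
  if (is.matrix(trajectories)) trajectories <- list(list(trajectories))
  trajectories <- lapply(trajectories, function(ep) {
    if (is.matrix(ep)) list(ep) else ep
  })
  n_layers <- length(trajectories[[1L]])
  rates <- vapply(seq_len(n_layers), function(l) {
    mean(vapply(trajectories, function(ep) mean(ep[[l]]), numeric(1L)))
  }, numeric(1L))
  names(rates) <- paste0("layer", seq_len(n_layers))
  rates
}

#' Evaluate a control policy's robustness to noise
#'
#' Runs `n_eval` episodes under the given noise model and the same episodes
#' (identical sub-stream seeds) with the noise disabled, and returns the
#' ratio of mean noisy return to mean noise-free return. At `sigma = 0` the
#' two runs are identical and the ratio is exactly 1.
#'
#' @param policy a function `observation -> action`, or a policy object with
#'   `$act` and `$reset` (see [snn_policy()]).
#' @param env an environment honoring the [env_reset()]/[env_step()]
#'   contract.
#' @param noise a [noise_spec()].
#' @param n_eval number of evaluation episodes.
#' @param seed master seed for episode sub-streams.
#' @return list with `ratio`, `mean_return`, `mean_return_clean`.
#' @export
evaluate_under_noise <- function(policy, env, noise, n_eval = 100L, seed = 1L) {
  pol <- as_policy(policy)
  run_one <- function(ep, spec) {
    with_seed(substream_seed(seed, paste0("episode", ep)), {
      pol$reset()
      fz <- if (spec$kind == "friction") {
        attr(apply_friction_noise(rep(1, length(env$friction %||% 1)), spec), "z")
      }
      r <- env_reset(env, friction_z = fz)
      state <- r$state
      obs <- r$observation
      total <- 0
      repeat {
        if (spec$kind == "observation") obs <- apply_observation_noise(obs, spec)
        a <- pol$act(obs)
        if (spec$kind == "action") a <- apply_action_noise(a, spec)
        sr <- env_step(env, state, a)
        state <- sr$state
        obs <- sr$observation
        total <- total + sr$reward
        if (sr$done) break
      }
      total
    })
  }
  clean_spec <- noise_spec(noise$kind, 0)
  noisy <- vapply(seq_len(n_eval), run_one, numeric(1L), spec = noise)
  clean <- vapply(seq_len(n_eval), run_one, numeric(1L), spec = clean_spec)
  mc <- mean(clean)
  ratio <- if (mc == 0) NA_real_ else mean(noisy) / mc
  list(ratio = ratio, mean_return = mean(noisy), mean_return_clean = mc)
}

as_policy <- function(policy) {
  if (is.function(policy)) list(act = policy, reset = function() invisible(NULL))
  else if (!is.null(policy$act)) policy
  else stop_validation("policy must be a function or have an $act element")
}

#' Spiking controller policy for continuous environments
#'
#' Composes place-code observation encoding, a stateful [snn_controller()],
#' and positive/negative sub-population action decoding into a policy usable
#' with [evaluate_under_noise()]. Each environment step spans one
#' integration interval of `act_pop$T_int` network steps. If a
#' [gaussian_head()] is supplied the decoded value is the mean of a
#' diagonal Gaussian from which the action is sampled.
#'
#' @param net a [snn_network()] whose input width is
#'   `n_obs * obs_code$pop_size` and output width
#'   `n_act * 2 * act_pop$subpop_size`.
#' @param obs_code a [population_code_spec()].
#' @param act_pop an [action_population_spec()].
#' @param head optional [gaussian_head()].
#' @export
snn_policy <- function(net, obs_code, act_pop, head = NULL) {
  ctrl <- snn_controller(net)
  act <- function(obs) {
    spikes_in <- encode_observation(obs, obs_code, act_pop$T_int)
    out <- ctrl$step(spikes_in)
    mu <- decode_action(out, act_pop)
    if (is.null(head)) mu else gaussian_action(mu, head)$action
  }
  list(act = act, reset = ctrl$reset, controller = ctrl)
}
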