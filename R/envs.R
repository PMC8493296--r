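# The noisy cue-association T-maze, Gaussian noise models, and a small
# pluggable continuous-control environment.

#' Cue-association task specification
#'
#' An episode presents `n_cues` randomly sided cues (each `cue_len` steps of
#' high spiking in the matching 10-neuron cue group, followed by a
#' `gap_len`-step gap), then a `delay_len`-step delay, then a
#' `decision_len`-step decision period during which the decision group is
#' active. Input layout is fixed: neurons 1-10 left cues, 11-20 right cues,
#' 21-30 decision, 31-40 task-independent noise. The correct side is the
#' majority of cue sides (`n_cues` is odd so ties cannot occur).
#'
#' Noise regimes: the high-noise preset has strictly higher background and
#' noise-group spike probabilities and a strictly lower in-cue probability
#' than the low-noise preset. Scale presets: `"full"` uses 7 cues with a
#' 120-step delay (~370-step episodes, 64 hidden neurons); `"scaled"` is the
#' compact configuration used for routine runs (3 cues, 95-step episodes,
#' 32 hidden neurons).
#'
#' @param noise `"low"` or `"high"` regime preset.
#' @param scale `"scaled"` or `"full"` timing preset.
#' @param n_cues,cue_len,gap_len,delay_len,decision_len overrides of the
#'   timing preset (steps; `n_cues` must be odd).
#' @param p_active,p_background,p_noise_group overrides of the regime spike
#'   probabilities.
#' @param n_cue_neurons neurons per input group.
#' @param n_hidden hidden-layer width paired with the scale preset.
#' @export
cue_task_spec <- function(noise = c("low", "high"), scale = c("scaled", "full"),
                          n_cues = NULL, cue_len = NULL, gap_len = NULL,
                          delay_len = NULL, decision_len = NULL,
                          p_active = NULL, p_background = NULL,
                          p_noise_group = NULL, n_cue_neurons = 10L,
                          n_hidden = NULL) {
  noise <- match.arg(noise)
  scale <- match.arg(scale)
  timing <- if (scale == "full") {
    list(n_cues = 7L, cue_len = 20L, gap_len = 10L, delay_len = 120L,
         decision_len = 40L, n_hidden = 64L)
  } else {
    list(n_cues = 3L, cue_len = 10L, gap_len = 5L, delay_len = 30L,
         decision_len = 20L, n_hidden = 32L)
  }
  probs <- if (noise == "low") {
    list(p_active = 0.5, p_background = 0.01, p_noise_group = 0.05)
  } else {
    list(p_active = 0.35, p_background = 0.05, p_noise_group = 0.15)
  }
  spec <- list(
    noise_level = noise, scale = scale, n_cue_neurons = as.integer(n_cue_neurons),
    n_cues = as.integer(n_cues %||% timing$n_cues),
    cue_len = as.integer(cue_len %||% timing$cue_len),
    gap_len = as.integer(gap_len %||% timing$gap_len),
    delay_len = as.integer(delay_len %||% timing$delay_len),
    decision_len = as.integer(decision_len %||% timing$decision_len),
    p_active = p_active %||% probs$p_active,
    p_background = p_background %||% probs$p_background,
    p_noise_group = p_noise_group %||% probs$p_noise_group,
    n_hidden = as.integer(n_hidden %||% timing$n_hidden))
  if (spec$n_cues %% 2L == 0L) stop_config("n_cues must be odd (no ties)")
  for (p in c("p_active", "p_background", "p_noise_group")) {
    if (spec[[p]] < 0 || spec[[p]] > 1) stop_config(p, " must be in [0, 1]")
  }
  spec$n_input <- 4L * spec$n_cue_neurons
  structure(spec, class = "cue_task_spec")
}

#' Episode length and decision window of a cue task
#'
#' @param spec a [cue_task_spec()].
#' @return `cue_episode_length()`: total steps per episode.
#'   `cue_decision_window()`: the step indices of the decision period.
#' @export
cue_episode_length <- function(spec) {
  spec$n_cues * (spec$cue_len + spec$gap_len) + spec$delay_len + spec$decision_len
}

#' @rdname cue_episode_length
#' @export
cue_decision_window <- function(spec) {
  len <- cue_episode_length(spec)
  (len - spec$decision_len + 1L):len
}

# Per-step, per-neuron spike probability array [B, T, 40] for a batch of
# episodes with the given cue sides (matrix [B, n_cues], 1 = left, 2 = right).
cue_prob_array <- function(spec, sides) {
  B <- nrow(sides)
  T_len <- cue_episode_length(spec)
  g <- spec$n_cue_neurons
  p <- array(spec$p_background, c(B, T_len, 4L * g))
  p[, , 3L * g + seq_len(g)] <- spec$p_noise_group
  for (ci in seq_len(spec$n_cues)) {
    t0 <- (ci - 1L) * (spec$cue_len + spec$gap_len)
    steps <- t0 + seq_len(spec$cue_len)
    left <- sides[, ci] == 1L
    if (any(left)) p[left, steps, seq_len(g)] <- spec$p_active
    if (any(!left)) p[!left, steps, g + seq_len(g)] <- spec$p_active
  }
  p[, cue_decision_window(spec), 2L * g + seq_len(g)] <- spec$p_active
  p
}

make_cue_batch <- function(spec, B) {
  sides <- matrix(sample(c(1L, 2L), B * spec$n_cues, replace = TRUE),
                  B, spec$n_cues)
  p <- cue_prob_array(spec, sides)
  input <- array(rbinom(length(p), 1L, as.vector(p)), dim(p))
  correct <- ifelse(rowSums(sides == 1L) > spec$n_cues / 2, "L", "R")
  list(input = input, sides = sides, correct = correct)
}

#' Generate one cue-association episode
#'
#' Cue sides are drawn uniformly at random; spikes are independent Bernoulli
#' draws at the interval-appropriate probabilities. Uses the current R
#' random stream, so a fixed seed reproduces the episode bit for bit.
#'
#' @param spec a [cue_task_spec()].
#' @return object of class `cue_episode`: `input` (binary
#'   `[episode_len, 40]`), `cue_sides` (`"L"`/`"R"` per cue), `correct_side`,
#'   and `decision_window`.
#' @export
make_cue_episode <- function(spec) {
  b <- make_cue_batch(spec, 1L)
  input <- b$input[1L, , ]
  dim(input) <- dim(b$input)[2:3]
  structure(list(input = input,
                 cue_sides = c("L", "R")[b$sides[1L, ]],
                 correct_side = b$correct[1L],
                 decision_window = cue_decision_window(spec),
                 spec = spec),
            class = "cue_episode")
}

#' Terminal reward of a cue decision
#'
#' @param decision `"L"` or `"R"`.
#' @param episode a `cue_episode` (or anything with `$correct_side`).
#' @return `+1` if the decision matches the majority side, else `-1`.
#' @export
cue_reward <- function(decision, episode) {
  if (identical(decision, episode$correct_side)) 1 else -1
}

# Noise models ------------------------------------------------------------

#' Gaussian noise specification
#'
#' Three multiplicative/additive Gaussian noise models for evaluating
#' trained controllers: observation noise is added to the observation each
#' step (`x + z`); action noise multiplies the action each step
#' (`a * (1 + z)`); friction noise multiplies the friction coefficients by
#' `(1 + z)` with `z` drawn once at episode start and held for the episode.
#' In every case `z ~ N(0, sigma^2)` elementwise.
#'
#' @param kind `"observation"`, `"action"` or `"friction"`.
#' @param sigma standard deviation of the noise.
#' @export
noise_spec <- function(kind = c("observation", "action", "friction"),
                       sigma = 0) {
  kind <- match.arg(kind)
  if (sigma < 0) stop_config("sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma), class = "noise_spec")
}

#' Apply the three Gaussian noise models
#'
#' `apply_observation_noise()` returns `x + z` with fresh `z` each call;
#' `apply_action_noise()` returns `a * (1 + z)` with fresh `z`;
#' `apply_friction_noise()` returns `f * (1 + z)` where `z` is drawn once
#' (pass the `z` attribute of an earlier result, or a stored draw, to hold
#' it constant across calls within an episode). All are exact identities at
#' `sigma = 0`.
#'
#' @param x,a,f observation, action and friction vectors.
#' @param spec a [noise_spec()] of the matching kind.
#' @param z optional pre-drawn noise vector (friction).
#' @export
apply_observation_noise <- function(x, spec) {
  stopifnot(spec$kind == "observation")
  if (spec$sigma == 0) return(x)
  x + rnorm(length(x), 0, spec$sigma)
}

#' @rdname apply_observation_noise
#' @export
apply_action_noise <- function(a, spec) {
  stopifnot(spec$kind == "action")
  if (spec$sigma == 0) return(a)
  a * (1 + rnorm(length(a), 0, spec$sigma))
}

#' @rdname apply_observation_noise
#' @export
apply_friction_noise <- function(f, spec, z = NULL) {
  stopifnot(spec$kind == "friction")
  if (is.null(z)) z <- if (spec$sigma == 0) numeric(length(f))
                       else rnorm(length(f), 0, spec$sigma)
  structure(f * (1 + z), z = z)
}

# Toy control environment --------------------------------------------------

#' Damped point-mass control environment
#'
#' A minimal continuous-control stand-in following the conventional
#' reset/step contract, so external physics environments can be plugged in
#' unchanged. Per-dimension dynamics
#' `v' = (1 - damping * friction) * v + action`, reward
#' `sum(v') - action_cost * sum(action^2)` (forward velocity with an energy
#' penalty on movement). The friction coefficient is exposed so friction
#' noise is meaningful. Under a constant action `a` the velocity converges
#' to `a / (damping * friction)` and the optimal constant action for the
#' velocity/energy trade-off is `1 / (2 * action_cost * damping * friction)`
#' per dimension.
#'
#' @param n_act action dimensionality.
#' @param damping velocity damping coefficient in (0, 1].
#' @param action_cost energy-penalty coefficient.
#' @param horizon episode length in environment steps.
#' @param friction baseline friction coefficients (recycled to `n_act`).
#' @export
toy_env <- function(n_act = 1L, damping = 0.1, action_cost = 0.05,
                    horizon = 200L, friction = 1) {
  if (damping <= 0 || damping > 1) stop_config("damping must be in (0, 1]")
  structure(list(n_act = as.integer(n_act), damping = damping,
                 action_cost = action_cost, horizon = as.integer(horizon),
                 friction = rep_len(friction, n_act)),
            class = "toy_env")
}

#' Reset/step contract for control environments
#'
#' `env_reset()` returns `list(state, observation)`; `env_step()` advances
#' one step and returns `list(state, observation, reward, done)`. For
#' [toy_env()], `friction_z` holds a per-episode friction-noise draw.
#'
#' @param env an environment object.
#' @param state the state returned by the previous call.
#' @param action numeric action vector.
#' @param friction_z optional friction noise vector `z` applied as
#'   `f * (1 + z)` for the whole episode.
#' @export
env_reset <- function(env, friction_z = NULL) UseMethod("env_reset")

#' @rdname env_reset
#' @export
env_step <- function(env, state, action) UseMethod("env_step")

#' @export
env_reset.toy_env <- function(env, friction_z = NULL) {
  f <- env$friction
  if (!is.null(friction_z)) f <- f * (1 + friction_z)
  state <- list(v = numeric(env$n_act), t = 0L, f = f)
  list(state = state, observation = state$v)
}

#' @export
env_step.toy_env <- function(env, state, action) {
  if (length(action) != env$n_act) stop_validation("action dimension mismatch")
  v <- (1 - env$damping * state$f) * state$v + action
  state$v <- v
  state$t <- state$t + 1L
  reward <- sum(v) - env$action_cost * sum(action^2)
  list(state = state, observation = v, reward = reward,
       done = state$t >= env$horizon)
}
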