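`%||%` <- function(x, y) if (is.null(x)) y else x

utils::globalVariables(c("iteration", "value"))

stop_config <- function(...) {
  stop(structure(class = c("plasticsnn_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("plasticsnn_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_binary <- function(x, what = "spike input") {
  if (!all(x == 0 | x == 1)) {
    stop_validation(what, " must be binary (0/1)")
  }
  invisible(x)
}

#' Derive a named random sub-stream seed
#'
#' All randomness in an experiment flows from one master seed. Named
#' sub-streams (environment, initialization, policy sampling, evaluation)
#' are derived deterministically from that seed so components never share or
#' reorder draws. The derivation is a small multiplicative string hash folded
#' into the positive 31-bit integer range.
#'
#' @param seed master integer seed.
#' @param name character stream name.
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 2654435 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
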