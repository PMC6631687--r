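# Classed error conditions so callers can distinguish bad inputs from
# numerical failures without matching on message text.

stop_invalid_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("ivivepk_invalid_input", "ivivepk_error")))
}

stop_fit_failure <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("ivivepk_fit_failure", "ivivepk_error")))
}

stop_data_quality <- function(msg) {
  stop(errorCondition(msg, class = c("ivivepk_data_quality", "ivivepk_error")))
}

stop_no_solution <- function(msg) {
  stop(errorCondition(msg, class = c("ivivepk_no_solution", "ivivepk_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("ivivepk_config_error", "ivivepk_error")))
}

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid_input(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps the synthetic generators pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid_input("`seed` must be a single finite number")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
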