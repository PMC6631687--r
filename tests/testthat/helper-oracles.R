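# Independent oracles used to validate the package's fitters. These
# deliberately share no code with the implementation: the monoexponential
# oracle is an exhaustive 1-D grid search with the intercept profiled out,
# and the triexponential oracle is a plain multi-start L-BFGS-B run.

# SSE of the best monoexponential model at each candidate half-life; C0 has
# a closed-form profile minimum for fixed decay rate.
grid_search_monoexp <- function(times, remaining,
                                t_half_grid = seq(1, 200, by = 0.01)) {
  best <- list(sse = Inf)
  for (th in t_half_grid) {
    e <- exp(-log(2) * times / th)
    c0 <- sum(remaining * e) / sum(e * e)
    sse <- sum((remaining - c0 * e)^2)
    if (sse < best$sse) best <- list(t_half = th, c0 = c0, sse = sse)
  }
  best
}

triexp_model <- function(t, a, lam) {
  a[1] * exp(-lam[1] * t) + a[2] * exp(-lam[2] * t) + a[3] * exp(-lam[3] * t)
}

# Multi-start oracle for the triexponential objective on the same bounded
# parameter domain as the fitter (bounds recomputed here from first
# principles: rates within [1/(3*t_max), 3/t_first]).
oracle_triexp_multistart <- function(times, conc, n_starts = 200, seed = 1) {
  t1 <- min(times[times > 0])
  llo <- log(1 / (3 * max(times))); lhi <- log(3 / t1)
  alo <- log(max(conc) * 1e-9); ahi <- log(max(conc) * 1e4)
  obj <- function(par) {
    r <- conc - triexp_model(times, exp(par[1:3]), exp(par[4:6]))
    sum(r * r)
  }
  lower <- c(rep(alo, 3), rep(llo, 3)); upper <- c(rep(ahi, 3), rep(lhi, 3))
  best <- Inf
  withr_seed <- function(code) { # local seed without touching global state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    for (i in seq_len(n_starts)) {
      la <- sort(runif(3, llo, lhi), decreasing = TRUE)
      aa <- runif(3, log(max(conc) * 0.01), log(max(conc) * 2))
      fit <- tryCatch(
        stats::optim(c(aa, la), obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 1000, factr = 1e3)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < best) best <- fit$value
    }
  })
  best
}

# A noisy single-animal corrected curve from the generator, for fitter tests.
synthetic_corrected_curve <- function(seed, profile = a1ar_profiles()$CBX) {
  st <- generate_pk_study(profile, noise_config(seed = seed), n_animals = 1)
  corrected_plasma_curve(st[[1]])
}
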