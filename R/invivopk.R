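#' Plasma concentration-time curve
#'
#' @param times Sampling times, minutes post injection.
#' @param conc Radioactivity concentration per mL plasma (plasma density is
#'   taken as 1 g/mL, so concentration per gram and per mL coincide).
#' @param conc_sd Optional per-point SD (present on aggregated mean curves).
#' @param n Number of animals contributing to each point (1 for an
#'   individual curve).
#' @return An object of class `plasma_curve`.
#' @export
plasma_curve <- function(times, conc, conc_sd = NULL, n = 1L) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc))
    stop_invalid_input("`times` and `conc` must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(conc)))
    stop_invalid_input("`times` and `conc` must be finite")
  if (any(conc < 0))
    stop_invalid_input("`conc` must be non-negative")
  if (any(diff(times) <= 0))
    stop_invalid_input("`times` must be strictly ascending")
  if (!is.null(conc_sd) && length(conc_sd) != length(times))
    stop_invalid_input("`conc_sd` must match `times` in length")
  structure(list(times = times, conc = conc, conc_sd = conc_sd, n = n),
            class = "plasma_curve")
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("<plasma_curve> %d points, %g-%g min, n = %d\n",
              length(x$times), min(x$times), max(x$times), x$n))
  invisible(x)
}

#' One animal of an in vivo radiotracer PK study
#'
#' @param animal_id Character label.
#' @param injected_activity Injected radioactivity (the dose `D`), e.g. Bq.
#' @param injected_amount Injected substance amount, nmol.
#' @param body_weight Body weight, kg.
#' @param samples Data frame with columns `time_pi` (min post injection),
#'   `activity_measured` (counting units, not decay corrected, total
#'   radioactivity) and `plasma_mass` (g).
#' @param parent_fractions Data frame with columns `times` (min) and
#'   `fractions` (parent fraction in \[0, 1\]).
#' @param isotope_half_life Physical half-life of the radionuclide, minutes
#'   (default 109.77, fluorine-18).
#' @return An object of class `animal_study`.
#' @export
animal_study <- function(animal_id, injected_activity, injected_amount,
                         body_weight, samples, parent_fractions,
                         isotope_half_life = 109.77) {
  assert_scalar_positive(injected_activity, "injected_activity")
  assert_scalar_positive(body_weight, "body_weight")
  assert_scalar_positive(isotope_half_life, "isotope_half_life")
  need <- c("time_pi", "activity_measured", "plasma_mass")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop_invalid_input("`samples` must have columns time_pi, activity_measured, plasma_mass")
  if (any(samples$time_pi < 0) || any(samples$plasma_mass <= 0) ||
      any(samples$activity_measured < 0))
    stop_invalid_input("sample invariants violated (time_pi >= 0, plasma_mass > 0, activity >= 0)")
  pf <- parent_fraction_series(parent_fractions$times, parent_fractions$fractions)
  structure(list(animal_id = as.character(animal_id),
                 injected_activity = injected_activity,
                 injected_amount = injected_amount,
                 body_weight = body_weight,
                 samples = samples, parent_fractions = pf,
                 isotope_half_life = isotope_half_life),
            class = "animal_study")
}

#' Parent-fraction time series
#'
#' Fraction of total plasma radioactivity attributable to unmetabolized
#' parent radiotracer, as measured by radio-TLC/HPLC at a set of times.
#'
#' @param times Minutes post injection, ascending.
#' @param fractions Parent fractions in \[0, 1\].
#' @return A data frame of class `parent_fraction_series`.
#' @export
parent_fraction_series <- function(times, fractions) {
  times <- as.numeric(times); fractions <- as.numeric(fractions)
  if (length(times) == 0L)
    stop_invalid_input("parent-fraction series must be non-empty")
  if (length(times) != length(fractions))
    stop_invalid_input("`times` and `fractions` must have equal length")
  if (any(diff(times) <= 0))
    stop_invalid_input("`times` must be strictly ascending")
  if (any(fractions < 0) || any(fractions > 1))
    stop_invalid_input("`fractions` must lie in [0, 1]")
  structure(data.frame(times = times, fractions = fractions),
            class = c("parent_fraction_series", "data.frame"))
}

#' Correct measured radioactivity for physical decay
#'
#' References activity back to injection time (t = 0):
#' `activity * 2^(time_pi / isotope_half_life)`.
#'
#' @param activity Measured activity (any counting unit), vectorized.
#' @param time_pi Minutes post injection.
#' @param isotope_half_life Radionuclide half-life, minutes.
#' @return Decay-corrected activity in the same units.
#' @export
decay_correct <- function(activity, time_pi, isotope_half_life = 109.77) {
  if (!is.numeric(isotope_half_life) || any(isotope_half_life <= 0))
    stop_invalid_input("`isotope_half_life` must be positive")
  activity * 2^(time_pi / isotope_half_life)
}

#' Correct a total-radioactivity curve for radiolabeled metabolites
#'
#' Multiplies each concentration by the parent fraction linearly interpolated
#' at the sample time, converting total plasma radioactivity into parent
#' radiotracer concentration. Outside the measured parent-fraction time range
#' the nearest measured fraction is used (boundary clamping).
#'
#' @param curve A [plasma_curve()] of total radioactivity concentration.
#' @param pf A [parent_fraction_series()].
#' @return A [plasma_curve()] of parent concentration.
#' @export
metabolite_correct <- function(curve, pf) {
  if (!inherits(curve, "plasma_curve"))
    stop_invalid_input("`curve` must be a plasma_curve")
  if (nrow(pf) == 0L)
    stop_invalid_input("parent-fraction series is empty")
  f <- stats::approx(pf$times, pf$fractions, xout = curve$times, rule = 2)$y
  plasma_curve(curve$times, curve$conc * f, conc_sd = curve$conc_sd, n = curve$n)
}

#' Standardized uptake value
#'
#' Normalizes a plasma radioactivity concentration to injected activity per
#' gram of body mass: `SUV = conc / (injected_activity / (body_weight * 1000))`.
#' With plasma density 1 g/mL the result is dimensionless; SUV = 1 means the
#' concentration equals the injected activity spread uniformly over the body
#' mass.
#'
#' @param conc Concentration, activity per mL (vectorized).
#' @param injected_activity Injected radioactivity (same counting units).
#' @param body_weight Body weight, kg.
#' @return SUV (unitless).
#' @export
compute_suv <- function(conc, injected_activity, body_weight) {
  assert_scalar_positive(injected_activity, "injected_activity")
  assert_scalar_positive(body_weight, "body_weight")
  conc / (injected_activity / (body_weight * 1000))
}

#' Decay- and metabolite-corrected concentration curve for one animal
#'
#' Converts raw gamma-counter measurements into a parent-radiotracer plasma
#' concentration curve: concentration = activity / plasma mass (1 g/mL), then
#' decay correction to injection time, then metabolite correction by the
#' animal's measured parent fractions.
#'
#' @param study An [animal_study()].
#' @return A [plasma_curve()] of parent concentration (activity/mL,
#'   decay-corrected).
#' @export
corrected_plasma_curve <- function(study) {
  if (!inherits(study, "animal_study"))
    stop_invalid_input("`study` must be an animal_study")
  s <- study$samples
  conc <- s$activity_measured / s$plasma_mass
  conc <- decay_correct(conc, s$time_pi, study$isotope_half_life)
  metabolite_correct(plasma_curve(s$time_pi, conc), study$parent_fractions)
}

#' Average individual animal curves into a mean data set
#'
#' Pointwise arithmetic mean and sample SD of the corrected concentration
#' across animals at each nominal sampling time. All animals must share the
#' same nominal grid; no resampling is attempted.
#'
#' @param studies List of [animal_study()] objects (>= 2).
#' @param suv If `TRUE`, average SUV-normalized curves instead of absolute
#'   concentration (the mean curve is then in SUV units).
#' @return A [plasma_curve()] with `conc_sd` filled and `n` set to the
#'   number of animals.
#' @export
aggregate_mean_curve <- function(studies, suv = FALSE) {
  if (length(studies) < 2L)
    stop_invalid_input("aggregation requires at least 2 animals")
  curves <- lapply(studies, corrected_plasma_curve)
  grid <- curves[[1]]$times
  same <- vapply(curves, function(cv)
    length(cv$times) == length(grid) && all(abs(cv$times - grid) < 1e-9), logical(1))
  if (!all(same))
    stop_invalid_input("animals are not sampled on a common nominal time grid")
  mat <- vapply(seq_along(curves), function(i) {
    cc <- curves[[i]]$conc
    if (suv) compute_suv(cc, studies[[i]]$injected_activity, studies[[i]]$body_weight)
    else cc
  }, numeric(length(grid)))
  plasma_curve(grid, rowMeans(mat), conc_sd = apply(mat, 1, stats::sd),
               n = length(studies))
}

# ---- triexponential model ------------------------------------------------

triexp_eval <- function(times, a, lam) {
  drop(exp(-outer(times, lam)) %*% a)
}

# Curve-stripping initializer: log-linear fit of the tail gives the terminal
# phase; peel it off and repeat for the intermediate and fast phases.
# Fallback shape multipliers are used where peeled residuals go non-positive.
triexp_strip_init <- function(t, y) {
  n <- length(t)
  tail_idx <- seq(max(1L, n - 4L), n)
  f3 <- stats::lm(log(pmax(y[tail_idx], 1e-12)) ~ t[tail_idx])
  lam3 <- max(-stats::coef(f3)[2], 1e-5)
  a3 <- exp(stats::coef(f3)[1])
  r1 <- y - a3 * exp(-lam3 * t)
  mid_idx <- which(t < t[tail_idx[1]] & r1 > 0)
  if (length(mid_idx) >= 2) {
    mid_idx <- mid_idx[mid_idx > min(2L, n)]
    if (length(mid_idx) < 2) mid_idx <- which(t < t[tail_idx[1]] & r1 > 0)
    f2 <- stats::lm(log(r1[mid_idx]) ~ t[mid_idx])
    lam2 <- -stats::coef(f2)[2]; a2 <- exp(stats::coef(f2)[1])
    if (!is.finite(lam2) || lam2 <= lam3) { lam2 <- 4 * lam3; a2 <- max(r1[1], y[1] / 4) }
  } else { lam2 <- 4 * lam3; a2 <- max(y[1] / 4, 1e-8) }
  r2 <- y - a3 * exp(-lam3 * t) - a2 * exp(-lam2 * t)
  early_idx <- which(t <= stats::quantile(t, 0.25) & r2 > 0)
  if (length(early_idx) >= 2) {
    f1 <- stats::lm(log(r2[early_idx]) ~ t[early_idx])
    lam1 <- -stats::coef(f1)[2]; a1 <- exp(stats::coef(f1)[1])
    if (!is.finite(lam1) || lam1 <= lam2) { lam1 <- 5 * lam2; a1 <- max(r2[1], y[1] / 2) }
  } else { lam1 <- 5 * lam2; a1 <- max(y[1] / 2, 1e-8) }
  list(a = pmax(c(a1, a2, a3), 1e-10), lam = c(lam1, lam2, lam3))
}

triexp_refine <- function(t, y, a0, lam0, lower, upper, wt = NULL) {
  par0 <- pmin(pmax(log(c(a0, lam0)), lower), upper)
  res_fun <- if (is.null(wt))
    function(par) y - triexp_eval(t, exp(par[1:3]), exp(par[4:6]))
  else
    function(par) (y - triexp_eval(t, exp(par[1:3]), exp(par[4:6]))) / wt
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = res_fun, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  a <- exp(fit$par[1:3]); lam <- exp(fit$par[4:6])
  list(a = a, lam = lam, sse = sum(res_fun(fit$par)^2))
}

# Box bounds (log scale) keeping the rate constants in the range the
# sampling grid can actually identify: a phase faster than max_rate has
# decayed below ~5% by the first sample, and one slower than min_rate is
# indistinguishable from a constant over the observation window. In either
# case the amplitude is unconstrained by the data and only corrupts the
# model AUC (and hence clearance).
triexp_bounds <- function(t, y, max_rate = NULL, min_rate = NULL) {
  t1 <- min(t[t > 0])
  if (is.null(max_rate)) max_rate <- 3 / t1
  if (is.null(min_rate)) min_rate <- 1 / (3 * max(t))
  ymax <- max(y)
  list(lower = c(rep(log(ymax * 1e-9), 3), rep(log(min_rate), 3)),
       upper = c(rep(log(ymax * 1e4), 3), rep(log(max_rate), 3)))
}

#' Fit a triexponential disposition model to a plasma curve
#'
#' Fits `C_p(t) = A1*exp(-lambda1*t) + A2*exp(-lambda2*t) + A3*exp(-lambda3*t)`
#' by unweighted nonlinear least squares on the concentration scale.
#' Parameters are optimized on the log scale (enforcing positivity);
#' initialization is by curve stripping (log-linear fit of the terminal tail,
#' peel, repeat) followed by refinement from the stripped start plus
#' `n_restarts` randomly perturbed starts. The returned phases are sorted by
#' decreasing rate constant; ties between equal-SSE optima are broken toward
#' the larger spread between `lambda1` and `lambda3`.
#'
#' @param curve A [plasma_curve()] with at least 7 points covering an early
#'   (< 5 min) and a late (> 60 min) phase.
#' @param n_restarts Number of perturbed restarts (default 20).
#' @param weights `"inverse_yhat2"` (default) weights residuals by 1/yhat^2
#'   (yhat from the curve-stripping model), i.e. relative least squares;
#'   `"uniform"` fits on the absolute concentration scale. Decay- and
#'   metabolite-corrected radiotracer concentrations carry multiplicative
#'   error (counting noise amplified by the decay correction, relative
#'   parent-fraction error), and a plasma curve spans 2 or more decades, so
#'   relative residuals are the matched objective; an unweighted fit lets
#'   the early high-concentration points dominate and leaves the terminal
#'   phase poorly determined.
#' @param max_rate Upper bound on the rate constants, 1/min. The default,
#'   3 divided by the first positive sampling time, is an identifiability
#'   constraint: a phase decaying below ~5% before the first sample cannot
#'   be estimated from the data and would only inflate the model AUC.
#' @param min_rate Lower bound on the rate constants, 1/min (default
#'   1 / (3 * last sampling time)): a phase with a half-life much longer
#'   than the observation window is indistinguishable from a constant and
#'   its AUC contribution is unbounded.
#' @param seed Seed for the restart perturbations (default 1; the fit is
#'   deterministic for fixed inputs and seed).
#' @return An object of class `triexp_fit` with fields `a` (A1..A3), `lam`
#'   (lambda1 > lambda2 > lambda3), `residual_sse` and `diagnostics` (a
#'   character vector flagging near-degenerate solutions such as a vanishing
#'   amplitude or nearly collapsed rate constants).
#' @export
fit_triexponential <- function(curve, n_restarts = 20,
                               weights = c("inverse_yhat2", "uniform"),
                               max_rate = NULL, min_rate = NULL, seed = 1) {
  weights <- match.arg(weights)
  if (!inherits(curve, "plasma_curve"))
    stop_invalid_input("`curve` must be a plasma_curve")
  t <- curve$times; y <- curve$conc
  if (length(t) < 7L)
    stop_invalid_input("triexponential fit requires at least 7 points")
  if (min(t) >= 5 || max(t) <= 60)
    stop_invalid_input("sampling must cover an early (< 5 min) and a late (> 60 min) phase")
  if (all(y <= 0))
    stop_invalid_input("all concentrations are zero")

  init <- triexp_strip_init(t, pmax(y, 1e-12))
  bnd <- triexp_bounds(t, y, max_rate, min_rate)
  wt <- if (weights == "inverse_yhat2")
    pmax(triexp_eval(t, init$a, init$lam), 1e-12) else NULL

  refine_one <- function(a0, lam0)
    triexp_refine(t, y, a0, lam0, bnd$lower, bnd$upper, wt)

  cands <- with_seed(seed, {
    n_local <- ceiling(n_restarts / 2)
    local_starts <- lapply(seq_len(n_local), function(i) {
      list(a = init$a * exp(stats::rnorm(3, 0, 0.4)),
           lam = init$lam * exp(stats::rnorm(3, 0, 0.4)))
    })
    # global draws guard against a misleading stripping start
    global_starts <- lapply(seq_len(n_restarts - n_local), function(i) {
      list(a = exp(stats::runif(3, log(0.01 * max(y)), log(2 * max(y)))),
           lam = exp(sort(stats::runif(3, bnd$lower[4], bnd$upper[4]),
                          decreasing = TRUE)))
    })
    starts <- c(list(init), local_starts, global_starts)
    Filter(Negate(is.null), lapply(starts, function(s) refine_one(s$a, s$lam)))
  })
  if (length(cands) == 0L)
    stop_fit_failure("triexponential fit failed to converge from any start",
                     diagnostics = list(init = init))
  sses <- vapply(cands, function(cc) cc$sse, numeric(1))
  best_sse <- min(sses)
  near <- which(sses <= best_sse * (1 + 1e-9))
  spread <- vapply(cands[near], function(cc) max(cc$lam) / min(cc$lam), numeric(1))
  best <- cands[[near[which.max(spread)]]]

  ord <- order(best$lam, decreasing = TRUE)
  a <- best$a[ord]; lam <- best$lam[ord]
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop_fit_failure("triexponential fit produced non-positive rate constants",
                     diagnostics = list(a = a, lam = lam, sse = best$sse))
  diagnostics <- character(0)
  if (any(a < 1e-6 * max(y)))
    diagnostics <- c(diagnostics, "near-zero amplitude: model may be over-parameterized (biexponential data?)")
  if (any(lam[-3] / lam[-1] < 1.2))
    diagnostics <- c(diagnostics, "nearly collapsed rate constants: phases poorly separated")
  structure(list(a = a, lam = lam, residual_sse = best$sse,
                 n_points = length(t), weights = weights,
                 diagnostics = diagnostics),
            class = "triexp_fit")
}

#' @export
print.triexp_fit <- function(x, ...) {
  cat("<triexp_fit>\n")
  cat(sprintf("  A      : %s\n", paste(signif(x$a, 4), collapse = ", ")))
  cat(sprintf("  lambda : %s  (1/min)\n", paste(signif(x$lam, 4), collapse = ", ")))
  cat(sprintf("  SSE %.4g on %d points\n", x$residual_sse, x$n_points))
  if (length(x$diagnostics)) cat("  !", paste(x$diagnostics, collapse = "\n  ! "), "\n")
  invisible(x)
}

#' PK parameters from a fitted triexponential model
#'
#' Derives plasma clearance, volume of distribution and terminal half-life
#' from the macroconstants:
#' `CL_p = D / sum(A_i / lambda_i)` (the denominator is the analytic AUC of
#' the model over \[0, Inf)), `V_d = CL_p / lambda3` and
#' `t_half_term = log(2) / lambda3`. If `body_weight` is given, `CL_p` and
#' `V_d` are normalized per kg (mL/min/kg, mL/kg); otherwise they are
#' absolute (mL/min, mL).
#'
#' @param fit A `triexp_fit`.
#' @param injected_dose Injected radioactivity `D` (same counting units as
#'   the fitted concentrations, per mL).
#' @param body_weight Body weight in kg, or `NULL` for absolute values.
#' @return An object of class `pk_parameters` with fields `cl_p`, `v_d`,
#'   `t_half_term`, `auc` and `lambda_terminal`.
#' @export
pk_parameters <- function(fit, injected_dose, body_weight = NULL) {
  if (!inherits(fit, "triexp_fit"))
    stop_invalid_input("`fit` must be a triexp_fit")
  assert_scalar_positive(injected_dose, "injected_dose")
  lam3 <- min(fit$lam)
  if (lam3 <= 0)
    stop_invalid_input("terminal rate constant must be positive")
  auc <- sum(fit$a / fit$lam)
  cl <- injected_dose / auc
  if (!is.null(body_weight)) {
    assert_scalar_positive(body_weight, "body_weight")
    cl <- cl / body_weight
  }
  structure(list(cl_p = cl, v_d = cl / lam3, t_half_term = log(2) / lam3,
                 auc = auc, lambda_terminal = lam3,
                 per_kg = !is.null(body_weight)),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  u <- if (x$per_kg) c("mL/min/kg", "mL/kg") else c("mL/min", "mL")
  cat(sprintf("<pk_parameters> CL_p = %.3g %s, V_d = %.3g %s, t1/2,term = %.3g min\n",
              x$cl_p, u[1], x$v_d, u[2], x$t_half_term))
  invisible(x)
}

#' Full in vivo analysis of a multi-animal study
#'
#' Runs the correction pipeline and triexponential fit on each animal and on
#' the aggregated mean curve, and reports the relative deviation between the
#' mean-curve clearance and the mean of the individual-animal clearances.
#' The mean-curve parameters use the across-animal mean injected dose and
#' body weight.
#'
#' @param studies List of [animal_study()] objects.
#' @param ... Passed on to [fit_triexponential()].
#' @return A list with `individual` (data frame of per-animal CL_p, V_d,
#'   t_half_term), `mean_curve` ([pk_parameters()] from the mean curve),
#'   `cl_p_deviation_pct` (percent deviation of the individual mean from the
#'   mean-curve CL_p) and `mean_fit` (the mean-curve `triexp_fit`).
#' @export
analyze_pk_study <- function(studies, ...) {
  if (length(studies) < 2L)
    stop_invalid_input("analysis requires at least 2 animals")
  indiv <- lapply(studies, function(st) {
    fit <- fit_triexponential(corrected_plasma_curve(st), ...)
    pk <- pk_parameters(fit, st$injected_activity, st$body_weight)
    data.frame(animal_id = st$animal_id, cl_p = pk$cl_p, v_d = pk$v_d,
               t_half_term = pk$t_half_term)
  })
  indiv <- do.call(rbind, indiv)
  mean_curve <- aggregate_mean_curve(studies)
  mean_fit <- fit_triexponential(mean_curve, ...)
  d_mean <- mean(vapply(studies, function(st) st$injected_activity, numeric(1)))
  bw_mean <- mean(vapply(studies, function(st) st$body_weight, numeric(1)))
  pk_mean <- pk_parameters(mean_fit, d_mean, bw_mean)
  list(individual = indiv, mean_curve = pk_mean, mean_fit = mean_fit,
       cl_p_deviation_pct = 100 * abs(pk_mean$cl_p - mean(indiv$cl_p)) / pk_mean$cl_p)
}
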