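make_triexp_fit <- function(a, lam) {
  structure(list(a = a, lam = lam, residual_sse = 0, n_points = NA,
                 weights = "uniform", diagnostics = character(0)),
            class = "triexp_fit")
}

flat_study <- function(id, level, times = c(1, 2, 3, 5, 10)) {
  animal_study(id, injected_activity = 1e6, injected_amount = 0.4,
               body_weight = 0.5,
               samples = data.frame(time_pi = times,
                                    activity_measured = level * 0.1,
                                    plasma_mass = 0.1),
               parent_fractions = data.frame(times = range(times),
                                             fractions = c(1, 1)),
               isotope_half_life = 1e9)
}

test_that("decay correction references activity to injection time", {
  expect_equal(decay_correct(123, 0, 109.77), 123)
  expect_equal(decay_correct(50, 109.77, 109.77), 100)
  expect_equal(decay_correct(100, 219.54, 109.77), 400)
  expect_error(decay_correct(100, 10, -5), class = "ivivepk_invalid_input")
})

test_that("decay and metabolite corrections commute", {
  times <- c(1, 5, 20, 60, 180)
  pf <- parent_fraction_series(c(0, 60, 180), c(1, 0.5, 0.25))
  set.seed(5)
  conc <- runif(5, 10, 100)
  a <- metabolite_correct(
    plasma_curve(times, decay_correct(conc, times, 109.77)), pf)
  b <- decay_correct(metabolite_correct(plasma_curve(times, conc), pf)$conc,
                     times, 109.77)
  expect_equal(a$conc, b)
})

test_that("metabolite correction interpolates and clamps parent fractions", {
  pf <- parent_fraction_series(c(1, 90, 180), c(0.98, 0.5, 0.25))
  cv <- metabolite_correct(plasma_curve(c(0.5, 1, 135, 180), c(100, 100, 8, 10)), pf)
  expect_equal(cv$conc[2], 98)           # measured point
  expect_equal(cv$conc[4], 2.5)          # 25% parent at end of study
  expect_equal(cv$conc[3], 8 * 0.375)    # linear interpolation
  expect_equal(cv$conc[1], 98)           # clamped before first measurement
  one <- parent_fraction_series(c(0, 200), c(1, 1))
  cv2 <- metabolite_correct(plasma_curve(c(1, 2, 3), c(5, 4, 3)), one)
  expect_equal(cv2$conc, c(5, 4, 3))
})

test_that("SUV normalization is dimensionless and linear", {
  expect_equal(compute_suv(21e6 / (0.5 * 1000), 21e6, 0.5), 1.0)
  expect_equal(compute_suv(0, 21e6, 0.5), 0)
  expect_equal(compute_suv(10, 1e6, 0.8), 2 * compute_suv(10, 1e6, 0.4))
})

test_that("mean-curve aggregation averages pointwise with sample SD", {
  studies <- list(flat_study("a", 2), flat_study("b", 4))
  mc <- aggregate_mean_curve(studies)
  expect_equal(mc$conc, rep(3, 5))
  expect_equal(mc$conc_sd, rep(sqrt(2), 5))
  expect_equal(mc$n, 2L)
  same <- aggregate_mean_curve(list(flat_study("a", 2), flat_study("b", 2)))
  expect_equal(same$conc, rep(2, 5))
  expect_equal(same$conc_sd, rep(0, 5))
  expect_error(aggregate_mean_curve(list(flat_study("a", 2))),
               class = "ivivepk_invalid_input")
  expect_error(aggregate_mean_curve(list(flat_study("a", 2),
                                         flat_study("b", 4, times = c(1, 2, 4, 5, 10)))),
               class = "ivivepk_invalid_input")
})

test_that("triexponential fit recovers noiseless parameters", {
  tt <- c(1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 60, 90, 120, 150, 180)
  a_true <- c(5, 3, 2); lam_true <- c(1, 0.1, 0.01)
  fit <- fit_triexponential(plasma_curve(tt, triexp_model(tt, a_true, lam_true)))
  expect_lt(max(abs(fit$a - a_true) / a_true), 1e-4)
  expect_lt(max(abs(fit$lam - lam_true) / lam_true), 1e-4)
  expect_true(all(diff(fit$lam) < 0))
})

test_that("biexponential data are flagged or rejected by the triexponential fit", {
  tt <- c(1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 60, 90, 120, 150, 180)
  y <- 5 * exp(-tt) + 3 * exp(-0.1 * tt)
  out <- tryCatch(fit_triexponential(plasma_curve(tt, y)), error = function(e) e)
  if (inherits(out, "error")) {
    expect_s3_class(out, "ivivepk_fit_failure")
  } else {
    expect_gt(length(out$diagnostics), 0)
  }
})

test_that("triexponential fit rejects inadequate sampling designs", {
  expect_error(fit_triexponential(plasma_curve(c(1, 5, 30, 90, 180), c(5, 4, 3, 2, 1))),
               class = "ivivepk_invalid_input")
  tt <- seq(10, 180, length.out = 10)  # no early phase
  expect_error(fit_triexponential(plasma_curve(tt, exp(-0.01 * tt))),
               class = "ivivepk_invalid_input")
})

test_that("PK parameters follow the closed-form macroconstant identities", {
  fit <- make_triexp_fit(c(5, 3, 2), c(1, 0.1, 0.01))
  pk <- pk_parameters(fit, injected_dose = 10)
  expect_equal(pk$cl_p, 10 / 235)
  expect_equal(pk$v_d, (10 / 235) / 0.01)
  expect_equal(pk$t_half_term, log(2) / 0.01)
  # dose linearity: scaling D scales CL_p, terminal half-life unchanged
  pk2 <- pk_parameters(fit, injected_dose = 30)
  expect_equal(pk2$cl_p, 3 * pk$cl_p)
  expect_equal(pk2$t_half_term, pk$t_half_term)
  # per-kg normalization
  pk3 <- pk_parameters(fit, injected_dose = 10, body_weight = 0.5)
  expect_equal(pk3$cl_p, pk$cl_p / 0.5)
  # algebraic identities tie V_d and t_half to lambda3 and CL_p exactly
  expect_equal(pk3$v_d, pk3$cl_p / min(fit$lam))
  expect_equal(pk3$t_half_term, log(2) / min(fit$lam))
})

test_that("analytic AUC of a fitted model agrees with adaptive quadrature", {
  cv <- synthetic_corrected_curve(seed = 21)
  fit <- fit_triexponential(cv)
  analytic <- sum(fit$a / fit$lam)
  quad <- stats::integrate(function(x) triexp_model(x, fit$a, fit$lam),
                           0, Inf, rel.tol = 1e-8)
  expect_lt(abs(analytic - quad$value) / analytic, 1e-6)
})

test_that("corrected curve from one noise-free animal recovers the generator truth", {
  pr <- a1ar_profiles()$CBX
  st <- generate_pk_study(pr, noise_off(1), n_animals = 1)
  fit <- fit_triexponential(corrected_plasma_curve(st[[1]]))
  pk <- pk_parameters(fit, st[[1]]$injected_activity, st[[1]]$body_weight)
  expect_lt(abs(pk$cl_p - pr$cl_p_true) / pr$cl_p_true, 0.005)
  expect_lt(abs(pk$t_half_term - pr$t_half_term_true) / pr$t_half_term_true, 0.005)
  expect_lt(abs(pk$v_d - pr$cl_p_true / (log(2) / pr$t_half_term_true)) / pk$v_d, 0.005)
})
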