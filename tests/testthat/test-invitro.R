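test_that("monoexponential fit recovers noiseless decay parameters exactly", {
  t <- c(0, 2, 5, 10, 15, 20)
  for (th_true in c(35.1, 19.8, 14.0)) {
    tc <- depletion_timecourse("X", t, 100 * exp(-log(2) * t / th_true))
    fit <- fit_monoexponential(tc)
    expect_lt(abs(fit$t_half - th_true) / th_true, 1e-6)
    expect_lt(abs(fit$c0 - 100) / 100, 1e-6)
    expect_equal(fit$n_points, length(t))
  }
})

test_that("monoexponential fit rejects degenerate inputs", {
  t <- c(0, 2, 5, 10, 15, 20)
  expect_error(fit_monoexponential(depletion_timecourse("X", t, rep(100, 6))),
               class = "ivivepk_fit_failure")
  expect_error(fit_monoexponential(depletion_timecourse("X", c(0, 10), c(100, 50))),
               class = "ivivepk_invalid_input")
  expect_error(depletion_timecourse("X", c(0, 5, 2), c(100, 80, 90)),
               class = "ivivepk_invalid_input")
  expect_error(depletion_timecourse("X", c(1, 5, 10), c(100, 80, 60)),
               class = "ivivepk_invalid_input")
})

test_that("noisy depletion fit matches the 1-D grid-search oracle", {
  profile <- compound_profile("SYN", log_p = 2.5, t_half_vitro_true = 20,
                              f_p_true = 0.03, cl_p_true = 3,
                              v_d_true = 300, t_half_term_true = log(2) * 100,
                              parent_fraction_anchor = data.frame(
                                times = c(0, 180), fractions = c(1, 0.5)))
  tcs <- generate_depletion(profile, noise_config(depletion_cv = 0.05, seed = 11),
                            n_replicates = 1)
  fit <- fit_monoexponential(tcs[[1]], weights = "uniform")
  oracle <- grid_search_monoexp(tcs[[1]]$times, tcs[[1]]$remaining)
  expect_lte(fit$residual_sse, oracle$sse * (1 + 1e-6))
  expect_lt(abs(fit$t_half - oracle$t_half), 0.011)
})

test_that("microsomal unbound fraction reproduces reference values and limits", {
  expect_equal(round(microsomal_unbound_fraction(c(2.19, 2.82, 2.93), 0.5), 2),
               c(0.90, 0.82, 0.80))
  expect_identical(microsomal_unbound_fraction(3.7, 0), 1)
  expect_error(microsomal_unbound_fraction(2.0, -0.5),
               class = "ivivepk_invalid_input")
})

test_that("unbound fraction is monotone in protein and lipophilicity", {
  p <- seq(0.1, 5, length.out = 30)
  for (lp in c(0.5, 2.19, 4)) {
    fm <- microsomal_unbound_fraction(lp, p)
    expect_true(all(diff(fm) < 0))
    expect_true(all(fm > 0 & fm <= 1))
  }
  lp <- seq(0.1, 6, length.out = 40)  # vertex of the exponent is < 0
  fm <- microsomal_unbound_fraction(lp, 0.5)
  expect_true(all(diff(fm) < 0))
  expect_lt(abs(microsomal_unbound_fraction(5, 1e-9) - 1), 1e-6)
})

test_that("intrinsic clearance scaling matches a unit-tracked oracle and reference values", {
  ctx <- assay_context(protein_conc = 0.5)
  sf <- scaling_factors()
  ref <- data.frame(lp = c(2.19, 2.82, 2.93), th = c(35.1, 19.8, 14.0),
                    cl_int = c(106.1, 204.1, 295.0))
  for (i in 1:3) {
    fm <- microsomal_unbound_fraction(ref$lp[i], 0.5)
    got <- scale_intrinsic_clearance(ref$th[i], fm, ctx, sf)
    # term-by-term: rate constant (1/min) -> per mg protein (mL/min/mg)
    # -> per g liver -> per kg body weight
    k_unbound <- (log(2) / ref$th[i]) / fm            # 1/min
    ml_per_min_per_mg <- k_unbound * (1 / 0.5)        # mL incubation per mg
    ml_per_min_per_g <- ml_per_min_per_mg * 60        # per g liver
    oracle <- ml_per_min_per_g * 40                   # per kg body weight
    expect_lt(abs(got - oracle) / oracle, 1e-9)
    expect_lt(abs(got - ref$cl_int[i]) / ref$cl_int[i], 0.01)
  }
  # proportionality: doubling the half-life halves the clearance
  fm <- microsomal_unbound_fraction(2.5, 0.5)
  expect_equal(scale_intrinsic_clearance(20, fm) / 2,
               scale_intrinsic_clearance(40, fm))
  expect_error(scale_intrinsic_clearance(-1, fm), class = "ivivepk_invalid_input")
  expect_error(scale_intrinsic_clearance(20, 1.5), class = "ivivepk_invalid_input")
})

test_that("replicate fitting reports per-replicate mean and SD", {
  profile <- a1ar_profiles()$CBX
  tcs <- generate_depletion(profile, noise_off(1), n_replicates = 3)
  tab <- fit_depletion_replicates(tcs, log_p = c(CBX = profile$log_p))
  expect_equal(tab$n_replicates, 3)
  expect_lt(abs(tab$t_half_mean - 35.1) / 35.1, 1e-6)
  expect_equal(tab$t_half_sd, 0, tolerance = 1e-6)
  # noisy replicates: summary equals direct mean/sd of individual fits
  tcs <- generate_depletion(profile, noise_config(seed = 3), n_replicates = 3)
  tab <- fit_depletion_replicates(tcs, log_p = c(CBX = profile$log_p))
  th <- vapply(tcs, function(tc) fit_monoexponential(tc)$t_half, numeric(1))
  expect_equal(tab$t_half_mean, mean(th))
  expect_equal(tab$t_half_sd, sd(th))
})
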