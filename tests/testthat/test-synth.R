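test_that("generators are deterministic in the seed and leave the RNG alone", {
  pr <- a1ar_profiles()$CPFPX
  n <- noise_config(seed = 99)
  expect_identical(generate_depletion(pr, n, 3), generate_depletion(pr, n, 3))
  s1 <- generate_pk_study(pr, n, 3); s2 <- generate_pk_study(pr, n, 3)
  expect_equal(s1[[2]]$samples, s2[[2]]$samples)
  expect_identical(generate_ultrafiltration(pr, n, 5),
                   generate_ultrafiltration(pr, n, 5))
  # different seeds give different data
  expect_false(identical(generate_ultrafiltration(pr, noise_config(seed = 1), 5),
                         generate_ultrafiltration(pr, noise_config(seed = 2), 5)))
  # the caller's RNG stream is not consumed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_pk_study(pr, n, 2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noise-free depletion is exactly monoexponential", {
  pr <- a1ar_profiles()$CBX
  tcs <- generate_depletion(pr, noise_off(1), n_replicates = 2)
  t <- tcs[[1]]$times
  expect_equal(tcs[[1]]$remaining, 100 * exp(-log(2) * t / 35.1))
  expect_lt(abs(fit_monoexponential(tcs[[1]])$t_half - 35.1) / 35.1, 1e-8)
})

test_that("depletion generator is unbiased for the half-life under default noise", {
  pr <- a1ar_profiles()$CBX
  th <- vapply(1:50, function(s) {
    tcs <- generate_depletion(pr, noise_config(seed = s), n_replicates = 3)
    mean(vapply(tcs, function(tc) fit_monoexponential(tc)$t_half, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(th) - 35.1) / 35.1, 0.02)
})

test_that("generated truths satisfy the macroconstant identities exactly", {
  pr <- a1ar_profiles()$MCBX
  st <- generate_pk_study(pr, noise_config(seed = 12), n_animals = 3)
  for (s in st) {
    tr <- attr(s, "truth")
    auc <- sum(tr$a / tr$lam)
    expect_equal(s$injected_activity / auc / s$body_weight, tr$cl_p,
                 tolerance = 1e-12)
    expect_equal(tr$v_d, tr$cl_p / min(tr$lam), tolerance = 1e-12)
    expect_equal(tr$t_half_term, log(2) / min(tr$lam), tolerance = 1e-12)
    expect_equal(tr$t_half_term, pr$t_half_term_true, tolerance = 1e-12)
  }
})

test_that("parent fractions decline to the measured terminal values", {
  prs <- a1ar_profiles()
  pf180 <- vapply(prs, function(p) {
    a <- p$parent_fraction_anchor
    stats::approx(a$times, a$fractions, xout = 180, rule = 2)$y
  }, numeric(1))
  expect_equal(unname(pf180[c("CPFPX", "MCBX", "CBX")]), c(0.07, 0.13, 0.25))
  # early anchors are within the reported ranges
  pf1 <- vapply(prs, function(p)
    stats::approx(p$parent_fraction_anchor$times, p$parent_fraction_anchor$fractions,
                  xout = 1)$y, numeric(1))
  expect_true(all(pf1 >= 0.98 & pf1 <= 0.99))
})

test_that("inconsistent profile truths are rejected", {
  expect_error(
    compound_profile("BAD", 2.5, 20, 0.03, cl_p_true = 3, v_d_true = 300,
                     t_half_term_true = 200,  # should be ~69 min
                     parent_fraction_anchor = data.frame(times = c(0, 180),
                                                         fractions = c(1, 0.5))),
    class = "ivivepk_config_error")
})

test_that("noise-free ultrafiltration returns the true free fraction exactly", {
  pr <- a1ar_profiles()$CPFPX
  uf <- generate_ultrafiltration(pr, noise_off(1), n_animals = 3)
  expect_equal(free_fraction(uf$counts_plasma, uf$counts_filtrate),
               rep(pr$f_p_true, 3))
})

test_that("ultrafiltration estimates are unbiased across seeds", {
  pr <- a1ar_profiles()$CPFPX  # true f_p ~ 0.017
  est <- vapply(1:100, function(s) {
    uf <- generate_ultrafiltration(pr, noise_config(seed = s), n_animals = 5)
    mean(free_fraction(uf$counts_plasma, uf$counts_filtrate))
  }, numeric(1))
  expect_lt(abs(mean(est) - pr$f_p_true) / pr$f_p_true, 0.05)
})

test_that("self-consistent profiles make the forward chain reproduce the truth", {
  pr <- self_consistent_profile(a1ar_profiles()$CBX)
  fm <- microsomal_unbound_fraction(pr$log_p, 0.5)
  cl_int <- scale_intrinsic_clearance(pr$t_half_vitro_true, fm)
  expect_equal(well_stirred_clearance(cl_int, pr$f_p_true), pr$cl_p_true)
  expect_equal(pr$t_half_term_true, log(2) * pr$v_d_true / pr$cl_p_true)
})
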