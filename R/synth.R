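# Synthetic-data generators emulating a rat radiotracer IVIVE study:
# monoexponential microsomal depletion with multiplicative noise,
# triexponential plasma kinetics emitted as decay-uncorrected total
# radioactivity with Poisson counting noise, declining parent fractions,
# and high-protein-binding ultrafiltration count pairs.

#' Ground-truth profile of a synthetic compound
#'
#' Bundles the quantities the generators treat as truth. The shipped default
#' profiles ([a1ar_profiles()]) describe three xanthine-type A1 adenosine
#' receptor radiotracers studied in rat.
#'
#' @param compound_id Character label.
#' @param log_p Octanol-water log P.
#' @param t_half_vitro_true True microsomal depletion half-life, min.
#' @param f_p_true True plasma free fraction, in (0, 1].
#' @param cl_p_true True in vivo plasma clearance, mL/min/kg.
#' @param v_d_true True volume of distribution, mL/kg.
#' @param t_half_term_true True terminal half-life, min. Must be consistent
#'   with `cl_p_true` and `v_d_true` (`t_half_term = log(2) * V_d / CL_p`) to
#'   within 5%, since the triexponential truth enforces that identity.
#' @param parent_fraction_anchor Data frame (`times`, `fractions`) giving the
#'   true parent-fraction decline; linearly interpolated by the generator.
#' @return An object of class `compound_profile`.
#' @export
compound_profile <- function(compound_id, log_p, t_half_vitro_true, f_p_true,
                             cl_p_true, v_d_true, t_half_term_true,
                             parent_fraction_anchor) {
  for (nm in c("t_half_vitro_true", "f_p_true", "cl_p_true", "v_d_true",
               "t_half_term_true"))
    assert_scalar_positive(get(nm), nm)
  if (f_p_true > 1) stop_invalid_input("`f_p_true` must be in (0, 1]")
  implied <- log(2) * v_d_true / cl_p_true
  if (abs(implied - t_half_term_true) / t_half_term_true > 0.05)
    stop_config(sprintf(
      "inconsistent truths: t_half_term_true = %.3g but log(2)*V_d/CL_p = %.3g",
      t_half_term_true, implied))
  pf <- parent_fraction_series(parent_fraction_anchor$times,
                               parent_fraction_anchor$fractions)
  structure(list(compound_id = compound_id, log_p = log_p,
                 t_half_vitro_true = t_half_vitro_true, f_p_true = f_p_true,
                 cl_p_true = cl_p_true, v_d_true = v_d_true,
                 t_half_term_true = t_half_term_true,
                 parent_fraction_anchor = pf),
            class = "compound_profile")
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf("<compound_profile> %s: logP %.2f, t1/2(vitro) %.1f min, f_p %.3f, CL_p %.2f mL/min/kg, V_d %.0f mL/kg, t1/2,term %.1f min\n",
              x$compound_id, x$log_p, x$t_half_vitro_true, x$f_p_true,
              x$cl_p_true, x$v_d_true, x$t_half_term_true))
  invisible(x)
}

# Hand-drawn monotone parent-fraction declines consistent with the measured
# anchor points (98-99% / 91-94% / 81-88% at 1/2/3 min; ~25% / 13% / 7% at
# 180 min for the slow / intermediate / fast metabolizer respectively).
pf_anchor_cbx <- function() data.frame(
  times = c(0, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 60, 90, 120, 150, 180),
  fractions = c(1, 0.99, 0.94, 0.88, 0.82, 0.76, 0.71, 0.64, 0.58, 0.50,
                0.44, 0.37, 0.31, 0.28, 0.26, 0.25))
pf_anchor_mcbx <- function() data.frame(
  times = c(0, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 60, 90, 120, 150, 180),
  fractions = c(1, 0.985, 0.92, 0.84, 0.73, 0.63, 0.55, 0.45, 0.38, 0.29,
                0.24, 0.185, 0.155, 0.14, 0.133, 0.13))
pf_anchor_cpfpx <- function() data.frame(
  times = c(0, 1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 60, 90, 120, 150, 180),
  fractions = c(1, 0.98, 0.91, 0.81, 0.68, 0.57, 0.48, 0.37, 0.30, 0.21,
                0.16, 0.115, 0.09, 0.08, 0.074, 0.07))

#' Reference profiles of the three xanthine A1AR radiotracers
#'
#' Ground-truth profiles for CBX, MCBX and CPFPX: measured log P and in
#' vitro half-lives, observed in vivo PK parameters (CL_p, V_d, terminal
#' half-life from mean-curve fits), and parent-fraction declines anchored at
#' the measured early and 180-min values. The plasma free fractions are
#' reconstructions obtained by inverting the well-stirred model against the
#' reported intrinsic and predicted clearances (the study reports free
#' fractions only graphically, as < 5%); they are defaults, not measured
#' values.
#'
#' @return Named list of [compound_profile()] objects (`CBX`, `MCBX`,
#'   `CPFPX`).
#' @export
a1ar_profiles <- function() {
  # free fractions back-solved from reported (CL_int, predicted CL_p) pairs
  fp <- mapply(invert_well_stirred_fp,
               cl_p = c(2.72, 7.76, 4.70),
               cl_int = c(106.1, 204.1, 295.0))
  list(
    CBX = compound_profile("CBX", log_p = 2.19, t_half_vitro_true = 35.1,
                           f_p_true = fp[1], cl_p_true = 3.22, v_d_true = 356,
                           t_half_term_true = 76.5,
                           parent_fraction_anchor = pf_anchor_cbx()),
    MCBX = compound_profile("MCBX", log_p = 2.82, t_half_vitro_true = 19.8,
                            f_p_true = fp[2], cl_p_true = 9.10, v_d_true = 715,
                            t_half_term_true = 54.5,
                            parent_fraction_anchor = pf_anchor_mcbx()),
    CPFPX = compound_profile("CPFPX", log_p = 2.93, t_half_vitro_true = 14.0,
                             f_p_true = fp[3], cl_p_true = 7.10, v_d_true = 523,
                             t_half_term_true = 51.0,
                             parent_fraction_anchor = pf_anchor_cpfpx()))
}

#' Make a profile's in vivo truth equal its in vitro forward prediction
#'
#' Replaces `cl_p_true` by the well-stirred prediction computed from the
#' profile's own in vitro half-life, log P and free fraction, and rescales
#' `t_half_term_true` to preserve the identity
#' `t_half_term = log(2) * V_d / CL_p`. With a self-consistent profile and
#' noise switched off, the full extrapolation chain reproduces the in vivo
#' truth exactly (AFE 1, RMSE 0 up to solver tolerance).
#'
#' @param profile A [compound_profile()].
#' @param ctx An [assay_context()].
#' @param sf A [scaling_factors()].
#' @return A modified [compound_profile()].
#' @export
self_consistent_profile <- function(profile, ctx = assay_context(),
                                    sf = scaling_factors()) {
  fm <- microsomal_unbound_fraction(profile$log_p, ctx$protein_conc)
  cl_int <- scale_intrinsic_clearance(profile$t_half_vitro_true, fm, ctx, sf)
  cl_p <- well_stirred_clearance(cl_int, profile$f_p_true, sf$hepatic_blood_flow_q)
  compound_profile(profile$compound_id, profile$log_p,
                   profile$t_half_vitro_true, profile$f_p_true,
                   cl_p_true = cl_p, v_d_true = profile$v_d_true,
                   t_half_term_true = log(2) * profile$v_d_true / cl_p,
                   parent_fraction_anchor = profile$parent_fraction_anchor)
}

#' Noise configuration for the synthetic generators
#'
#' All variability knobs in one place. The defaults describe a plausible
#' small-animal radiotracer study; the source study reports no noise
#' magnitudes, so these are stated assumptions.
#'
#' @param depletion_cv Multiplicative (lognormal) CV on depletion
#'   measurements (default 0.05).
#' @param pf_sd Additive SD on measured parent fractions (default 0.02).
#' @param cl_cv Between-animal lognormal CV on plasma clearance
#'   (default 0.10).
#' @param bw_sd SD of body weight, kg (default 0.044).
#' @param act_sd SD of injected activity, Bq (default 2.5e6).
#' @param amt_sd SD of injected amount, nmol (default 0.20).
#' @param plasma_mass_sd SD of the plasma aliquot mass, g (default 0.01).
#' @param counting If `TRUE` (default), apply Poisson counting noise to
#'   measured activities.
#' @param counts_per_bq Gamma-counter efficiency, counts registered per Bq
#'   of sample activity per second (default 0.5); the counting duration is
#'   part of [study_design()].
#' @param seed Integer seed; required by every generator call.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(depletion_cv = 0.05, pf_sd = 0.02, cl_cv = 0.10,
                         bw_sd = 0.044, act_sd = 2.5e6, amt_sd = 0.20,
                         plasma_mass_sd = 0.01, counting = TRUE,
                         counts_per_bq = 0.5, seed = 1) {
  vals <- c(depletion_cv = depletion_cv, pf_sd = pf_sd, cl_cv = cl_cv,
            bw_sd = bw_sd, act_sd = act_sd, amt_sd = amt_sd,
            plasma_mass_sd = plasma_mass_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_invalid_input("noise magnitudes must be non-negative")
  assert_scalar_positive(counts_per_bq, "counts_per_bq")
  structure(c(as.list(vals), list(counting = isTRUE(counting),
                                  counts_per_bq = counts_per_bq, seed = seed)),
            class = "noise_config")
}

#' Noise-free configuration
#'
#' Convenience wrapper: all SDs and CVs zero, counting noise off. Generators
#' then emit exact model values, so full-pipeline round trips recover the
#' profile truths to solver tolerance.
#'
#' @param seed Integer seed (unused when nothing is random, but kept so the
#'   generator signatures stay uniform).
#' @return A `noise_config`.
#' @export
noise_off <- function(seed = 1) {
  noise_config(depletion_cv = 0, pf_sd = 0, cl_cv = 0, bw_sd = 0, act_sd = 0,
               amt_sd = 0, plasma_mass_sd = 0, counting = FALSE, seed = seed)
}

#' Design constants of the emulated in vivo study
#'
#' Means and structural choices of the synthetic rat study: the arterial
#' sampling grid (dense early, sparse late, over 180 min), population means
#' for body weight (0.503 kg), injected activity (21 MBq) and amount
#' (0.39 nmol), plasma aliquot mass, the fluorine-18 half-life, the
#' depletion sampling times, and the triexponential shape parameters
#' (`lambda1 = lam1_mult * lambda3`, `lambda2 = lam2_mult * lambda3`,
#' amplitude proportions `a_shape`), which are free parameters chosen to
#' produce three visually distinct kinetic phases.
#'
#' @param sampling_times Minutes post injection for plasma sampling.
#' @param depletion_times Minutes for the microsomal assay samples.
#' @param bw_mean Mean body weight, kg.
#' @param act_mean Mean injected activity, Bq.
#' @param amt_mean Mean injected amount, nmol.
#' @param plasma_mass_mean Mean plasma aliquot mass, g.
#' @param isotope_half_life Radionuclide half-life, min (fluorine-18).
#' @param lam1_mult,lam2_mult Rate-constant multipliers relative to the
#'   terminal phase.
#' @param a_shape Relative amplitudes A1:A2:A3 before AUC rescaling.
#' @param spike_bq Range (Bq) of the ultrafiltration plasma spike.
#' @param count_time_s Gamma-counting duration per sample, seconds (applies
#'   to plasma samples and ultrafiltration aliquots alike).
#' @return A list of class `study_design`.
#' @export
study_design <- function(sampling_times = c(1, 2, 3, 5, 7.5, 10, 15, 20, 30,
                                            40, 60, 90, 120, 150, 180),
                         depletion_times = c(0, 2, 5, 10, 15, 20),
                         bw_mean = 0.503, act_mean = 21e6, amt_mean = 0.39,
                         plasma_mass_mean = 0.1, isotope_half_life = 109.77,
                         lam1_mult = 20, lam2_mult = 4,
                         a_shape = c(3, 1, 1/3),
                         spike_bq = c(5000, 6000), count_time_s = 60) {
  if (lam1_mult <= lam2_mult || lam2_mult <= 1)
    stop_config("need lam1_mult > lam2_mult > 1 for three distinct phases")
  structure(list(sampling_times = sampling_times,
                 depletion_times = depletion_times, bw_mean = bw_mean,
                 act_mean = act_mean, amt_mean = amt_mean,
                 plasma_mass_mean = plasma_mass_mean,
                 isotope_half_life = isotope_half_life,
                 lam1_mult = lam1_mult, lam2_mult = lam2_mult,
                 a_shape = a_shape, spike_bq = spike_bq,
                 count_time_s = count_time_s),
            class = "study_design")
}

#' Generate microsomal depletion replicates
#'
#' Emits `remaining(t) = 100 * exp(-log(2) * t / t_half_vitro_true) * eps`
#' with lognormal multiplicative noise of CV `depletion_cv`, renormalized so
#' the t = 0 sample reads exactly 100 (mirroring peak-area-ratio
#' normalization against the t = 0 sample).
#'
#' @param profile A [compound_profile()].
#' @param noise A [noise_config()].
#' @param n_replicates Number of replicates (default 3, a triplicate assay).
#' @param design A [study_design()] (supplies the sampling times).
#' @return List of [depletion_timecourse()] objects.
#' @export
generate_depletion <- function(profile, noise = noise_config(),
                               n_replicates = 3, design = study_design()) {
  if (n_replicates < 1) stop_invalid_input("`n_replicates` must be >= 1")
  t <- design$depletion_times
  true_curve <- 100 * exp(-log(2) * t / profile$t_half_vitro_true)
  sdlog <- sqrt(log(1 + noise$depletion_cv^2))
  with_seed(noise$seed, {
    lapply(seq_len(n_replicates), function(r) {
      eps <- if (sdlog > 0) stats::rlnorm(length(t), -sdlog^2 / 2, sdlog)
             else rep(1, length(t))
      y <- true_curve * eps
      y <- y / y[1] * 100
      depletion_timecourse(profile$compound_id, t, y)
    })
  })
}

# Truth macroconstants for one animal: lambda3 from the terminal half-life,
# faster phases as fixed multiples, amplitudes in the design proportions
# rescaled so the analytic AUC matches the animal's dose over clearance.
triexp_truth <- function(profile, cl_p, d, bw, design) {
  lam3 <- log(2) / profile$t_half_term_true
  lam <- lam3 * c(design$lam1_mult, design$lam2_mult, 1)
  auc <- d / (cl_p * bw)
  u <- design$a_shape
  a <- u * auc / sum(u / lam)
  list(a = a, lam = lam)
}

#' Generate a multi-animal in vivo PK study
#'
#' Builds a ground-truth triexponential parent-concentration curve per animal
#' (terminal rate from the profile's terminal half-life, amplitudes rescaled
#' so that `D / sum(A_i/lambda_i)` equals the animal's clearance) and emits
#' what a gamma counter would actually see: decay-UNcorrected total
#' radioactivity (parent divided by the parent fraction, multiplied by
#' `2^(-t/isotope_half_life)`) in a weighed plasma aliquot, with optional
#' Poisson counting noise. Per-animal clearance varies lognormally around
#' `cl_p_true`; body weight, injected activity and amount are drawn around
#' the design means. Measured parent fractions carry additive noise. The
#' analysis pipeline must undo both corrections to recover the truth.
#'
#' @param profile A [compound_profile()].
#' @param noise A [noise_config()].
#' @param n_animals Number of animals (default 8).
#' @param design A [study_design()].
#' @return List of [animal_study()] objects; each carries its true
#'   per-animal parameters in `attr(, "truth")`.
#' @export
generate_pk_study <- function(profile, noise = noise_config(), n_animals = 8,
                              design = study_design()) {
  if (n_animals < 1) stop_invalid_input("`n_animals` must be >= 1")
  t <- design$sampling_times
  pf_true <- stats::approx(profile$parent_fraction_anchor$times,
                           profile$parent_fraction_anchor$fractions,
                           xout = t, rule = 2)$y
  sdlog_cl <- sqrt(log(1 + noise$cl_cv^2))
  with_seed(noise$seed, {
    lapply(seq_len(n_animals), function(i) {
      bw <- max(stats::rnorm(1, design$bw_mean, noise$bw_sd), 0.2)
      d <- max(stats::rnorm(1, design$act_mean, noise$act_sd), design$act_mean / 10)
      amt <- max(stats::rnorm(1, design$amt_mean, noise$amt_sd), 0.01)
      cl_i <- profile$cl_p_true *
        (if (sdlog_cl > 0) stats::rlnorm(1, -sdlog_cl^2 / 2, sdlog_cl) else 1)
      tru <- triexp_truth(profile, cl_i, d, bw, design)
      parent <- triexp_eval(t, tru$a, tru$lam)
      total <- parent / pf_true
      decayed <- total * 2^(-t / design$isotope_half_life)
      pmass <- pmax(stats::rnorm(length(t), design$plasma_mass_mean,
                                 noise$plasma_mass_sd), 0.01)
      activity <- decayed * pmass
      if (noise$counting) {
        # expected counts = Bq x counter efficiency x counting duration
        cpb <- noise$counts_per_bq * design$count_time_s
        activity <- stats::rpois(length(t), activity * cpb) / cpb
      }
      pf_meas <- pmin(pmax(pf_true + stats::rnorm(length(t), 0, noise$pf_sd),
                           0.005), 1)
      st <- animal_study(
        animal_id = sprintf("%s_%02d", profile$compound_id, i),
        injected_activity = d, injected_amount = amt, body_weight = bw,
        samples = data.frame(time_pi = t, activity_measured = activity,
                             plasma_mass = pmass),
        parent_fractions = data.frame(times = t, fractions = pf_meas),
        isotope_half_life = design$isotope_half_life)
      attr(st, "truth") <- list(cl_p = cl_i, v_d = cl_i / tru$lam[3],
                                t_half_term = log(2) / tru$lam[3],
                                a = tru$a, lam = tru$lam)
      st
    })
  })
}

#' Generate ultrafiltration count pairs
#'
#' Emulates a protein-binding assay: plasma spiked with a few kBq of
#' radiotracer, equal 50-uL volumes of plasma and filtrate counted. Expected
#' filtrate counts are `f_p_true` times the plasma counts; Poisson noise is
#' applied to both when counting noise is on.
#'
#' @param profile A [compound_profile()].
#' @param noise A [noise_config()].
#' @param n_animals Number of animals (default 7).
#' @param design A [study_design()].
#' @return Data frame with columns `animal_id`, `counts_plasma`,
#'   `counts_filtrate`.
#' @export
generate_ultrafiltration <- function(profile, noise = noise_config(),
                                     n_animals = 7, design = study_design()) {
  if (n_animals < 1) stop_invalid_input("`n_animals` must be >= 1")
  with_seed(noise$seed, {
    spike <- stats::runif(n_animals, design$spike_bq[1], design$spike_bq[2])
    # 50 uL counted out of ~250 uL spiked plasma
    expected_plasma <- spike * 0.2 * noise$counts_per_bq * design$count_time_s
    expected_filtrate <- profile$f_p_true * expected_plasma
    if (noise$counting) {
      cp <- stats::rpois(n_animals, expected_plasma)
      cf <- stats::rpois(n_animals, expected_filtrate)
    } else {
      cp <- expected_plasma; cf <- expected_filtrate
    }
    data.frame(animal_id = sprintf("%s_uf%02d", profile$compound_id,
                                   seq_len(n_animals)),
               counts_plasma = cp, counts_filtrate = cf)
  })
}
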