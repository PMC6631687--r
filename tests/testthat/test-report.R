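test_that("table-mode pipeline reproduces the reference accuracy summary", {
  cfg <- pipeline_config(
    "tables", compounds = a1ar_reference_compounds(),
    observed = a1ar_reference_compounds()[c("compound_id", "cl_p_observed")])
  run <- run_ivive(cfg)
  expect_equal(round(run$report$per_compound$fold_error, 2), c(0.84, 0.85, 0.66))
  expect_equal(round(run$report$afe, 2), 0.78)
  expect_equal(round(run$report$fold_underprediction, 1), 1.3)
  expect_equal(round(run$report$rmse, 1), 1.6)
  expect_equal(round(run$stability$f_mic, 2), c(0.90, 0.82, 0.80))
})

test_that("missing compounds are reported as an explicit cross-reference error", {
  comp <- a1ar_reference_compounds()
  obs <- data.frame(compound_id = c("CBX", "MCBX"), cl_p_observed = c(3.22, 9.10))
  expect_error(run_ivive(pipeline_config("tables", compounds = comp, observed = obs)),
               regexp = "CPFPX", class = "ivivepk_invalid_input")
})

test_that("synthetic mode without noise is self-consistent", {
  run <- run_ivive(pipeline_config("synthetic", noise = noise_off(1), n_animals = 2))
  expect_equal(run$report$afe, 1.0, tolerance = 1e-4)
  expect_lt(run$report$rmse, 1e-3)
})

test_that("synthetic mode is reproducible file-for-file", {
  dirs <- file.path(tempfile(), c("a", "b"))
  for (d in dirs)
    run_ivive(pipeline_config("synthetic", noise = noise_config(seed = 8),
                              n_animals = 3, output_dir = d))
  for (f in c("stability_table.csv", "accuracy_report.csv", "pk_parameters.csv"))
    expect_identical(readLines(file.path(dirs[1], f)),
                     readLines(file.path(dirs[2], f)))
})

test_that("rank ordering reproduces the stability and clearance orderings", {
  th <- rank_order(c("CBX", "MCBX", "CPFPX"), c(35.1, 19.8, 14.0))
  expect_equal(th$compound_id, c("CBX", "MCBX", "CPFPX"))
  cl <- rank_order(c("CBX", "MCBX", "CPFPX"), c(2.72, 7.76, 4.70),
                   descending = FALSE)
  expect_equal(cl$compound_id, c("CBX", "CPFPX", "MCBX"))
  expect_equal(rank_order("X", 5)$compound_id, "X")
  ties <- rank_order(c("a", "b", "c"), c(1, 1, 1))
  expect_equal(ties$compound_id, c("a", "b", "c"))
})

test_that("CSV interfaces round-trip the generated datasets", {
  pr <- a1ar_profiles()$MCBX
  tcs <- generate_depletion(pr, noise_config(seed = 2), n_replicates = 3)
  p <- tempfile(fileext = ".csv")
  write_depletion_csv(tcs, p)
  back <- read_depletion_csv(p)
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$remaining, tcs[[2]]$remaining)

  st <- generate_pk_study(pr, noise_config(seed = 2), n_animals = 2)
  paths <- replicate(3, tempfile(fileext = ".csv"))
  write_pk_study_csv(st, paths[1], paths[2], paths[3])
  st2 <- read_pk_study_csv(paths[1], paths[2], paths[3])
  expect_equal(st2[[1]]$samples$activity_measured,
               st[[1]]$samples$activity_measured)
  expect_equal(st2[[2]]$body_weight, st[[2]]$body_weight)
  expect_equal(corrected_plasma_curve(st2[[1]])$conc,
               corrected_plasma_curve(st[[1]])$conc)

  cfgp <- tempfile(fileext = ".cfg")
  writeLines(c("protein_conc = 0.25", "# comment", "hepatic_blood_flow_q: 70",
               "label = rat"), cfgp)
  kv <- read_kv_config(cfgp)
  expect_equal(kv$protein_conc, 0.25)
  expect_equal(kv$hepatic_blood_flow_q, 70)
  expect_equal(kv$label, "rat")
})
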