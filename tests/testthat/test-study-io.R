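test_that("measurement sets round-trip losslessly through CSV + YAML", {
  vp <- reference_vp()
  dir <- withr::local_tempdir()
  write_measurement_set(vp$dataset, dir)
  back <- read_measurement_set(dir)
  expect_equal(back$time, vp$dataset$time, tolerance = 1e-9)
  expect_equal(back$strain, vp$dataset$strain, tolerance = 1e-9)
  expect_equal(back$HR, vp$dataset$HR)
  expect_equal(back$EDV, vp$dataset$EDV, tolerance = 1e-9)
  expect_equal(back$EF, vp$dataset$EF, tolerance = 1e-9)
  expect_equal(back$RVD, vp$dataset$RVD, tolerance = 1e-9)
})

test_that("reader validates schema strictly", {
  vp <- reference_vp()
  dir <- withr::local_tempdir()
  write_measurement_set(vp$dataset, dir)

  # missing segment column is named in the error
  df <- utils::read.csv(file.path(dir, "strain.csv"))
  utils::write.csv(df[, setdiff(names(df), "IVS")],
                   file.path(dir, "strain.csv"), row.names = FALSE)
  expect_error(read_measurement_set(dir), "IVS")

  # EF out of range in the sidecar
  write_measurement_set(vp$dataset, dir)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  meta$EF <- 1.2
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  expect_error(read_measurement_set(dir), "EF")

  expect_error(read_measurement_set(file.path(dir, "nope")), "missing")
})

test_that("virtual patients are self-consistent and reproducible", {
  vp <- reference_vp()
  # the defining property: the generating parameters fit their own dataset
  mo <- simulate_heart(vp$true_theta, HR = vp$dataset$HR)
  expect_equal(compute_error_terms(mo, vp$dataset)$X2, 0, tolerance = 1e-18)

  vp2 <- reference_vp()
  expect_identical(vp$dataset$strain, vp2$dataset$strain)

  # noise extension is seeded and off by default
  th <- vp$true_theta
  vpn1 <- generate_virtual_patient(th, 71, noise_sd = 0.01, seed = 4)
  vpn2 <- generate_virtual_patient(th, 71, noise_sd = 0.01, seed = 4)
  expect_identical(vpn1$dataset$strain, vpn2$dataset$strain)
  expect_gt(compute_error_terms(mo, vpn1$dataset)$X2, 0)

  presets <- virtual_patient_presets()
  expect_named(presets, c("healthy", "early", "overt"))
  for (p in presets) expect_silent(validate_parameters(
    default_parameter_space(), p))
})

test_that("maximum-likelihood sample selection follows the tie rules", {
  fake <- list(X2 = c(3, 1, 2), iteration = c(0L, 1L, 2L))
  expect_equal(select_max_likelihood_sample(fake), 2)
  tie <- list(X2 = c(2, 1, 1), iteration = c(0L, 2L, 1L))
  expect_equal(select_max_likelihood_sample(tie), 3)
  expect_error(select_max_likelihood_sample(list(X2 = c(Inf, Inf),
                                                 iteration = c(0L, 1L))),
               "finite")
  # agrees with a brute-force scan
  set.seed(51)
  X2 <- sample(c(runif(50, 1, 9), Inf))
  fake2 <- list(X2 = X2, iteration = seq_along(X2))
  expect_equal(select_max_likelihood_sample(fake2), which.min(X2))
})

test_that("sample sets persist and reload", {
  vp <- reference_vp()
  cfg <- amis_config(n_samples_per_iter = 10, min_iterations = 3,
                     max_iterations = 3, seed = 2)
  res <- amis_estimate(vp$dataset, config = cfg)
  dir <- withr::local_tempdir()
  write_sample_set(res, dir)
  back <- read_sample_set(dir)
  expect_equal(nrow(back$samples), 30)
  expect_equal(back$samples$weight_T1, res$weight, tolerance = 1e-12)
  expect_equal(back$samples$SfAct_RVbase, res$theta$SfAct_RVbase,
               tolerance = 1e-12)
  expect_equal(nrow(back$trace), 3)

  report <- run_report(res)
  expect_equal(sum(grepl("^\\| (SfAct|k1|dT|AmRef|RSD|Q0)", report)), 20)
})

test_that("the CLI front end is reproducible and fails loudly", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  code1 <- cardamis_cli(c("virtual-patient", "--preset", "healthy",
                          "--seed", "7", "--out", out1))
  code2 <- cardamis_cli(c("virtual-patient", "--preset", "healthy",
                          "--seed", "7", "--out", out2))
  expect_identical(code1, 0L)
  expect_identical(code2, 0L)
  expect_identical(readLines(file.path(out1, "strain.csv")),
                   readLines(file.path(out2, "strain.csv")))
  expect_true(file.exists(file.path(out1, "true_parameters.csv")))

  expect_identical(cardamis_cli(c("fit", "--data", "/no/such/dir",
                                  "--out", out1)), 2L)
  expect_identical(suppressMessages(cardamis_cli(character(0))), 2L)
  expect_identical(cardamis_cli(c("virtual-patient", "--preset", "zebra",
                                  "--out", out1)), 2L)
})
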