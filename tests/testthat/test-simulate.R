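test_that("generation is seed-deterministic down to the CSV bytes", {
  c1 <- generate_cohort(seed = 5)
  c2 <- generate_cohort(seed = 5)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(c1, p1)
  write_cohort_csv(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  c3 <- generate_cohort(seed = 6)
  expect_false(identical(c1$psa_total, c3$psa_total))
})

test_that("generated cohorts always satisfy the cohort invariants", {
  for (seed in 1:3) {
    co <- generate_cohort(seed = seed)
    expect_equal(nrow(validate_cohort(co)), 0)
    expect_equal(nrow(co), 357)
  }
})

test_that("n_scale pro-rates the group sizes with documented rounding", {
  co <- generate_cohort(seed = 9, n_scale = 0.1)
  # round(c(174,34,74,75) * 0.1) = 17, 3, 7, 8
  pr <- profile_cohort(co)
  expect_equal(as.integer(table(pr$gs_group)), c(17L, 3L, 7L, 8L))
  expect_equal(nrow(co), 35)
  big <- generate_cohort(seed = 9, n_scale = 2)
  expect_equal(nrow(big), 714)
})

test_that("a zero-correlation copula yields independent serum markers", {
  config <- default_config()
  config$latent_corr <- diag(3)
  dimnames(config$latent_corr) <- dimnames(default_config()$latent_corr)
  co <- generate_cohort(config, seed = 10, n_scale = 28) # ~10^4
  # within the benign group (no mixture-induced association)
  ben <- co[co$pathology == "benign", ]
  tau <- kendall_tau_b(psa_level(ben$psa_total), ft_level(ben$ft_ratio))
  expect_lt(abs(tau), 0.03)
})

test_that("invalid configurations are rejected at construction", {
  config <- default_config()
  config$latent_corr[1, 2] <- 2 # asymmetric and out of range
  expect_error(generate_cohort(config, seed = 1), class = "psc_domain_error")
  config2 <- default_config()
  config2$groups$pirads_probs[[1]] <- rep(0.5, 5)
  expect_error(generate_cohort(config2, seed = 1), class = "psc_domain_error")
  expect_error(generate_cohort(seed = 1, n_scale = 0), class = "psc_domain_error")
})

test_that("the censoring flag exercises the sentinel pathway end to end", {
  co <- generate_cohort(default_config(censor_frac = 0.1), seed = 11)
  cens <- co$psa_censored_high
  expect_gt(sum(cens), 10)
  expect_true(all(co$ft_ratio[cens] == 0.001))
  expect_true(all(co$psa_total[cens] == 1000))
  pr <- profile_cohort(co)
  expect_true(all(pr$ft_level[cens] == 4L))
  expect_true(all(pr$psa_level[cens] == 4L))
  # round-trips through CSV with the sentinel intact
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  expect_equal(read_cohort_csv(path)$ft_ratio[cens],
               rep(0.001, sum(cens)))
})

test_that("calibration report flags a deliberately detuned generator", {
  ok <- calibration_report(generate_cohort(seed = 12, n_scale = 3))
  tau_rows <- grepl("tau", ok$metric)
  expect_true(all(ok$within[tau_rows]))
  config <- default_config()
  config$latent_corr <- diag(3)
  config$groups$psa_meanlog <- rep(1.0, 4) # grossly miscalibrated PSA
  bad <- calibration_report(generate_cohort(config, seed = 12, n_scale = 3),
                            config)
  expect_false(all(bad$within[grepl("psa_median|tau", bad$metric)]))
})

test_that("raising a group's PSA location raises its mean PSA level", {
  config <- default_config()
  config$groups$psa_meanlog[1] <- config$groups$psa_meanlog[1] + 0.5
  lo <- generate_cohort(seed = 13, n_scale = 3)
  hi <- generate_cohort(config, seed = 13, n_scale = 3)
  mean_l1 <- function(co) {
    pr <- profile_cohort(co)
    mean(pr$psa_level[pr$gs_group == 1])
  }
  expect_gt(mean_l1(hi), mean_l1(lo))
})
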