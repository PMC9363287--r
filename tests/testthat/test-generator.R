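# --- loading calibration ---------------------------------------------------

test_that("calibrate_loadings inverts the composite-reliability formula", {
  expect_equal(calibrate_loadings(0.63, 4), 0.5464, tolerance = 1e-4)
  expect_equal(calibrate_loadings(0.70, 2), 0.7338, tolerance = 1e-4)
  # round trip: CR of k equal loadings equals the target to 1e-12
  for (cr in c(0.3, 0.63, 0.7, 0.9)) for (k in c(2, 4, 6)) {
    l <- calibrate_loadings(cr, k)
    expect_equal(construct_reliability(rep(l, k)), cr, tolerance = 1e-12)
  }
  # CR -> 1 pushes the loading to 1
  expect_gt(calibrate_loadings(1 - 1e-9, 5), 0.999)
  expect_error(calibrate_loadings(1, 4), "strictly")
  expect_error(calibrate_loadings(0.6, 1), "at least 2")
})

# --- generating parameters -------------------------------------------------

test_that("generating parameters encode unit-variance bookkeeping", {
  gp <- build_generating_parameters(generator_config())
  psi <- gp$params$psi
  expect_equal(psi["Fibrosis", "Fibrosis"], 1 - 0.74^2)      # 0.4524
  expect_equal(psi["InflOxStress", "InflOxStress"], 1 - 0.29^2) # 0.9159
  expect_equal(psi["Myocardium", "Myocardium"], 1 - 0.65^2)
  # implied covariance is a proper correlation matrix
  Sig <- implied_covariance(gp$params)$values
  expect_equal(unname(diag(Sig)), rep(1, 14), tolerance = 1e-12)
  expect_true(all(eigen(Sig, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("zero paths give a block-diagonal implied covariance", {
  cfg <- generator_config(sel_to_io = 0, io_to_fib = 0, io_to_myo = 0,
                          so_infl = 0, so_ox = 0, age_link_d = 0)
  Sig <- implied_covariance(build_generating_parameters(cfg)$params)$values
  m <- panel_sem_model()
  for (f1 in names(m$factors)) for (f2 in names(m$factors)) {
    if (f1 != f2)
      expect_equal(max(abs(Sig[m$factors[[f1]], m$factors[[f2]]])), 0)
  }
})

test_that("config validation rejects out-of-range values and unknown keys", {
  expect_error(generator_config(mortality_placebo = 1.5), "rate")
  expect_error(generator_config(not_a_key = 1), "unknown generator_config key")
  expect_error(generator_config(cr_infl = 1.2), "0, 1")
  expect_error(generator_config(sel_to_io = -0.9, age_link_d = 0.6), "< 1")
  expect_error(generator_config(mode = "case-control"), "rct")
})

# --- baseline simulation ---------------------------------------------------

test_that("baseline simulation is seed-deterministic to the byte", {
  cfg <- generator_config()
  b1 <- simulate_baseline(cfg, n = 300, seed = 9)
  b2 <- simulate_baseline(cfg, n = 300, seed = 9)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(b1, f1); write_cohort(b2, f2)
  expect_identical(readLines(f1), readLines(f2))
  b3 <- simulate_baseline(cfg, n = 300, seed = 10)
  expect_false(identical(b1$selenium_ugL, b3$selenium_ugL))
})

# one larger baseline shared by the calibration checks below
cfg_big <- generator_config()
base_big <- simulate_baseline(cfg_big, n = 50000, seed = 4711)

test_that("baseline marginals hit the configured calibration", {
  expect_equal(mean(base_big$selenium_ugL), 67.1, tolerance = 0.5 / 67.1)
  expect_equal(cor(base_big$selenium_ugL, base_big$age_years), -0.13,
               tolerance = 0.03 / 0.13)
  expect_true(all(base_big$age_years >= 70 & base_big$age_years <= 88))
  expect_true(all(as.matrix(base_big[, panel_markers()]) > 0))
})

test_that("log-indicator correlations converge to the implied matrix", {
  gp <- build_generating_parameters(cfg_big)
  tab <- sel_age_quotient(preprocess(base_big))$table
  vars <- gp$model$manifest
  emp <- cor(tab[, vars])
  expect_lt(max(abs(emp - implied_covariance(gp$params)$values)), 0.02)
})

test_that("about half the markers carry age correlations in the stated band", {
  tab <- preprocess(base_big)
  ra <- cor(tab[, panel_markers()], tab$age_years)[, 1]
  linked <- names(ra)[abs(ra) >= 0.18]
  expect_gte(length(linked), 6)
  expect_lte(length(linked), 8)
  expect_true(all(ra[linked] > 0.18 & ra[linked] < 0.37))
  expect_equal(mean(ra[linked]), 0.25, tolerance = 0.05 / 0.25)
})

# --- follow-up -------------------------------------------------------------

test_that("retest correlations of within-factor scores equal the configured rho", {
  cfg0 <- generator_config(
    shift_placebo_infl = 0, shift_placebo_ox = 0, shift_placebo_fib = 0,
    shift_placebo_myo = 0, shift_active_infl = 0, shift_active_ox = 0,
    shift_active_fib = 0, shift_active_myo = 0)
  b <- simulate_baseline(cfg0, n = 50000, seed = 31)
  f <- simulate_followup(cfg0, b, seed = 32)
  m <- panel_cfa_model()
  l1 <- log(as.matrix(as.data.frame(b)[, panel_markers()]))
  l2 <- log(as.matrix(as.data.frame(f)[, panel_markers()]))
  rho <- c(Inflammation = 0.57, OxStress = 0.67, Fibrosis = 0.76)
  for (fac in names(rho)) {
    c1 <- rowMeans(scale(l1[, m$factors[[fac]], drop = FALSE]))
    c2 <- rowMeans(scale(l2[, m$factors[[fac]], drop = FALSE]))
    expect_equal(cor(c1, c2), rho[[fac]], tolerance = 0.02 / rho[[fac]])
  }
  # every single marker also retests at its factor's rho
  for (fac in names(rho)) for (j in m$factors[[fac]])
    expect_equal(cor(l1[, j], l2[, j]), rho[[fac]],
                 tolerance = 0.03 / rho[[fac]])
})

test_that("rho = 1 with zero shifts reproduces the baseline exactly", {
  cfg1 <- generator_config(
    retest_infl = 1, retest_ox = 1, retest_fib = 1, retest_myo = 1,
    shift_placebo_infl = 0, shift_placebo_ox = 0, shift_placebo_fib = 0,
    shift_placebo_myo = 0, shift_active_infl = 0, shift_active_ox = 0,
    shift_active_fib = 0, shift_active_myo = 0)
  b <- simulate_baseline(cfg1, n = 200, seed = 13)
  f <- simulate_followup(cfg1, b, seed = 14)
  expect_equal(as.data.frame(f)[, panel_markers()],
               as.data.frame(b)[, panel_markers()], tolerance = 1e-12)
})

test_that("arm shifts move the latent means in the configured directions", {
  cfg <- generator_config()
  b <- simulate_baseline(cfg, n = 20000, seed = 15)
  f <- simulate_followup(cfg, b, seed = 16)
  lat2 <- attr(f, "latents")
  pl <- b$arm == "placebo"
  expect_gt(mean(lat2$Inflammation[pl]), mean(lat2$Inflammation[!pl]))
  expect_gt(mean(lat2$Fibrosis[pl]), mean(lat2$Fibrosis[!pl]))
})

test_that("follow-up refuses a table without generator provenance", {
  cfg <- generator_config()
  b <- simulate_baseline(cfg, n = 50, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_cohort(b, path)
  suppressMessages(reread <- read_cohort(path))  # CSV strips true latents
  expect_error(simulate_followup(cfg, reread), "simulate_baseline")
})

# --- mortality -------------------------------------------------------------

test_that("mortality rates honour arm and boundary configurations", {
  cfg <- generator_config()
  b <- simulate_baseline(cfg, n = 4000, seed = 17)
  withr <- simulate_mortality(cfg, b, seed = 18)
  expect_true(all(withr$cv_death_5y %in% 0:1))
  cfg0 <- generator_config(mortality_active = 0, mortality_placebo = 0)
  none <- simulate_mortality(cfg0, b, seed = 18)
  expect_equal(sum(none$cv_death_5y), 0)
  noarm <- as.data.frame(b)
  noarm$arm <- "none"
  expect_error(simulate_mortality(cfg, as_cohort_table(noarm, cfg, 1)),
               "requires arm")
})

test_that("death counts are binomial at the configured rates across seeds", {
  cfg <- generator_config()
  b <- simulate_baseline(cfg, n = 2000, seed = 19)
  n_pl <- sum(b$arm == "placebo")
  x2 <- sapply(1:25, function(s) {
    d <- simulate_mortality(cfg, b, seed = 100 + s)
    k <- sum(d$cv_death_5y[d$arm == "placebo"])
    (k - n_pl * 0.126)^2 / (n_pl * 0.126 * (1 - 0.126))
  })
  # each squared standardized deviate ~ chi^2_1; none should blow past
  # the alpha = 0.001 critical value in 25 tries more than once
  expect_lte(sum(x2 > qchisq(0.999, 1)), 1)
})

test_that("observational quartile rates interpolate the printed extremes", {
  cfg <- generator_config(mode = "observational")
  b <- simulate_baseline(cfg, n = 200000, seed = 23)
  d <- simulate_mortality(cfg, b, seed = 24)
  qi <- cohortsem:::selenium_quartile(d$selenium_ugL)
  expect_equal(mean(d$cv_death_5y[qi == 1]), 29 / 107, tolerance = 0.02)
  expect_equal(mean(d$cv_death_5y[qi == 4]), 16 / 111, tolerance = 0.03)
  r2 <- mean(d$cv_death_5y[qi == 2])
  expect_gt(r2, 16 / 111); expect_lt(r2, 29 / 107)
})
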