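# Simultaneous multi-contrast fitting.

truth_unloaded <- c(core_radius = 200, shell_thickness = 15,
                    polydispersity = 0.2, hydration = 0.5,
                    volume_fraction = 0.009)

test_that("build_problem populates fixed SLDs from contrast labels", {
  pr <- build_problem(simulate_scenario(lnc_scenarios(noise_pct = 0)$unloaded))
  cores <- vapply(pr$datasets, `[[`, numeric(1), "sld_core")
  solvs <- vapply(pr$datasets, `[[`, numeric(1), "sld_solvent")
  expect_equal(unique(round(cores, 2)), c(0.15, 0.43))
  expect_equal(unique(round(solvs, 2)), c(-0.56, 6.37))
  expect_equal(pr$dry_shell, rep(0.13, 4))
  # a single dataset is a valid problem
  d1 <- simulate_dataset(lnc_scenarios(noise_pct = 0)$unloaded, 2)
  expect_s3_class(build_problem(d1), "sas_fit_problem")
  # unknown contrast labels are rejected when SLDs are absent
  bad <- d1; bad$contrast_label <- "mystery"; bad$sld_core <- NA_real_
  expect_error(build_problem(bad), "contrast label")
  expect_error(build_problem(d1, shared_free = "banana"), "unknown shared")
  expect_error(build_problem(d1, shared_free = "core_radius"), "neither free nor fixed")
})

test_that("noise-free 4-contrast data are recovered to optimizer precision", {
  pr <- build_problem(simulate_scenario(lnc_scenarios(noise_pct = 0)$unloaded))
  fit <- sas_fit(pr, seed = 1)
  expect_lt(fit$chi2_reduced, 1e-6)
  for (nm in names(truth_unloaded))
    expect_rel(fit$estimates[[nm]], truth_unloaded[[nm]], 1e-3)
  expect_equal(fit$estimates[["background.1"]], 0.8, tolerance = 1e-3)
  expect_equal(fit$estimates[["background.2"]], 0.06, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_false(any(fit$at_bound[names(truth_unloaded)]))
  # derived block: total radius is the exact sum
  expect_equal(fit$derived$total_radius,
               fit$estimates[["core_radius"]] + fit$estimates[["shell_thickness"]])
})

test_that("noisy recovery is calibrated: truth inside 95% intervals", {
  pr <- build_problem(simulate_scenario(lnc_scenarios(noise_pct = 3)$unloaded))
  fit <- sas_fit(pr, seed = 1234)
  expect_gt(fit$chi2_reduced, 0.5)
  expect_lt(fit$chi2_reduced, 2)
  for (nm in names(truth_unloaded)) {
    z <- abs(fit$estimates[[nm]] - truth_unloaded[[nm]]) / fit$uncertainties[[nm]]
    expect_lt(z, 1.96)
  }
  # tight relative accuracy on the well-determined parameters
  expect_rel(fit$estimates[["core_radius"]], 200, 0.01)
  expect_rel(fit$estimates[["polydispersity"]], 0.2, 0.05)
  expect_rel(fit$estimates[["volume_fraction"]], 0.009, 0.05)
})

test_that("fits are deterministic given the seed", {
  pr <- build_problem(simulate_scenario(lnc_scenarios(noise_pct = 3)$unloaded))
  f1 <- sas_fit(pr, seed = 7, n_starts = 2)
  f2 <- sas_fit(pr, seed = 7, n_starts = 2)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$covariance, f2$covariance)
})

test_that("an uninformative zero-contrast dataset leaves estimates unchanged", {
  sets <- simulate_scenario(lnc_scenarios(noise_pct = 0)$unloaded)
  # all three SLDs equal: the model is pure background whatever the structure
  qs <- sets[[1]]$q
  flat <- sas_dataset(qs, rep(0.05, length(qs)),
                      rep(1e-3, length(qs)), contrast_label = "null",
                      sld_solvent = 0.13, sld_core = 0.13)
  pr0 <- build_problem(sets)
  pr1 <- build_problem(c(sets, list(flat)))
  f0 <- sas_fit(pr0, seed = 3, n_starts = 1, start = truth_unloaded)
  f1 <- sas_fit(pr1, seed = 3, n_starts = 1, start = truth_unloaded)
  for (nm in names(truth_unloaded))
    expect_rel(f1$estimates[[nm]], f0$estimates[[nm]], 1e-6)
})

test_that("derived quantities follow the mixing rule and concentration arithmetic", {
  pr <- build_problem(simulate_scenario(lnc_scenarios(noise_pct = 0)$unloaded))
  fit <- sas_fit(pr, seed = 1, n_starts = 1, start = truth_unloaded)
  d <- fit$derived
  # shell SLD in D2O at 50% hydration: mix of dry 0.13 and the solvent
  i_d2o <- which(vapply(pr$datasets, `[[`, character(1), "contrast_label") ==
                   "h-core/D2O")
  expect_equal(unname(d$shell_sld_per_contrast[i_d2o]),
               mix_sld(c(0.13, solvent_sld(1)), c(0.5, 0.5)), tolerance = 1e-6)
  expect_equal(d$hydration_pct, 50, tolerance = 0.1)
  # theoretical volume fraction from concentration at 1.0 g/mL density
  expect_equal(d$theoretical_volume_fraction, 6.2 / 1000)
  dq62 <- derived_quantities(fit, pr)
  expect_equal(dq62$total_radius_se^2,
               fit$covariance["core_radius", "core_radius"] +
                 fit$covariance["shell_thickness", "shell_thickness"] +
                 2 * fit$covariance["core_radius", "shell_thickness"],
               tolerance = 1e-10)
})

test_that("a contrast-matched core collapses the core-radius information", {
  scs <- lnc_scenarios(noise_pct = 3)
  pr4 <- build_problem(simulate_scenario(scs$unloaded))
  prm <- build_problem(simulate_scenario(scs$matched_core))
  nuis4 <- c(background.1 = 0.8, background.2 = 0.06,
             background.3 = 0.8, background.4 = 0.06)
  c4 <- parameter_covariance(pr4, c(truth_unloaded, nuis4))
  cm <- parameter_covariance(prm, c(truth_unloaded, background.1 = 0.1))
  infl <- sqrt(cm["core_radius", "core_radius"] /
                 c4["core_radius", "core_radius"])
  expect_gt(infl, 3)
})

test_that("scenario battery flags consistency and a shifted truth", {
  scs <- lnc_scenarios(noise_pct = 3)
  free4 <- c("core_radius", "shell_thickness", "polydispersity",
             "volume_fraction")
  probs <- lapply(scs$dilution, function(s)
    build_problem(simulate_scenario(s), shared_free = free4,
                  fixed = list(hydration = 0.5)))
  bat <- scenario_battery(probs, seed = 3)
  expect_true(bat$consistent)
  expect_gt(bat$phi_r2, 0.99)
  # a scenario with a +20% core radius must be flagged
  shifted <- scs$dilution[[2]]
  shifted$truth$core_radius <- 240
  probs2 <- probs
  probs2[[2]] <- build_problem(simulate_scenario(shifted), shared_free = free4,
                               fixed = list(hydration = 0.5))
  bat2 <- scenario_battery(probs2, seed = 3)
  expect_false(bat2$agreement[["core_radius"]])
  expect_error(
    scenario_battery(list(probs[[1]],
                          build_problem(probs[[2]]$datasets,
                                        shared_free = c(free4, "hydration")))),
    "incompatible")
})
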