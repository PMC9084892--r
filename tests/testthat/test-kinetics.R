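test_that("one-site simulation obeys its closed-form limits", {
  p <- one_site_kinetics(1e5, 1e-2, 1.2)
  expect_equal(p$kd, 1e-2 / 1e5)
  times <- seq(0, 600, by = 1)
  # no analyte: flat zero throughout association
  expect_equal(simulate_one_site(p, 0, times), rep(0, length(times)))
  # at conc = kd the association plateau is rmax / 2
  r <- simulate_one_site(p, p$kd, 1e5)
  expect_equal(r, p$rmax / 2, tolerance = 1e-10)
  expect_error(simulate_one_site(p, 1e-6, c(-1, 0)), "negative times")
  expect_error(one_site_kinetics(-1, 1, 1), "> 0")
})

test_that("simulation matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- one_site_kinetics(1e5, 1e-2, 1)
  conc <- 1e-6
  times <- seq(0, 10, by = 0.5)
  ode <- deSolve::ode(
    y = c(R = 0), times = times,
    func = function(t, y, parms) {
      list(p$kon * conc * (p$rmax - y[1]) - p$koff * y[1])
    }, method = "lsoda", rtol = 1e-12, atol = 1e-14)
  expect_equal(simulate_one_site(p, conc, times), unname(ode[, "R"]),
               tolerance = 1e-8)
})

test_that("association and dissociation phases are monotone and bounded", {
  p <- one_site_kinetics(2e5, 5e-3, 1)
  for (conc in c(1e-8, 1e-7, 1e-6)) {
    t_all <- seq(0, 900, by = 1)
    r <- simulate_one_site(p, conc, t_all, t_dissoc = 300)
    req <- p$rmax * conc / (conc + p$kd)
    assoc <- r[t_all <= 300]
    dissoc <- r[t_all > 300]
    expect_true(all(diff(assoc) >= -1e-15))
    expect_true(all(assoc <= req + 1e-12))
    expect_true(all(diff(dissoc) <= 1e-15))
    expect_true(all(dissoc >= 0))
  }
})

test_that("double referencing is exact algebra on aligned grids", {
  p <- one_site_kinetics(1e5, 1e-2, 1)
  g <- gen_sensorgrams(p, noise_sd = 0, drift = 1e-3, seed = 5)
  raw <- g$samples[[3L]]
  iref <- g$internal_refs[[3L]]
  pref <- g$parallel_refs[[3L]]
  zero <- sensorgram(raw$construct, 0, raw$time, rep(0, length(raw$time)),
                     raw$assoc_window, raw$dissoc_window)
  # all references zero: corrected equals raw
  expect_equal(double_reference(raw, zero, zero, zero)$response,
               raw$response)
  # raw equal to internal reference: minus the parallel difference
  expect_equal(double_reference(iref, iref, pref, zero)$response,
               -(pref$response - 0))
  # drift-only internal reference removes the constructed drift exactly
  truth_signal <- simulate_one_site(p, raw$conc, raw$time, t_dissoc = 300)
  corrected <- double_reference(raw, iref, NULL)
  expect_equal(corrected$response, truth_signal, tolerance = 1e-12)
})

test_that("referencing is invariant to a common drift term", {
  p <- one_site_kinetics(1e5, 1e-2, 1)
  g <- gen_sensorgrams(p, noise_sd = 0, seed = 6)
  raw <- g$samples[[1L]]
  iref <- g$internal_refs[[1L]]
  common <- 0.002 * raw$time
  raw2 <- raw; raw2$response <- raw$response + common
  iref2 <- iref; iref2$response <- iref$response + common
  expect_equal(double_reference(raw, iref)$response,
               double_reference(raw2, iref2)$response, tolerance = 1e-12)
})

test_that("global fit is the identity on noiseless one-site data", {
  p <- one_site_kinetics(1e5, 1e-2, 1)
  g <- gen_sensorgrams(p, noise_sd = 0, seed = 2)
  fit <- fit_global_kinetics(g$samples)
  expect_equal(fit$kon, p$kon, tolerance = 1e-6)
  expect_equal(fit$koff, p$koff, tolerance = 1e-6)
  expect_equal(fit$kd, fit$koff / fit$kon)  # exact identity
  expect_false(fit$lack_of_fit)
})

test_that("1% noise keeps rate estimates within 5% with small fit errors", {
  p <- one_site_kinetics(1e5, 1e-2, 1)
  g <- gen_sensorgrams(p, noise_sd = 0.01, seed = 8)
  fit <- fit_global_kinetics(g$samples)
  expect_lt(abs(fit$kon / p$kon - 1), 0.05)
  expect_lt(abs(fit$koff / p$koff - 1), 0.05)
  # relative fit errors in the instrument's reported 1-5% regime
  expect_lt(fit$rel_se[["kon"]], 0.05)
  expect_lt(fit$rel_se[["koff"]], 0.05)
  expect_false(fit$lack_of_fit)
})

test_that("a 50/50 two-species mixture trips the lack-of-fit diagnostics", {
  p <- one_site_kinetics(1e5, 1e-2, 1)
  g_mix <- gen_sensorgrams(p, noise_sd = 0.01, het_fraction = 0.5,
                           het_koff_factor = 10, seed = 8)
  g_one <- gen_sensorgrams(p, noise_sd = 0.01, seed = 8)
  f_mix <- fit_global_kinetics(g_mix$samples)
  f_one <- fit_global_kinetics(g_one$samples)
  expect_true(f_mix$lack_of_fit)
  expect_false(f_one$lack_of_fit)
  # with noise below the model misfit the residual excess is > 3x the
  # matched one-site dataset
  g_mix_lo <- gen_sensorgrams(p, noise_sd = 0.001, het_fraction = 0.5,
                              het_koff_factor = 10, seed = 9)
  g_one_lo <- gen_sensorgrams(p, noise_sd = 0.001, seed = 9)
  f_mix_lo <- fit_global_kinetics(g_mix_lo$samples)
  f_one_lo <- fit_global_kinetics(g_one_lo$samples)
  expect_gt(f_mix_lo$residual_rms / f_one_lo$residual_rms, 3)
})

test_that("fit validates the concentration design", {
  p <- one_site_kinetics(1e5, 1e-2, 1)
  g <- gen_sensorgrams(p, concs = c(1e-7, 2e-7), noise_sd = 0, seed = 1)
  expect_error(fit_global_kinetics(g$samples), ">= 3 distinct")
  g2 <- gen_sensorgrams(p, concs = c(1e-7, 1.5e-7, 2e-7), noise_sd = 0,
                        seed = 1)
  expect_warning(fit_global_kinetics(g2$samples), "3-fold")
})

test_that("fold-change summary: identities, means, missing baselines", {
  panel <- data.frame(construct = c("a", "a", "b", "b"),
                      nacl = c(150, 10, 150, 10),
                      kon = c(1e5, 1e6, 2e5, 8e6),
                      koff = c(1e-2, 1e-2, 2e-2, 2e-2),
                      kd = c(1e-7, 1e-8, 1e-7, 2.5e-9))
  fc <- fold_change_summary(panel)
  base_rows <- fc$ratios[fc$ratios$nacl == 150, ]
  expect_true(all(base_rows$kon_ratio == 1))
  low <- fc$summary[fc$summary$nacl == 10, ]
  expect_equal(low$kon_fold_geomean, sqrt(10 * 40))  # 20.0
  expect_equal(low$kon_fold_mean, 25.0)
  expect_error(
    fold_change_summary(data.frame(construct = "c", nacl = 10, kon = 1,
                                   koff = 1, kd = 1)),
    "missing the baseline")
})

test_that("a panel built around a 17-fold on-rate shift is summarized faithfully", {
  # four constructs, kon(10 mM) / kon(150 mM) drawn around 17
  set.seed(123)
  folds <- 17 * exp(rnorm(4, 0, 0.15))
  panel <- do.call(rbind, lapply(1:4, function(i) {
    kon0 <- 10^runif(1, 4.5, 5.5)
    koff <- 10^runif(1, -2.5, -1.5)
    data.frame(construct = paste0("c", i), nacl = c(150, 10),
               kon = c(kon0, kon0 * folds[i]), koff = koff,
               kd = koff / c(kon0, kon0 * folds[i]))
  }))
  fc <- fold_change_summary(panel)
  gm <- fc$summary$kon_fold_geomean[fc$summary$nacl == 10]
  expect_equal(gm, exp(mean(log(folds))), tolerance = 1e-12)
  expect_equal(gm, 17, tolerance = 0.2)
})
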