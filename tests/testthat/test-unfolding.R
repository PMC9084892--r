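test_that("state free energies are linear in urea with N as reference", {
  sh <- list(sN = 0, sI = 0, sD = 0, mI = -2.35, mD = -1.8)
  co <- list(bN = 1, bI = 1, bD = 1, dG_I0 = 4.7, dG_D0 = 10.0)
  g0 <- state_free_energies(co, sh, 0)
  expect_identical(g0$dG_N, 0)
  expect_equal(g0$dG_I, 4.7)
  g2 <- state_free_energies(co, sh, 2.0)
  expect_equal(g2$dG_I, 0.0)
  sh2 <- list(mI = -2.0, mD = -1.8, sN = 0, sI = 0, sD = 0)
  co2 <- list(dG_I0 = 4.0, dG_D0 = 10.0, bN = 1, bI = 1, bD = 1)
  g5 <- state_free_energies(co2, sh2, 5.0)
  expect_equal(c(g5$dG_N, g5$dG_I, g5$dG_D), c(0, -6.0, 1.0))
  expect_error(state_free_energies(co, sh, -1), ">= 0")
})

test_that("Boltzmann populations: limits, normalization, numerical range", {
  p <- boltzmann_populations(0, 0, 293.15)
  expect_equal(unlist(p), c(pN = 1/3, pI = 1/3, pD = 1/3))
  p <- boltzmann_populations(50, 50, 293.15)
  expect_gt(p$pN, 1 - 1e-10)
  # stable far beyond double overflow of a naive exp
  p <- boltzmann_populations(c(-500, 500), c(500, -500), 293.15)
  expect_true(all(is.finite(unlist(p))))
  expect_equal(p$pI[1L], 1, tolerance = 1e-12)
  expect_equal(p$pD[2L], 1, tolerance = 1e-12)
  expect_error(boltzmann_populations(NaN, 0, 293.15), "non-finite")
  expect_error(boltzmann_populations(0, 0, -1), "> 0")
  # normalization within 1e-12 over a random parameter sweep
  set.seed(42)
  dgi <- runif(200, -30, 30)
  dgd <- runif(200, -30, 30)
  pp <- boltzmann_populations(dgi, dgd, 293.15)
  expect_lt(max(abs(rowSums(as.matrix(pp)) - 1)), 1e-12)
  expect_true(all(as.matrix(pp) >= 0 & as.matrix(pp) <= 1))
})

test_that("a 2 kcal/mol gap shifts the intermediate population ~30-fold", {
  # two systems differing only in dG_I (4.7 vs 2.7), D state negligible
  p_hi <- boltzmann_populations(4.7, 50, 293.15)
  p_lo <- boltzmann_populations(2.7, 50, 293.15)
  ratio <- p_lo$pI / p_hi$pI
  # the bare Boltzmann factor is exp(2/RT) ~ 31; the population ratio
  # differs only by the partition-function normalization (<1%)
  expect_equal(ratio, exp(2 / (R_GAS * 293.15)), tolerance = 0.01)
  expect_equal(signif(ratio, 1), 30)
})

test_that("three-state FIR reduces to a single baseline in degenerate cases", {
  sh <- list(sN = 0.005, sI = 0, sD = 0.003, mI = 0, mD = 0)
  co <- list(bN = 0.8, bI = 1.0, bD = 1.1, dG_I0 = 100, dG_D0 = 100)
  C <- seq(0, 6, length.out = 25)
  expect_equal(fir_three_state(co, sh, C), 0.8 + 0.005 * C,
               tolerance = 1e-12)
  # identical baselines make the free energies irrelevant
  sh2 <- list(sN = 0.004, sI = 0.004, sD = 0.004, mI = -2, mD = -4)
  co2 <- list(bN = 0.9, bI = 0.9, bD = 0.9, dG_I0 = 3, dG_D0 = 12)
  expect_equal(fir_three_state(co2, sh2, C), 0.9 + 0.004 * C,
               tolerance = 1e-12)
})

test_that("three-state FIR matches the literal fitting-function oracle", {
  co <- list(bN = 0.80, bI = 1.00, bD = 1.10, dG_I0 = 4.0, dG_D0 = 10.0)
  sh <- list(sN = 0.005, sI = 0.0, sD = 0.003, mI = -2.0, mD = -1.8)
  v <- fir_three_state(co, sh, 2.0, 293.15)
  expect_equal(v, oracle_fir_three_state(0.80, 0.005, 1.00, 0, 1.10, 0.003,
                                         4.0, -2.0, 10.0, -1.8, 2.0, 293.15),
               tolerance = 1e-14)
  expect_equal(v, 0.905, tolerance = 1e-3)
  # 100-point grid over parameters and concentrations
  set.seed(7)
  for (i in 1:100) {
    co_i <- list(bN = runif(1, 0.6, 1), bI = runif(1, 0.8, 1.2),
                 bD = runif(1, 1, 1.3), dG_I0 = runif(1, 0, 8),
                 dG_D0 = runif(1, 5, 18))
    sh_i <- list(sN = runif(1, -0.02, 0.02), sI = runif(1, -0.02, 0.02),
                 sD = runif(1, -0.02, 0.02), mI = runif(1, -4, -0.5),
                 mD = runif(1, -6, -1))
    C <- runif(1, 0, 6)
    expect_equal(
      fir_three_state(co_i, sh_i, C, 293.15),
      oracle_fir_three_state(co_i$bN, sh_i$sN, co_i$bI, sh_i$sI, co_i$bD,
                             sh_i$sD, co_i$dG_I0, sh_i$mI, co_i$dG_D0,
                             sh_i$mD, C, 293.15),
      tolerance = 1e-12)
  }
})

test_that("with an unreachable D state the model is the two-state LEM curve", {
  co <- list(bN = 0.85, bI = 1.05, bD = 1.2, dG_I0 = 3.2, dG_D0 = 1e4)
  sh <- list(sN = 0.01, sI = 0.002, sD = 0.005, mI = -2.2, mD = -4)
  C <- seq(0, 6, length.out = 61)
  expect_equal(fir_three_state(co, sh, C, 293.15),
               oracle_fir_two_state(0.85, 0.01, 1.05, 0.002, 3.2, -2.2,
                                    C, 293.15),
               tolerance = 1e-12)
})

test_that("unfolding_curve validates and canonically orders its points", {
  u <- c(3, 1, 2, 4, 5, 6, 0.5, 2.5)
  cv <- unfolding_curve("x", u, rep(1, 8))
  expect_identical(cv$urea, sort(u))
  expect_error(unfolding_curve("x", 1:7, rep(1, 7)), "at least 8")
  expect_error(unfolding_curve("x", c(-1, 1:7), rep(1, 8)), ">= 0")
  expect_error(unfolding_curve("x", 1:8, c(0, rep(1, 7))), "> 0")
})

test_that("noiseless global fit recovers every free parameter", {
  g <- gen_urea_curves(noise_sd = 0, seed = 11)
  fit <- suppressWarnings(fit_global_three_state(g$curves))
  tru <- g$truth
  expect_equal(fit$shared$mI, tru$shared$mI, tolerance = 1e-4)
  expect_equal(fit$shared$mD, tru$shared$mD, tolerance = 1e-4)
  expect_equal(fit$shared$sN, tru$shared$sN, tolerance = 1e-4)
  for (lb in names(tru$per_construct)) {
    row <- fit$per_construct[fit$per_construct$construct == lb, ]
    expect_equal(row$dG_I0, tru$per_construct[[lb]]$dG_I0, tolerance = 1e-4)
    expect_equal(row$dG_D0, tru$per_construct[[lb]]$dG_D0, tolerance = 1e-4)
    expect_equal(row$bN, tru$per_construct[[lb]]$bN, tolerance = 1e-4)
  }
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("derived quantities obey the midpoint identity", {
  g <- gen_urea_curves(noise_sd = 0.003, seed = 3)
  fit <- suppressWarnings(fit_global_three_state(g$curves))
  for (i in seq_len(nrow(fit$per_construct))) {
    row <- fit$per_construct[i, ]
    expect_equal(row$c_urea_IN, -row$dG_I0 / fit$shared$mI,
                 tolerance = 1e-12)
    # at C_urea I-N the N and I states are equally populated
    co <- list(bN = row$bN, bI = row$bI, bD = row$bD,
               dG_I0 = row$dG_I0, dG_D0 = row$dG_D0)
    gse <- state_free_energies(co, fit$shared, row$c_urea_IN)
    pop <- boltzmann_populations(gse$dG_I, gse$dG_D, fit$temperature)
    expect_equal(pop$pN, pop$pI, tolerance = 1e-10)
  }
})

test_that("the fit is invariant to curve order and point order", {
  g <- gen_urea_curves(noise_sd = 0.005, seed = 21)
  f1 <- suppressWarnings(fit_global_three_state(g$curves))
  set.seed(99)
  shuffled <- lapply(g$curves[sample(length(g$curves))], function(cv) {
    idx <- sample(length(cv$urea))
    unfolding_curve(cv$construct, cv$urea[idx], cv$fir[idx], cv$temperature)
  })
  f2 <- suppressWarnings(fit_global_three_state(shuffled))
  expect_equal(f1$shared, f2$shared, tolerance = 1e-8)
  expect_equal(f1$per_construct$dG_I0, f2$per_construct$dG_I0,
               tolerance = 1e-8)
})

test_that("construct comparison propagates errors and validates labels", {
  g <- gen_urea_curves(noise_sd = 0.005, seed = 1)
  fit <- suppressWarnings(fit_global_three_state(g$curves))
  expect_identical(compare_constructs(fit, "A1 short", "A1 short"),
                   list(ddG = 0, se = 0))
  a <- fit$per_construct[fit$per_construct$construct == "A1+OGly+N", ]
  b <- fit$per_construct[fit$per_construct$construct == "A1 short", ]
  cc <- compare_constructs(fit, "A1+OGly+N", "A1 short")
  expect_equal(cc$ddG, a$dG_IN - b$dG_IN)
  expect_equal(cc$se, sqrt(a$dG_IN_se^2 + b$dG_IN_se^2))
  expect_error(compare_constructs(fit, "nope", "A1 short"), "not present")
})

test_that("fit refuses degenerate inputs", {
  g <- gen_urea_curves(noise_sd = 0, seed = 1)
  one <- g$curves[[1L]]
  short <- unfolding_curve(one$construct, one$urea[1:8], one$fir[1:8])
  expect_error(fit_global_three_state(list(short)), "refusing to fit")
  warm <- unfolding_curve("other", one$urea, one$fir, temperature = 310)
  expect_error(fit_global_three_state(list(one, warm)), "same temperature")
  expect_error(fit_global_three_state(list(one, one)), "unique")
})
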