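paper_protocol <- function() itc_protocol(cell_conc = 22e-6,
                                          syringe_conc = 250e-6)

test_that("predicted heats match the bisection mass-balance oracle", {
  pr <- paper_protocol()
  th <- one_site_thermo(n = 1, ka = 5.6e6, dh = 8)
  q <- predict_injection_heats(pr, th)
  q_oracle <- oracle_itc_heats(22e-6, 250e-6, pr$injection_volumes,
                               pr$priming_volume, pr$cell_volume,
                               1, 5.6e6, 8)
  expect_lt(max(abs(q - q_oracle)), 1e-9 * max(abs(q)))
  # endothermic binding gives positive heats while free sites remain;
  # after saturation the displacement dilution shrinks the bound pool and
  # the prescribed heat expression goes slightly negative
  cum_titrant <- cumsum(c(pr$priming_volume, pr$injection_volumes)) * 250e-6
  pre_sat <- which(cum_titrant[-1L] < 22e-6 * pr$cell_volume)
  expect_true(all(q[pre_sat] > 0))
})

test_that("zero enthalpy gives exactly zero heats", {
  q <- predict_injection_heats(paper_protocol(),
                               one_site_thermo(1, 1e6, dh = 0))
  expect_identical(q, rep(0, 18L))
})

test_that("infinitely tight binding produces the step isotherm", {
  pr <- paper_protocol()
  th <- one_site_thermo(n = 1, ka = 1e15, dh = 8)
  q <- predict_injection_heats(pr, th)
  # closed form: bound = min(sites, titrant) through the same bookkeeping
  cc <- foldbind:::.itc_concentrations(pr)
  b <- pmin(cc$mt, cc$xt)
  b_prev <- c(0, b[-length(b)])
  q_step <- (pr$cell_volume * 8 *
               (b - b_prev * (1 - cc$vols / (2 * pr$cell_volume))))[-1L]
  expect_lt(max(abs(q - q_step)), 1e-6 * max(abs(q)))
  # before the equivalence point each heat is dh times the net titrant
  # bound; past it binding ceases and only the small negative dilution
  # term of the heat expression remains
  expect_true(all(diff(pmin(cc$mt, cc$xt) == cc$xt) <= 0))
  # the crossover injection itself still binds partway through
  post <- setdiff(which(cc$xt[-1L] > cc$mt[-1L]),
                  min(which(cc$xt[-1L] > cc$mt[-1L])))
  expect_true(all(q[post] <= 0))
  expect_lt(max(abs(q[post])) / q[1L], 0.2)
})

test_that("total heat never exceeds the stoichiometric bound", {
  pr <- paper_protocol()
  for (ka in c(1e4, 1e6, 1e9, 1e15)) {
    th <- one_site_thermo(1, ka, 8)
    q <- predict_injection_heats(pr, th)
    cap <- 8 * min(sum(250e-6 * pr$injection_volumes),
                   1 * 22e-6 * pr$cell_volume)
    expect_lte(sum(q), cap + 1e-9)
  }
})

test_that("noiseless predict -> fit round trip recovers n, ka, dh", {
  pr <- paper_protocol()
  th <- one_site_thermo(n = 0.95, ka = 5.6e6, dh = 8)
  q <- predict_injection_heats(pr, th)
  fit <- fit_one_site_itc(q, pr)
  expect_equal(fit$thermo$n, th$n, tolerance = 1e-5)
  expect_equal(fit$thermo$ka, th$ka, tolerance = 1e-5)
  expect_equal(fit$thermo$dh, th$dh, tolerance = 1e-5)
  expect_equal(fit$offset, 0, tolerance = 1e-8)
})

test_that("round trip holds across the reliable c-value range", {
  pr <- paper_protocol()
  for (cval in c(5, 50, 500)) {
    ka <- cval / 22e-6
    th <- one_site_thermo(1, ka, -4.5)
    q <- predict_injection_heats(pr, th)
    fit <- fit_one_site_itc(q, pr, fit_offset = FALSE)
    expect_equal(fit$thermo$ka, ka, tolerance = 1e-4)
    expect_equal(fit$thermo$dh, -4.5, tolerance = 1e-5)
  }
})

test_that("an endothermic fit is entropically driven", {
  g <- gen_itc(one_site_thermo(1, 5.6e6, 8), noise_frac = 0.02, seed = 4)
  fit <- fit_one_site_itc(g$heats, g$protocol)
  th <- fit$thermo
  expect_gt(th$dh, 0)
  expect_gt(th$tds, th$dh)   # TdS > dH > 0: binding driven by entropy
  expect_lt(th$dg, 0)
  expect_equal(th$dg + th$tds, th$dh)        # exact identity
  expect_equal(th$kd * th$ka, 1)             # exact identity
})

test_that("thermodynamic decomposition matches direct arithmetic", {
  d <- decompose_thermo(kd = 1, dh = 3.3)
  expect_identical(d$dg, 0)
  expect_identical(d$tds, 3.3)
  d2 <- decompose_thermo(kd = 180e-9, dh = 10, temperature = 295.15)
  expect_equal(d2$dg, 1.9872e-3 * 295.15 * log(1.8e-7), tolerance = 1e-12)
  expect_equal(d2$dg, -9.11, tolerance = 1e-3)
  expect_equal(d2$tds, 10 - d2$dg)
})

test_that("enthalpy-entropy compensation rank check", {
  expect_true(compensation_rank_check(
    data.frame(label = c("a", "b"), dh = c(1, 2), tds = c(3, 4))
  )$same_rank_order)
  rev <- compensation_rank_check(
    data.frame(label = c("a", "b", "c"), dh = c(1, 2, 3), tds = c(3, 2, 1)))
  expect_false(rev$same_rank_order)
  expect_equal(rev$spearman, -1)
  # panel with dh_i = tds_i + const + small noise keeps a common rank order
  set.seed(11)
  tds <- sort(runif(7, 5, 25))
  panel <- data.frame(label = paste0("c", 1:7), dh = tds - 9 +
                        rnorm(7, 0, 0.05), tds = tds)
  chk <- compensation_rank_check(panel)
  expect_true(chk$same_rank_order)
  expect_equal(chk$spearman, 1)
})

test_that("protocol and fit validation", {
  expect_warning(itc_protocol(cell_conc = 1e-3, syringe_conc = 1e-4),
                 "saturation")
  pr <- paper_protocol()
  expect_error(fit_one_site_itc(1:5, pr), ">= 6")
  th_tight <- one_site_thermo(1, 2.3e8, 5)  # c-value ~ 5000
  q <- predict_injection_heats(pr, th_tight)
  expect_warning(fit_one_site_itc(q, pr, fit_offset = FALSE), "c-value")
})
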