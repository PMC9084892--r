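test_that("exchangeable-amide counting follows the field convention", {
  p <- hdx_peptide(1238, 1243, "ACDEFG")
  expect_identical(p$max_exchangeable, 5L)       # length - 1, no prolines
  p2 <- hdx_peptide(1238, 1243, "ACPDPG")
  expect_identical(p2$max_exchangeable, 3L)      # two non-terminal prolines
  p3 <- hdx_peptide(10, 10, "A")
  expect_identical(p3$max_exchangeable, 0L)
  expect_error(hdx_peptide(5, 3, "A"), ">=")
  expect_error(hdx_peptide(1, 3, "AC"), "does not match")
})

test_that("relative uptake percent is linear with the documented scaling", {
  p <- hdx_peptide(1, 6, "ACDEFG")  # 5 exchangeable
  expect_identical(relative_uptake_percent(0, p), 0)
  expect_equal(relative_uptake_percent(1.0, p), 20.0)
  expect_equal(relative_uptake_percent(1.0, p, normalize_d2o = TRUE),
               100 / (5 * 0.933))
  expect_equal(round(relative_uptake_percent(1.0, p, normalize_d2o = TRUE),
                     1), 21.4)
  # linearity
  u <- c(0.3, 0.6, 1.2)
  expect_equal(relative_uptake_percent(u, p),
               u * relative_uptake_percent(1, p))
  pp <- hdx_peptide(1, 2, "AP")
  expect_error(relative_uptake_percent(1, pp), "no exchangeable")
})

test_that("coverage and redundancy on hand-enumerable maps", {
  full <- hdx_peptide(1, 10, "ACDEFGHIKL")
  cr <- coverage_and_redundancy(list(full), 1, 10)
  expect_equal(cr$coverage, 100)
  expect_equal(cr$redundancy, 1.0)
  two <- list(hdx_peptide(1, 5, "ACDEF"), hdx_peptide(4, 10, "EFGHIKL"))
  cr2 <- coverage_and_redundancy(two, 1, 10)
  expect_equal(cr2$coverage, 100)
  expect_equal(cr2$redundancy, 1.2)
  # partial coverage and the covered-only redundancy variant
  cr3 <- coverage_and_redundancy(list(hdx_peptide(1, 5, "ACDEF")), 1, 10)
  expect_equal(cr3$coverage, 50)
  expect_equal(cr3$redundancy, 0.5)
  cr4 <- coverage_and_redundancy(list(hdx_peptide(1, 5, "ACDEF")), 1, 10,
                                 covered_only = TRUE)
  expect_equal(cr4$redundancy, 1.0)
  expect_warning(
    coverage_and_redundancy(list(full, hdx_peptide(50, 55, "ACDEFG")),
                            1, 10), "outside the region")
})

test_that("coverage is monotone and redundancy strictly increasing under additions", {
  set.seed(5)
  peps <- list()
  prev_cov <- 0
  prev_red <- 0
  for (i in 1:12) {
    s <- sample(1:90, 1)
    l <- sample(5:10, 1)
    peps[[i]] <- hdx_peptide(s, s + l - 1,
                             paste(rep("A", l), collapse = ""))
    cr <- coverage_and_redundancy(peps, 1, 100)
    expect_gte(cr$coverage, prev_cov)
    expect_gt(cr$redundancy, prev_red)
    prev_cov <- cr$coverage
    prev_red <- cr$redundancy
  }
})

make_hdx <- function(label, uptakes, timepoint = 3600, reps = 2) {
  # uptakes: named vector peptide-id -> mean uptake; two replicates each
  rows <- do.call(rbind, lapply(seq_along(uptakes), function(i) {
    st <- 10 * i
    data.frame(construct = label, pep_start = st, pep_end = st + 5,
               pep_sequence = "ACDEFG", timepoint_s = timepoint,
               replicate = seq_len(reps), uptake_Da = uptakes[i],
               stringsAsFactors = FALSE)
  }))
  hdx_experiment(label, rows)
}

test_that("difference maps apply the strict significance threshold", {
  a <- make_hdx("A", c(2.0, 2.0, 2.0))
  expect_identical(sum(difference_map(a, a)$entries$significant), 0L)
  b <- make_hdx("B", c(2.0 - 0.8, 2.0 - 0.70, 2.0 - 0.71))
  dm <- difference_map(a, b)
  expect_equal(dm$entries$delta_Da, c(0.8, 0.70, 0.71))
  # strict inequality: 0.70 exactly is NOT significant, 0.71 is
  expect_identical(dm$entries$significant, c(TRUE, FALSE, TRUE))
  # propagated repeatability for duplicate measurements
  expect_equal(dm$entries$se_Da, rep(0.15 * sqrt(1/2 + 1/2), 3))
})

test_that("difference maps are antisymmetric and replicate-consistent", {
  g <- gen_hdx(seed = 3)
  ab <- difference_map(g$reference, g$other)
  ba <- difference_map(g$other, g$reference)
  expect_equal(ab$entries$delta_Da, -ba$entries$delta_Da)
  # collapsing replicates to their means changes nothing
  collapse <- function(ex) {
    m <- aggregate(uptake_Da ~ construct + pep_start + pep_end +
                     pep_sequence + timepoint_s, ex$measurements, mean)
    m$replicate <- 1L
    hdx_experiment(ex$construct, m)
  }
  ab2 <- difference_map(collapse(g$reference), collapse(g$other))
  expect_equal(ab$entries$delta_Da, ab2$entries$delta_Da, tolerance = 1e-12)
  # but the propagated error honors the replicate counts
  expect_equal(unique(ab$entries$se_Da), 0.15)
  expect_equal(unique(ab2$entries$se_Da), 0.15 * sqrt(2))
})

test_that("protection applied to two loop regions is found where the truth says", {
  g <- gen_hdx(seed = 7)
  dm <- difference_map(g$reference, g$other)
  regions <- g$truth$protected_regions
  overlaps <- function(st, en) {
    any(vapply(regions, function(r) st <= r[2] && en >= r[1], logical(1)))
  }
  sig <- dm$entries[dm$entries$significant, ]
  # every significant entry overlaps a protected region
  expect_true(all(mapply(overlaps, sig$pep_start, sig$pep_end)))
  expect_gt(nrow(sig), 0)
  # significance appears where the generator's noiseless gap exceeds the
  # threshold; verify at the latest timepoint for one protected peptide
  expect_true(any(sig$timepoint_s == 14400))
  # reference (unprotected) exchanges more: protected deltas positive
  expect_true(all(sig$delta_Da > 0))
})

test_that("equal protection yields no significant differences", {
  g <- gen_hdx(protection_factor = 1, seed = 11)
  dm <- difference_map(g$reference, g$other)
  expect_identical(sum(dm$entries$significant), 0L)
})

test_that("experiments that share nothing fail loudly", {
  a <- make_hdx("A", c(1, 2))
  rows <- data.frame(construct = "B", pep_start = 500, pep_end = 505,
                     pep_sequence = "ACDEFG", timepoint_s = 10,
                     replicate = 1, uptake_Da = 1)
  b <- hdx_experiment("B", rows)
  expect_error(difference_map(a, b), "share no")
})

test_that("uptake outside the physical window is rejected", {
  rows <- data.frame(construct = "A", pep_start = 1, pep_end = 6,
                     pep_sequence = "ACDEFG", timepoint_s = 10,
                     replicate = 1, uptake_Da = 7.0)  # > 5 + 0.5
  expect_error(hdx_experiment("A", rows), "outside")
})
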