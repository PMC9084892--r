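#' Default three-state unfolding truth for the four-construct panel
#'
#' The study conditions for the urea-denaturation generator: shared state
#' baseline slopes and m-values, and per-construct baseline intercepts and
#' zero-urea free energies, for a panel of one nonglycosylated core-domain
#' construct and three O-glycosylated linker constructs. The N-linker
#' constructs carry a 2 kcal/mol larger N-to-I free-energy gap, with the
#' full-length glycosylated construct at 4.7 kcal/mol; first transitions
#' fall between 1 and 3 M urea and the second above 5 M.
#'
#' @return A list with `shared` (sN, sI, sD, mI, mD) and `per_construct`
#'   (named list of bN, bI, bD, dG_I0, dG_D0 per construct).
#' @export
default_unfolding_truth <- function() {
  per <- list(
    "A1 short"     = list(bN = 0.84, bI = 1.00, bD = 1.09,
                          dG_I0 = 2.5, dG_D0 = 13.1),
    "A1+OGly+C"    = list(bN = 0.85, bI = 1.01, bD = 1.10,
                          dG_I0 = 2.7, dG_D0 = 13.3),
    "A1+OGly+N"    = list(bN = 0.83, bI = 0.99, bD = 1.08,
                          dG_I0 = 4.5, dG_D0 = 15.1),
    "A1+OGly+N+C"  = list(bN = 0.86, bI = 1.02, bD = 1.11,
                          dG_I0 = 4.7, dG_D0 = 15.3)
  )
  list(shared = list(sN = 0.010, sI = 0.002, sD = 0.005,
                     mI = -2.0, mD = -4.0),
       per_construct = per)
}

#' Generate synthetic urea-denaturation curves
#'
#' FIR sampled from the three-state model plus i.i.d. Gaussian noise, on
#' the experimental design of 24 urea steps spanning 0.135-6 M. The truth
#' parameters are embedded in the output for recovery studies. This is a
#' synthetic emulation of instrument source data, not a measurement.
#'
#' @param truth Truth parameters as from [default_unfolding_truth()].
#' @param n_points Urea steps per curve (default 24).
#' @param c_range Urea range in M (default `c(0.135, 6)`).
#' @param noise_sd Gaussian FIR noise sd (default 0.005).
#' @param temperature Kelvin (default 293.15).
#' @param seed Integer seed; identical inputs give identical output.
#' @return A list with `curves` (list of [unfolding_curve()]), `truth`,
#'   and `table` (long-format data.frame with columns `construct`,
#'   `urea_M`, `fir`).
#' @export
gen_urea_curves <- function(truth = default_unfolding_truth(),
                            n_points = 24L, c_range = c(0.135, 6),
                            noise_sd = 0.005, temperature = 293.15,
                            seed = 1L) {
  set.seed(seed)
  conc <- seq(c_range[1L], c_range[2L], length.out = n_points)
  curves <- list()
  rows <- list()
  for (lb in names(truth$per_construct)) {
    fir0 <- fir_three_state(truth$per_construct[[lb]], truth$shared,
                            conc, temperature)
    fir <- fir0 + stats::rnorm(n_points, 0, noise_sd)
    curves[[lb]] <- unfolding_curve(lb, conc, fir, temperature)
    rows[[lb]] <- data.frame(construct = lb, urea_M = conc, fir = fir,
                             stringsAsFactors = FALSE)
  }
  list(curves = unname(curves), truth = truth,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Generate a synthetic thermal ramp
#'
#' FIR is built as a linear baseline plus logistic transitions at the
#' configured midpoints (a phenomenological shape with known transition
#' locations, not a thermodynamic model); backscatter as a flat baseline
#' plus an optional saturating rise beginning at the aggregation onset.
#' Scan 30-85 C emulating a 1 C/min ramp.
#'
#' @param construct Label for the generated curve.
#' @param midpoints Transition midpoints in C (default `c(53.2, 63.0)`).
#' @param widths Logistic widths in C (default 1.5 per transition).
#' @param amplitudes FIR amplitudes per transition (default 0.12 each).
#' @param baseline FIR baseline intercept at scan start (default 0.85).
#' @param baseline_slope FIR baseline slope per C (default 5e-4).
#' @param aggregation_onset Onset temperature in C, or `NA` for a construct
#'   protected from aggregation over the whole scan.
#' @param scan Scan range in C (default `c(30, 85)`).
#' @param step Sampling interval in C (default 0.1, ~6 s at 1 C/min).
#' @param noise_sd FIR noise sd; default amplitude/20 of the first
#'   transition (signal-to-noise 20).
#' @param backscatter_noise_frac Backscatter noise sd as a fraction of the
#'   aggregation rise (default 0.01).
#' @param seed Integer seed.
#' @return A list with `curve` (a [thermal_ramp()]) and `truth`.
#' @export
gen_thermal <- function(construct = "synthetic",
                        midpoints = c(53.2, 63.0),
                        widths = rep(1.5, length(midpoints)),
                        amplitudes = rep(0.12, length(midpoints)),
                        baseline = 0.85, baseline_slope = 5e-4,
                        aggregation_onset = NA,
                        scan = c(30, 85), step = 0.1,
                        noise_sd = NULL,
                        backscatter_noise_frac = 0.01,
                        seed = 1L) {
  set.seed(seed)
  tc <- seq(scan[1L], scan[2L], by = step)
  fir <- baseline + baseline_slope * (tc - scan[1L])
  for (i in seq_along(midpoints)) {
    fir <- fir + amplitudes[i] * stats::plogis((tc - midpoints[i]) / widths[i])
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (length(amplitudes) > 0L) amplitudes[1L] / 20 else 1e-4
  }
  fir <- fir + stats::rnorm(length(tc), 0, noise_sd)

  rise_amp <- 1000
  bs <- rep(100, length(tc))
  if (!is.na(aggregation_onset)) {
    past <- tc > aggregation_onset
    bs[past] <- bs[past] +
      rise_amp * (1 - exp(-(tc[past] - aggregation_onset) / 3))
  }
  bs <- bs + stats::rnorm(length(tc), 0, backscatter_noise_frac * rise_amp)

  list(curve = thermal_ramp(construct, tc, fir, backscatter = bs,
                            ramp_rate = 1),
       truth = list(midpoints = midpoints, widths = widths,
                    amplitudes = amplitudes,
                    aggregation_onset = aggregation_onset,
                    noise_sd = noise_sd))
}

#' Generate synthetic BLI sensorgrams with reference wells
#'
#' Simulates one-site sensorgrams at the requested analyte concentrations
#' with optional baseline drift, Gaussian noise, and an optional second
#' binding species (heterogeneity) that a one-site fit cannot describe.
#' Buffer-only internal references (drift plus noise) and unloaded-sensor
#' parallel references (noise only) are generated alongside, so the double
#' referencing and global fit can be exercised end to end.
#'
#' @param truth A [one_site_kinetics()] parameter set.
#' @param concs Analyte concentrations in M (default a 5-step 3-fold
#'   dilution series around KD).
#' @param t_assoc,t_dissoc Phase durations in s (defaults 300 and 600).
#' @param dt Sampling period in s (default 1).
#' @param noise_sd Noise sd as a fraction of `rmax` (default 0.01).
#' @param drift Linear baseline drift in sensor units per s (default 0).
#' @param het_fraction Fraction of the response carried by a second
#'   species (default 0, i.e. a pure one-site system).
#' @param het_koff_factor Fold-change of the second species' `koff`
#'   (default 10).
#' @param construct Construct label.
#' @param nacl NaCl in mM (metadata).
#' @param seed Integer seed.
#' @return A list with `samples`, `internal_refs`, `parallel_refs`
#'   (lists of [sensorgram()] per concentration) and `truth`.
#' @export
gen_sensorgrams <- function(truth, concs = NULL, t_assoc = 300,
                            t_dissoc = 600, dt = 1, noise_sd = 0.01,
                            drift = 0, het_fraction = 0,
                            het_koff_factor = 10,
                            construct = "synthetic", nacl = 150,
                            seed = 1L) {
  stopifnot(inherits(truth, "one_site_kinetics"))
  set.seed(seed)
  if (is.null(concs)) concs <- truth$kd * 3^seq(-2, 2)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  sd_abs <- noise_sd * truth$rmax

  species2 <- one_site_kinetics(truth$kon, truth$koff * het_koff_factor,
                                truth$rmax)
  mk <- function(conc, signal) {
    sensorgram(construct, conc, times, signal,
               assoc_window = c(0, t_assoc),
               dissoc_window = c(t_assoc, t_assoc + t_dissoc), nacl = nacl)
  }
  samples <- internal_refs <- parallel_refs <- vector("list", length(concs))
  for (i in seq_along(concs)) {
    sig1 <- simulate_one_site(truth, concs[i], times, t_dissoc = t_assoc)
    sig <- if (het_fraction > 0) {
      sig2 <- simulate_one_site(species2, concs[i], times,
                                t_dissoc = t_assoc)
      (1 - het_fraction) * sig1 + het_fraction * sig2
    } else sig1
    dr <- drift * times
    samples[[i]] <- mk(concs[i],
                       sig + dr + stats::rnorm(length(times), 0, sd_abs))
    internal_refs[[i]] <- mk(0, dr + stats::rnorm(length(times), 0, sd_abs))
    parallel_refs[[i]] <- mk(concs[i],
                             stats::rnorm(length(times), 0, sd_abs))
  }
  list(samples = samples, internal_refs = internal_refs,
       parallel_refs = parallel_refs,
       truth = list(kinetics = truth, concs = concs,
                    noise_sd = noise_sd, drift = drift,
                    het_fraction = het_fraction,
                    het_koff_factor = het_koff_factor))
}

#' Generate synthetic ITC injection heats
#'
#' Heats from [predict_injection_heats()] plus i.i.d. Gaussian noise with
#' sd equal to `noise_frac` of the first predicted injection heat
#' magnitude.
#'
#' @param truth A [one_site_thermo()].
#' @param protocol An [itc_protocol()]; the default mirrors a titration of
#'   250 uM titrant into 22 uM macromolecule with a 0.4 ul priming
#'   injection followed by 18 x 2 ul injections every 180 s at 22 C.
#' @param noise_frac Noise sd as a fraction of the first injection heat
#'   (default 0.02).
#' @param seed Integer seed.
#' @return A list with `heats` (kcal per analyzed injection), `protocol`,
#'   `truth`.
#' @export
gen_itc <- function(truth,
                    protocol = itc_protocol(cell_conc = 22e-6,
                                            syringe_conc = 250e-6),
                    noise_frac = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "one_site_thermo"))
  set.seed(seed)
  q0 <- predict_injection_heats(protocol, truth)
  sd_abs <- noise_frac * abs(q0[1L])
  list(heats = q0 + stats::rnorm(length(q0), 0, sd_abs),
       protocol = protocol,
       truth = list(thermo = truth, noise_frac = noise_frac))
}

## random overlapping pseudo-peptic digestion of a sequence
.pseudo_digest <- function(n_res, offset, min_len = 5L, max_len = 20L) {
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L
  while (pos <= n_res - min_len + 1L) {
    len <- sample(min_len:max_len, 1L)
    end <- min(n_res, pos + len - 1L)
    starts <- c(starts, pos)
    ends <- c(ends, end)
    # dense overlapping map: mean advance ~3 residues per peptide gives
    # ~5x redundancy, typical of a pepsin map
    pos <- pos + sample(2:4, 1L)
  }
  data.frame(start = starts + offset - 1L, end = ends + offset - 1L)
}

#' Generate a pair of synthetic HDX experiments
#'
#' Per-residue deuterium uptake follows 1 - exp(-k_int * t / PF), with
#' intrinsic exchange rates drawn log-uniformly over 1e-2 to 1e2 per
#' minute, summed over each peptide's exchangeable amides, scaled by the
#' D2O fraction and (1 - back exchange), plus Gaussian replicate noise.
#' Construct B carries extra protection factors over the configured
#' regions, producing uptake gaps a difference map should recover.
#'
#' @param n_res Number of residues in the segment (default 120).
#' @param offset Residue number of the first residue (default 1250,
#'   pre-pro-protein numbering).
#' @param protected_regions A list of `c(start, end)` residue ranges (in
#'   the offset numbering) extra-protected in construct B.
#' @param protection_factor Fold extra protection in those regions
#'   (default 20).
#' @param timepoints Exchange times in s (default
#'   `c(10, 60, 600, 3600, 14400)`).
#' @param d2o_fraction Labeling D2O fraction (default 0.933).
#' @param back_exchange Back-exchange fraction (default 0.325, the middle
#'   of the typical 30-35% range).
#' @param replicate_sd Per-replicate uptake noise in Da (default
#'   `0.15 / sqrt(2)`, so duplicate means carry ~0.15 Da error).
#' @param n_replicates Technical replicates (default 2).
#' @param labels Labels for the two constructs.
#' @param seed Integer seed.
#' @return A list with `reference` and `other` ([hdx_experiment()]
#'   objects; the reference is the unprotected construct A) and `truth`
#'   (per-residue rates, peptide map, protection configuration).
#' @export
gen_hdx <- function(n_res = 120L, offset = 1250L,
                    protected_regions = list(c(1270, 1279), c(1305, 1314)),
                    protection_factor = 20,
                    timepoints = c(10, 60, 600, 3600, 14400),
                    d2o_fraction = 0.933, back_exchange = 0.325,
                    replicate_sd = 0.15 / sqrt(2), n_replicates = 2L,
                    labels = c("A", "B"), seed = 1L) {
  set.seed(seed)
  aa_pool <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "Q", "R", "S", "T", "V", "W", "Y", "P")
  # ~5% prolines to exercise the exchangeable-amide rule
  seq_aa <- sample(aa_pool, n_res, replace = TRUE,
                   prob = c(rep(1, 19), 1))
  residues <- offset:(offset + n_res - 1L)
  # intrinsic rates per minute, log-uniform over 1e-2..1e2
  k_int <- 10^stats::runif(n_res, -2, 2)

  pf_b <- rep(1, n_res)
  for (rg in protected_regions) {
    pf_b[residues >= rg[1L] & residues <= rg[2L]] <- protection_factor
  }

  pep <- .pseudo_digest(n_res, offset)
  pep$sequence <- vapply(seq_len(nrow(pep)), function(i) {
    paste(seq_aa[(pep$start[i]:pep$end[i]) - offset + 1L], collapse = "")
  }, character(1L))

  scale <- d2o_fraction * (1 - back_exchange)
  uptake_one <- function(p_start, p_end, t, pf) {
    idx <- (p_start:p_end) - offset + 1L
    # exchangeable amides: positions 2..len, prolines excluded
    idx <- idx[-1L]
    idx <- idx[seq_aa[idx] != "P"]
    if (length(idx) == 0L) return(0)
    sum(scale * (1 - exp(-(k_int[idx] / 60) * t / pf[idx])))
  }

  build <- function(label, pf) {
    rows <- list()
    for (i in seq_len(nrow(pep))) {
      for (t in timepoints) {
        mu <- uptake_one(pep$start[i], pep$end[i], t, pf)
        for (r in seq_len(n_replicates)) {
          u <- mu + stats::rnorm(1L, 0, replicate_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            construct = label, pep_start = pep$start[i],
            pep_end = pep$end[i], pep_sequence = pep$sequence[i],
            timepoint_s = t, replicate = r,
            uptake_Da = max(u, -0.45), stringsAsFactors = FALSE)
        }
      }
    }
    hdx_experiment(label, do.call(rbind, rows), d2o_fraction)
  }

  ref <- build(labels[1L], rep(1, n_res))
  oth <- build(labels[2L], pf_b)
  list(reference = ref, other = oth,
       truth = list(sequence = paste(seq_aa, collapse = ""),
                    offset = offset, k_int_per_min = k_int,
                    protection_factor_b = pf_b,
                    protected_regions = protected_regions,
                    peptides = pep, timepoints = timepoints,
                    d2o_fraction = d2o_fraction,
                    back_exchange = back_exchange,
                    replicate_sd = replicate_sd))
}
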