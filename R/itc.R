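#' ITC titration protocol
#'
#' Geometry and bookkeeping of an isothermal titration: cell volume,
#' macromolecule (cell) and titrant (syringe) concentrations, the injection
#' schedule, and temperature. A priming injection, customary before the
#' analyzed series, is excluded from the heat analysis but included in the
#' concentration bookkeeping.
#'
#' @param cell_conc Macromolecule concentration in the cell, M.
#' @param syringe_conc Titrant concentration in the syringe, M.
#' @param injection_volumes Analyzed injection volumes in liters (e.g.
#'   `rep(2e-9 * 1000, 18)` for 18 x 2 ul... in liters: `rep(2e-6, 18)`).
#' @param priming_volume Priming injection volume in liters (default
#'   0.4 ul); excluded from the analysis, included in dilution bookkeeping.
#'   Use 0 for no priming injection.
#' @param cell_volume Cell volume in liters (default 200 ul, typical of the
#'   instrument class).
#' @param temperature Temperature in kelvin (default 295.15, i.e. 22 C).
#' @param spacing Injection spacing in s (metadata, default 180).
#' @return An object of class `"itc_protocol"`.
#' @export
itc_protocol <- function(cell_conc, syringe_conc,
                         injection_volumes = rep(2e-6, 18L),
                         priming_volume = 0.4e-6,
                         cell_volume = 2.0e-4,
                         temperature = 295.15, spacing = 180) {
  .check_scalar(cell_conc, "cell_conc", positive = TRUE)
  .check_scalar(syringe_conc, "syringe_conc", positive = TRUE)
  .check_scalar(cell_volume, "cell_volume", positive = TRUE)
  .check_scalar(priming_volume, "priming_volume", nonneg = TRUE)
  .check_scalar(temperature, "temperature", positive = TRUE)
  injection_volumes <- as.numeric(injection_volumes)
  if (any(injection_volumes <= 0)) {
    stop("injection volumes must be > 0", call. = FALSE)
  }
  if (syringe_conc <= cell_conc) {
    warning("syringe concentration not above cell concentration; ",
            "the titration may not reach saturation", call. = FALSE)
  }
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 priming_volume = priming_volume,
                 cell_volume = cell_volume, temperature = temperature,
                 spacing = spacing),
            class = "itc_protocol")
}

#' One-site binding thermodynamics
#'
#' @param n Stoichiometry (titrant sites per macromolecule), `> 0`.
#' @param ka Association constant in M^-1, `> 0`.
#' @param dh Binding enthalpy in kcal/mol (positive = endothermic).
#' @param temperature Temperature in kelvin for the derived quantities.
#' @return An object of class `"one_site_thermo"` with derived
#'   `kd = 1/ka`, `dg = -RT ln(ka * 1 M)` and `tds = dh - dg` (kcal/mol),
#'   1 M standard state.
#' @export
one_site_thermo <- function(n, ka, dh, temperature = 295.15) {
  .check_scalar(n, "n", positive = TRUE)
  .check_scalar(ka, "ka", positive = TRUE)
  .check_scalar(dh, "dh")
  .check_scalar(temperature, "temperature", positive = TRUE)
  dg <- -R_GAS * temperature * log(ka)
  structure(list(n = n, ka = ka, dh = dh, kd = 1 / ka,
                 dg = dg, tds = dh - dg, temperature = temperature),
            class = "one_site_thermo")
}

#' @export
print.one_site_thermo <- function(x, ...) {
  cat(sprintf("<one_site_thermo> n = %.3g, KD = %.3g M, dG = %.2f, dH = %.2f, TdS = %.2f kcal/mol\n",
              x$n, x$kd, x$dg, x$dh, x$tds))
  invisible(x)
}

## bound-complex concentration for one-site binding by the stable root of
## the quadratic in [complex]; s_tot = n * macromolecule sites
.bound_complex <- function(s_tot, x_tot, ka) {
  kd <- 1 / ka
  b <- s_tot + x_tot + kd
  # numerically stable smaller root of B^2 - b*B + s_tot*x_tot = 0
  disc <- sqrt(pmax(b^2 - 4 * s_tot * x_tot, 0))
  2 * s_tot * x_tot / (b + disc)
}

## cumulative cell concentrations after each injection under the
## displacement ("perfusion") dilution model: each injection of volume dV
## dilutes existing contents by (1 - dV/V0) before adding titrant
.itc_concentrations <- function(protocol) {
  v0 <- protocol$cell_volume
  vols <- c(if (protocol$priming_volume > 0) protocol$priming_volume,
            protocol$injection_volumes)
  m <- protocol$cell_conc
  x <- 0
  mt <- xt <- numeric(length(vols))
  for (i in seq_along(vols)) {
    f <- 1 - vols[i] / v0
    m <- m * f
    x <- x * f + protocol$syringe_conc * vols[i] / v0
    mt[i] <- m
    xt[i] <- x
  }
  list(mt = mt, xt = xt, vols = vols,
       primed = protocol$priming_volume > 0)
}

#' Predicted injection heats for a one-site titration
#'
#' For each injection the running total macromolecule and titrant
#' concentrations are updated under the displacement dilution model, the
#' single-site equilibrium is solved through the stable root of the
#' quadratic in bound complex, and the heat is
#' `q_i = V0 * dh * (B_i - B_{i-1} * (1 - dV_i / (2 V0)))` where `B` is the
#' bound concentration (the half-volume term is the standard correction for
#' material displaced during the injection). The priming injection is
#' included in the concentration bookkeeping but its heat is not returned.
#' Endothermic binding (`dh > 0`) yields positive heats.
#'
#' @param protocol An [itc_protocol()].
#' @param thermo A [one_site_thermo()].
#' @return Heats in kcal, one per analyzed injection.
#' @export
predict_injection_heats <- function(protocol, thermo) {
  stopifnot(inherits(protocol, "itc_protocol"),
            inherits(thermo, "one_site_thermo"))
  if (thermo$ka <= 0) stop("ka must be > 0", call. = FALSE)
  cc <- .itc_concentrations(protocol)
  b <- .bound_complex(thermo$n * cc$mt, cc$xt, thermo$ka)
  v0 <- protocol$cell_volume
  b_prev <- c(0, b[-length(b)])
  q <- v0 * thermo$dh * (b - b_prev * (1 - cc$vols / (2 * v0)))
  if (cc$primed) q <- q[-1L]
  q
}

#' Fit a one-site model to integrated injection heats
#'
#' Least-squares fit of stoichiometry `n`, association constant `ka` (log
#' scale) and enthalpy `dh` -- plus, optionally, a constant per-injection
#' dilution-heat offset -- to integrated injection heats, using the same
#' displacement-dilution isotherm as [predict_injection_heats()]. Standard
#' errors come from the curvature at the optimum. A Wiseman c-value
#' (`n * ka * cell_conc`) outside [1, 1000] triggers a reliability
#' warning.
#'
#' @param heats Integrated heats in kcal, one per analyzed injection
#'   (priming injection excluded).
#' @param protocol The matching [itc_protocol()].
#' @param fit_offset Fit a constant dilution-heat offset (default `TRUE`).
#' @param max_restarts Random restarts on non-convergence.
#' @return An object of class `"one_site_thermo_fit"`: the fitted
#'   [one_site_thermo()] under `$thermo`, plus `se` (named: `n`, `ka`,
#'   `dh`, and `offset` if fitted), `offset`, `residual_rms`, `c_value`.
#' @export
fit_one_site_itc <- function(heats, protocol, fit_offset = TRUE,
                             max_restarts = 10L) {
  stopifnot(inherits(protocol, "itc_protocol"))
  heats <- as.numeric(heats)
  if (length(heats) < 6L) {
    stop("need >= 6 analyzed injections", call. = FALSE)
  }
  if (length(heats) != length(protocol$injection_volumes)) {
    stop("length of 'heats' must match the protocol's analyzed injections",
         call. = FALSE)
  }

  # self-start: total heat ~ dh * min(titrant, sites) moles; midpoint
  # of the steepest heat change gives the equivalence point for n
  v0 <- protocol$cell_volume
  mol_inj <- protocol$syringe_conc * protocol$injection_volumes
  dh0 <- sum(heats) / (protocol$cell_conc * v0)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- if (sum(heats) >= 0) 5 else -5
  ka0 <- 10 / protocol$cell_conc  # c-value of 10 as a neutral start
  theta0 <- c(n = 1, lka = log(ka0), dh = dh0)
  # offset parameter carried in units of the mean absolute heat so all
  # free parameters are O(1)
  q_scale <- mean(abs(heats))
  if (q_scale == 0) q_scale <- 1
  if (fit_offset) theta0 <- c(theta0, offset = 0)

  fn <- function(th) {
    thermo <- list(n = th[[1L]], ka = exp(th[[2L]]), dh = th[[3L]],
                   kd = exp(-th[[2L]]))
    class(thermo) <- "one_site_thermo"
    q <- predict_injection_heats(protocol, thermo)
    if (fit_offset) {
      q <- q + th[[4L]] * q_scale * mol_inj / mean(mol_inj)
    }
    q - heats
  }

  best <- NULL
  for (attempt in 0:max_restarts) {
    th_try <- if (attempt == 0L) theta0 else {
      set.seed(27182L + attempt)
      theta0 + abs(theta0) * stats::runif(length(theta0), -0.2, 0.2) +
        (theta0 == 0) * stats::runif(length(theta0), -0.05, 0.05)
    }
    fit <- try(minpack.lm::nls.lm(
      par = th_try, fn = fn,
      lower = c(1e-3, log(1e-2), -Inf, if (fit_offset) -Inf),
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 1024)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$info %in% 1:4 && all(is.finite(fit$par)) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
    if (!is.null(best) && attempt == 0L) break
  }
  if (is.null(best)) {
    stop("one-site ITC fit did not converge", call. = FALSE)
  }

  theta <- best$par
  r <- fn(theta)
  dof <- max(1L, length(r) - length(theta))
  sigma2 <- sum(r^2) / dof
  J <- .num_jacobian(fn, theta)
  se_raw <- .se_from_jacobian(J, sigma2)

  n_hat <- theta[[1L]]
  ka_hat <- exp(theta[[2L]])
  dh_hat <- theta[[3L]]
  thermo <- one_site_thermo(n_hat, ka_hat, dh_hat, protocol$temperature)
  se <- c(n = se_raw[1L], ka = ka_hat * se_raw[2L], dh = se_raw[3L])
  if (fit_offset) se <- c(se, offset = se_raw[4L] * q_scale)

  c_value <- n_hat * ka_hat * protocol$cell_conc
  if (c_value < 1 || c_value > 1000) {
    warning(sprintf(
      "Wiseman c-value %.3g outside [1, 1000]; fitted ka may be unreliable",
      c_value), call. = FALSE)
  }

  structure(list(thermo = thermo, se = se,
                 offset = if (fit_offset) theta[[4L]] * q_scale else 0,
                 residual_rms = sqrt(mean(r^2)), c_value = c_value),
            class = "one_site_thermo_fit")
}

#' @export
print.one_site_thermo_fit <- function(x, ...) {
  print(x$thermo)
  cat(sprintf("  c-value %.3g, residual RMS %.3g kcal\n",
              x$c_value, x$residual_rms))
  invisible(x)
}

#' Decompose a binding affinity into dG and TdS
#'
#' `dg = RT ln(kd / 1 M)` at the 1 M standard state, and
#' `tds = dh - dg` so that `dg + tds = dh` holds exactly.
#'
#' @param kd Dissociation constant in M, `> 0`.
#' @param dh Binding enthalpy in kcal/mol.
#' @param temperature Temperature in kelvin.
#' @return A list with `dg` and `tds` in kcal/mol.
#' @export
decompose_thermo <- function(kd, dh, temperature = 295.15) {
  .check_scalar(kd, "kd", positive = TRUE)
  .check_scalar(dh, "dh")
  .check_scalar(temperature, "temperature", positive = TRUE)
  dg <- R_GAS * temperature * log(kd)
  list(dg = dg, tds = dh - dg)
}

#' Enthalpy-entropy compensation rank check
#'
#' Tests whether the rank order of the enthalpic terms across a construct
#' panel equals the rank order of the entropic terms, the signature of
#' enthalpy-entropy compensation. Reports the Spearman rank correlation.
#' Ties are broken by label order and flagged.
#'
#' @param panel A data.frame with columns `label`, `dh`, `tds` (one row per
#'   construct), or a named list of [one_site_thermo()] objects.
#' @return A list with `same_rank_order` (logical), `spearman`, `ranks`
#'   (data.frame), `ties` (logical).
#' @export
compensation_rank_check <- function(panel) {
  if (is.list(panel) && !is.data.frame(panel)) {
    panel <- do.call(rbind, lapply(names(panel), function(lb) {
      data.frame(label = lb, dh = panel[[lb]]$dh, tds = panel[[lb]]$tds,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(panel), nrow(panel) >= 2L,
            all(c("label", "dh", "tds") %in% names(panel)))
  ties <- anyDuplicated(panel$dh) > 0L || anyDuplicated(panel$tds) > 0L
  if (ties) {
    warning("ties in dh or tds broken by label order", call. = FALSE)
  }
  # first-occurrence ranking breaks ties by the row (label) order
  rh <- rank(panel$dh, ties.method = "first")
  rs <- rank(panel$tds, ties.method = "first")
  ranks <- data.frame(label = panel$label, dh_rank = rh, tds_rank = rs,
                      stringsAsFactors = FALSE)
  list(same_rank_order = all(rh == rs),
       spearman = stats::cor(panel$dh, panel$tds, method = "spearman"),
       ranks = ranks, ties = ties)
}
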