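#' One-site kinetic parameter set
#'
#' @param kon Association rate constant, M^-1 s^-1, `> 0`.
#' @param koff Dissociation rate constant, s^-1, `> 0`.
#' @param rmax Maximum response at analyte saturation, sensor units, `> 0`.
#' @return An object of class `"one_site_kinetics"` with derived
#'   `kd = koff / kon` (M).
#' @export
one_site_kinetics <- function(kon, koff, rmax) {
  .check_scalar(kon, "kon", positive = TRUE)
  .check_scalar(koff, "koff", positive = TRUE)
  .check_scalar(rmax, "rmax", positive = TRUE)
  structure(list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon),
            class = "one_site_kinetics")
}

#' @export
print.one_site_kinetics <- function(x, ...) {
  cat(sprintf("<one_site_kinetics> kon = %.3g /M/s, koff = %.3g /s, KD = %.3g M, Rmax = %.3g\n",
              x$kon, x$koff, x$kd, x$rmax))
  invisible(x)
}

#' A biolayer-interferometry sensorgram
#'
#' @param construct Construct label.
#' @param conc Analyte concentration in M, `>= 0`.
#' @param time Time in s, strictly increasing.
#' @param response Sensor response, same length as `time`.
#' @param assoc_window,dissoc_window Two-element `(t_start, t_end)` vectors
#'   in s; the dissociation window must start at or after the association
#'   window ends.
#' @param nacl NaCl concentration in mM (condition metadata, default 150).
#' @return An object of class `"sensorgram"`.
#' @export
sensorgram <- function(construct, conc, time, response,
                       assoc_window, dissoc_window, nacl = 150) {
  stopifnot(is.character(construct), length(construct) == 1L)
  .check_scalar(conc, "conc", nonneg = TRUE)
  time <- as.numeric(time)
  response <- as.numeric(response)
  if (length(time) != length(response)) {
    stop("'time' and 'response' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("'time' must be finite and strictly increasing", call. = FALSE)
  }
  stopifnot(length(assoc_window) == 2L, length(dissoc_window) == 2L)
  if (assoc_window[2L] <= assoc_window[1L] ||
      dissoc_window[2L] <= dissoc_window[1L] ||
      dissoc_window[1L] < assoc_window[2L]) {
    stop("phase windows must be ordered: association before dissociation, ",
         "non-overlapping", call. = FALSE)
  }
  structure(list(construct = construct, conc = conc, nacl = nacl,
                 time = time, response = response,
                 assoc_window = as.numeric(assoc_window),
                 dissoc_window = as.numeric(dissoc_window)),
            class = "sensorgram")
}

#' Simulate a one-site sensorgram response
#'
#' Association from a start value `r0`:
#' `R(t) = Req + (r0 - Req) * exp(-kobs * (t - t0))` with
#' `kobs = kon * conc + koff` and `Req = rmax * conc / (conc + kd)`.
#' Dissociation decays exponentially from the response at the phase
#' boundary with rate `koff`.
#'
#' @param params A [one_site_kinetics()] parameter set.
#' @param conc Analyte concentration in M, `>= 0`.
#' @param times Time points in s, `>= 0`.
#' @param t_dissoc Start of the dissociation phase in s; times beyond it
#'   follow the dissociation model.
#' @param r0 Response at `t = 0` (default 0).
#' @return Responses at `times`.
#' @export
simulate_one_site <- function(params, conc, times, t_dissoc = Inf, r0 = 0) {
  stopifnot(inherits(params, "one_site_kinetics"))
  .check_scalar(conc, "conc", nonneg = TRUE)
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative times rejected", call. = FALSE)
  kobs <- params$kon * conc + params$koff
  req <- params$rmax * conc / (conc + params$kd)
  r <- req + (r0 - req) * exp(-kobs * pmin(times, t_dissoc))
  if (is.finite(t_dissoc)) {
    rd <- req + (r0 - req) * exp(-kobs * t_dissoc)
    late <- times > t_dissoc
    r[late] <- rd * exp(-params$koff * (times[late] - t_dissoc))
  }
  r
}

## interpolate a reference trace onto the sample grid; tolerate grid
## mismatches of up to one sample period
.align_reference <- function(time, ref) {
  if (length(ref$time) == length(time) &&
      max(abs(ref$time - time)) < 1e-9) {
    return(ref$response)
  }
  period <- stats::median(diff(time))
  if (min(time) < min(ref$time) - period ||
      max(time) > max(ref$time) + period) {
    stop("reference time grid differs from the sample grid by more than ",
         "one sample period", call. = FALSE)
  }
  stats::approx(ref$time, ref$response, xout = time, rule = 2)$y
}

#' Double referencing of a raw sensorgram
#'
#' `corrected = (raw - internal_ref) - (parallel_ref -
#' parallel_internal_ref)`, where the internal reference is a buffer-only
#' well on the same sensor and the parallel reference is the same analyte
#' on an unloaded sensor. With no parallel internal reference,
#' `corrected = raw - internal_ref - parallel_ref`. Reference traces on a
#' grid differing by at most one sample period are linearly interpolated.
#'
#' @param raw Sample [sensorgram()].
#' @param internal_ref Buffer-only reference on the loaded sensor.
#' @param parallel_ref Analyte on an unloaded sensor (optional).
#' @param parallel_internal_ref Buffer-only on the unloaded sensor
#'   (optional).
#' @return The corrected [sensorgram()].
#' @export
double_reference <- function(raw, internal_ref, parallel_ref = NULL,
                             parallel_internal_ref = NULL) {
  stopifnot(inherits(raw, "sensorgram"), inherits(internal_ref, "sensorgram"))
  corr <- raw$response - .align_reference(raw$time, internal_ref)
  if (!is.null(parallel_ref)) {
    pr <- .align_reference(raw$time, parallel_ref)
    if (!is.null(parallel_internal_ref)) {
      pr <- pr - .align_reference(raw$time, parallel_internal_ref)
    }
    corr <- corr - pr
  }
  out <- raw
  out$response <- corr
  out
}

## residuals of the global one-site model for a parameter vector
## theta = (log kon, log koff, rmax_1..rmax_m or rmax shared)
.kin_residuals <- function(theta, grams, shared_rmax) {
  kon <- exp(theta[1L])
  koff <- exp(theta[2L])
  unlist(lapply(seq_along(grams), function(i) {
    g <- grams[[i]]
    rmax <- if (shared_rmax) theta[3L] else theta[2L + i]
    par <- list(kon = kon, koff = koff, rmax = rmax, kd = koff / kon)
    class(par) <- "one_site_kinetics"
    sel_a <- g$time >= g$assoc_window[1L] & g$time <= g$assoc_window[2L]
    sel_d <- g$time >= g$dissoc_window[1L] & g$time <= g$dissoc_window[2L]
    t0 <- g$assoc_window[1L]
    td <- g$assoc_window[2L] - t0
    t_use <- c(g$time[sel_a], g$time[sel_d]) - t0
    model <- simulate_one_site(par, g$conc, t_use, t_dissoc = td)
    model - c(g$response[sel_a], g$response[sel_d])
  }), use.names = FALSE)
}

## high-frequency noise estimate from second differences of each trace
.noise_estimate <- function(grams) {
  s2 <- unlist(lapply(grams, function(g) diff(g$response, differences = 2L)))
  stats::sd(s2) / sqrt(6)
}

## Wald-Wolfowitz runs test on residual signs (normal approximation)
.runs_test_z <- function(r) {
  s <- sign(r)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0L || n2 == 0L) return(-Inf)
  runs <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  (runs - mu) / sqrt(v)
}

#' Global one-site kinetic fit across analyte concentrations
#'
#' Fits a single `kon` and `koff` jointly to the association and
#' dissociation phases of all sensorgrams; `rmax` is fitted per sensor by
#' default (tip loading varies) or shared. Rates are fitted on the log
#' scale by Levenberg-Marquardt least squares. The dissociation phase
#' starts from the fitted association model value at the phase boundary,
#' not the noisy datum. Reports relative standard errors, the residual
#' RMS, and a lack-of-fit flag raised when the residual RMS exceeds 3x the
#' high-frequency noise estimate or the residuals fail a runs test --
#' the signature of heterogeneous (multi-species) binding that a one-site
#' model cannot describe.
#'
#' @param grams List of [sensorgram()] objects at `>= 3` distinct
#'   concentrations.
#' @param shared_rmax Share a single `rmax` across sensors (default
#'   `FALSE`).
#' @param max_restarts Random restarts on non-convergence.
#' @return An object of class `"one_site_fit"`: `kon`, `koff`, `kd`,
#'   `rmax` (named by trace), `rel_se` (named relative standard errors),
#'   `residual_rms`, `noise_estimate`, `lack_of_fit`, `runs_z`.
#' @export
fit_global_kinetics <- function(grams, shared_rmax = FALSE,
                                max_restarts = 10L) {
  stopifnot(length(grams) >= 1L,
            all(vapply(grams, inherits, TRUE, "sensorgram")))
  concs <- vapply(grams, `[[`, numeric(1L), "conc")
  if (length(unique(concs[concs > 0])) < 3L) {
    stop("need sensorgrams at >= 3 distinct nonzero concentrations",
         call. = FALSE)
  }
  pos <- concs[concs > 0]
  if (max(pos) / min(pos) < 3) {
    warning("analyte concentrations span < 3-fold; ",
            "fit may be ill-conditioned", call. = FALSE)
  }

  # self-starting values: koff from the tail of the highest-concentration
  # dissociation, kon from kobs at the two extreme concentrations
  rmax0 <- max(vapply(grams, function(g) max(g$response), numeric(1L)))
  rmax0 <- max(rmax0, 1e-6)
  koff0 <- 0.01
  hi <- which.max(concs)
  g <- grams[[hi]]
  sel_d <- g$time >= g$dissoc_window[1L] & g$time <= g$dissoc_window[2L]
  rd <- g$response[sel_d]
  if (sum(rd > 0.05 * rmax0) > 4L) {
    td <- g$time[sel_d][rd > 0.05 * rmax0]
    ld <- log(rd[rd > 0.05 * rmax0])
    koff0 <- max(1e-5, -stats::coef(stats::lm(ld ~ td))[[2L]])
  }
  kon0 <- max(1e2, koff0 / max(1e-9, stats::median(pos)))

  n_rmax <- if (shared_rmax) 1L else length(grams)
  theta0 <- c(log(kon0), log(koff0), rep(rmax0, n_rmax))
  fn <- function(th) .kin_residuals(th, grams, shared_rmax)

  best <- NULL
  for (attempt in 0:max_restarts) {
    th_try <- if (attempt == 0L) theta0 else {
      set.seed(48151L + attempt)
      theta0 * (1 + stats::runif(length(theta0), -0.2, 0.2))
    }
    fit <- try(minpack.lm::nls.lm(
      par = th_try, fn = fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 1024)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$info %in% 1:4 && all(is.finite(fit$par)) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
    if (!is.null(best) && attempt == 0L) break
  }
  if (is.null(best)) {
    stop("global kinetic fit did not converge; check phase windows and ",
         "concentration series", call. = FALSE)
  }

  theta <- best$par
  r <- fn(theta)
  dof <- max(1L, length(r) - length(theta))
  sigma2 <- sum(r^2) / dof
  J <- .num_jacobian(fn, theta)
  covm <- .pinv(crossprod(J)) * sigma2
  se <- sqrt(pmax(diag(covm), 0))

  kon <- exp(theta[1L])
  koff <- exp(theta[2L])
  rmax <- if (shared_rmax) rep(theta[3L], length(grams)) else theta[-(1:2)]
  names(rmax) <- vapply(grams, function(g)
    sprintf("%s@%.3g", g$construct, g$conc), character(1L))

  # log-scale SEs are already relative for the rates
  rel_se <- c(kon = se[1L], koff = se[2L],
              rmax = mean(se[-(1:2)] / abs(theta[-(1:2)])))

  rms <- sqrt(mean(r^2))
  noise <- .noise_estimate(grams)
  runs_z <- .runs_test_z(r)
  # runs structure only counts when residuals are above numerical noise;
  # an essentially perfect fit always has "structured" 1e-12 residuals
  scale <- max(abs(unlist(lapply(grams, `[[`, "response"))), 1e-12)
  lof <- (noise > 0 && rms / noise > 3) ||
    (rms > 1e-6 * scale && runs_z < -6)

  structure(list(kon = kon, koff = koff, kd = koff / kon, rmax = rmax,
                 rel_se = rel_se, residual_rms = rms,
                 noise_estimate = noise, runs_z = runs_z,
                 lack_of_fit = lof, n_traces = length(grams)),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> kon = %.3g /M/s (+-%.1f%%), koff = %.3g /s (+-%.1f%%), KD = %.3g M\n",
              x$kon, 100 * x$rel_se[["kon"]], x$koff,
              100 * x$rel_se[["koff"]], x$kd))
  cat(sprintf("  %d traces, residual RMS %.3g (noise %.3g)%s\n", x$n_traces,
              x$residual_rms, x$noise_estimate,
              if (x$lack_of_fit) "  ** lack of fit: one-site model inadequate **" else ""))
  invisible(x)
}

#' Fold-change summary of kinetic constants across conditions
#'
#' Ratios of `kon`, `koff` and `kd` for every (construct, NaCl) condition
#' relative to the same construct at the baseline NaCl concentration,
#' with the cross-construct average fold change per NaCl level reported as
#' the geometric mean (ratios are multiplicative); the arithmetic mean is
#' reported alongside. Constructs missing the baseline condition are
#' listed, not silently dropped.
#'
#' @param panel A data.frame with columns `construct`, `nacl`, `kon`,
#'   `koff`, `kd` (one row per fitted condition).
#' @param baseline_nacl NaCl concentration (mM) used as the per-construct
#'   baseline (default 150).
#' @return A list with `ratios` (per condition) and `summary` (per NaCl
#'   level: geometric and arithmetic mean fold changes) data.frames.
#' @export
fold_change_summary <- function(panel, baseline_nacl = 150) {
  stopifnot(is.data.frame(panel),
            all(c("construct", "nacl", "kon", "koff", "kd") %in% names(panel)))
  base <- panel[panel$nacl == baseline_nacl, ]
  missing <- setdiff(unique(panel$construct), base$construct)
  if (length(missing) > 0L) {
    stop("constructs missing the baseline condition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratios <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    b <- base[base$construct == row$construct, ]
    data.frame(construct = row$construct, nacl = row$nacl,
               kon_ratio = row$kon / b$kon,
               koff_ratio = row$koff / b$koff,
               kd_ratio = row$kd / b$kd,
               stringsAsFactors = FALSE)
  }))
  gm <- function(x) exp(mean(log(x)))
  summ <- do.call(rbind, lapply(split(ratios, ratios$nacl), function(d) {
    data.frame(nacl = d$nacl[1L],
               kon_fold_geomean = gm(d$kon_ratio),
               kon_fold_mean = mean(d$kon_ratio),
               koff_fold_geomean = gm(d$koff_ratio),
               koff_fold_mean = mean(d$koff_ratio),
               kd_fold_geomean = gm(d$kd_ratio),
               kd_fold_mean = mean(d$kd_ratio),
               n_constructs = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(ratios = ratios, summary = summ)
}
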