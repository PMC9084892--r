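#' Thermal ramp curve
#'
#' FIR (and optionally backscattered-light intensity) recorded while
#' temperature is ramped, e.g. 30 to 85 C at 1 C/min on a nanoDSF
#' instrument.
#'
#' @param construct Construct label.
#' @param temp_c Temperatures in C, strictly increasing, within 0-120 C.
#' @param fir FIR values, `> 0`.
#' @param backscatter Optional backscattered-light intensities (aggregation
#'   readout), same length as `temp_c`.
#' @param ramp_rate Ramp rate in C/min (metadata; default 1).
#' @return An object of class `"thermal_ramp"`.
#' @export
thermal_ramp <- function(construct, temp_c, fir, backscatter = NULL,
                         ramp_rate = 1) {
  stopifnot(is.character(construct), length(construct) == 1L)
  temp_c <- as.numeric(temp_c)
  fir <- as.numeric(fir)
  if (length(temp_c) != length(fir)) {
    stop("'temp_c' and 'fir' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(temp_c)) || any(diff(temp_c) <= 0)) {
    stop("'temp_c' must be finite and strictly increasing", call. = FALSE)
  }
  if (min(temp_c) < 0 || max(temp_c) > 120) {
    stop("temperatures outside the physically plausible 0-120 C range",
         call. = FALSE)
  }
  if (any(!is.finite(fir)) || any(fir <= 0)) {
    stop("FIR values must be finite and > 0", call. = FALSE)
  }
  if (!is.null(backscatter)) {
    backscatter <- as.numeric(backscatter)
    if (length(backscatter) != length(temp_c) || any(!is.finite(backscatter))) {
      stop("'backscatter' must match 'temp_c' and be finite", call. = FALSE)
    }
  }
  structure(list(construct = construct, temp_c = temp_c, fir = fir,
                 backscatter = backscatter, ramp_rate = ramp_rate),
            class = "thermal_ramp")
}

#' @export
print.thermal_ramp <- function(x, ...) {
  cat(sprintf("<thermal_ramp> %s: %d samples, %.1f-%.1f C%s\n", x$construct,
              length(x$temp_c), min(x$temp_c), max(x$temp_c),
              if (is.null(x$backscatter)) "" else ", with backscatter"))
  invisible(x)
}

## Savitzky-Golay style local quadratic fit over a temperature window.
## Returns the derivative of order `deriv` (0 = smoothed value) at each
## sample. The window shrinks at the scan endpoints instead of padding, and
## the temperature-based window handles mildly nonuniform grids.
.local_poly_deriv <- function(x, y, half_window, deriv = 1L) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- which(x >= x[i] - half_window & x <= x[i] + half_window)
    if (length(idx) < 4L) {  # too few points for a stable quadratic
      idx <- seq.int(max(1L, i - 2L), min(n, i + 2L))
    }
    dx <- x[idx] - x[i]
    fit <- stats::lm.fit(cbind(1, dx, dx^2), y[idx])
    out[i] <- switch(as.character(deriv),
                     "0" = fit$coefficients[1L],
                     "1" = fit$coefficients[2L],
                     "2" = 2 * fit$coefficients[3L])
  }
  out
}

#' Smoothed derivative dFIR/dT of a thermal ramp
#'
#' Order-2 Savitzky-Golay smoothing over a temperature window, with the
#' analytic first derivative of the local quadratic evaluated at each
#' sample. The window shrinks at the endpoints of the scan; output is
#' aligned to the input temperatures. The order-2 polynomial reproduces the
#' exact derivative of any quadratic input away from the endpoints.
#'
#' @param curve A [thermal_ramp()].
#' @param smooth_window Full smoothing window in C (default 2.5).
#' @return A data.frame with columns `temp_c` and `dfir_dt`.
#' @export
fir_derivative <- function(curve, smooth_window = 2.5) {
  stopifnot(inherits(curve, "thermal_ramp"))
  .check_scalar(smooth_window, "smooth_window", positive = TRUE)
  span <- max(curve$temp_c) - min(curve$temp_c)
  if (smooth_window > span) {
    stop("smoothing window larger than the scanned temperature range",
         call. = FALSE)
  }
  d <- .local_poly_deriv(curve$temp_c, curve$fir, smooth_window / 2, 1L)
  data.frame(temp_c = curve$temp_c, dfir_dt = d)
}

## peak prominence: height above the higher of the two bounding valleys,
## where a valley is the minimum between the peak and the nearest
## higher-or-equal peak (or the series end) on each side
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    n <- length(y)
    left_bound <- 1L
    for (j in seq_len(p - 1L)) {
      k <- p - j
      if (y[k] >= y[p]) { left_bound <- k; break }
    }
    right_bound <- n
    if (p < n) for (k in (p + 1L):n) {
      if (y[k] >= y[p]) { right_bound <- k; break }
    }
    left_min <- if (left_bound < p) min(y[left_bound:(p - 1L)]) else y[p]
    right_min <- if (right_bound > p) min(y[(p + 1L):right_bound]) else y[p]
    y[p] - max(left_min, right_min)
  }, numeric(1L))
}

#' Detect unfolding transitions in a dFIR/dT series
#'
#' Local maxima of the derivative with prominence at least
#' `min_prominence` times the global derivative maximum are reported as
#' melting transitions (Tm = derivative-peak temperature). Shoulders --
#' zero crossings of the second derivative where the first derivative is
#' positive but no resolved peak exists -- are reported separately as
#' low-confidence candidates.
#'
#' @param derivative A data.frame with columns `temp_c`, `dfir_dt`, as from
#'   [fir_derivative()].
#' @param min_prominence Prominence threshold as a fraction of the global
#'   derivative maximum (default 0.1).
#' @param smooth_window Window in C for the second-derivative shoulder
#'   scan (default 2.5).
#' @return A data.frame with columns `tm_c`, `prominence`, `kind`
#'   (`"peak"` or `"shoulder"`), ordered by temperature; zero rows when the
#'   derivative is flat.
#' @export
detect_transitions <- function(derivative, min_prominence = 0.1,
                               smooth_window = 2.5) {
  stopifnot(is.data.frame(derivative), nrow(derivative) > 0L,
            all(c("temp_c", "dfir_dt") %in% names(derivative)))
  tc <- derivative$temp_c
  d <- derivative$dfir_dt
  n <- length(d)
  out <- data.frame(tm_c = numeric(0), prominence = numeric(0),
                    kind = character(0), stringsAsFactors = FALSE)
  dmax <- max(d)
  if (n < 3L || dmax <= 0 || (max(d) - min(d)) < 1e-12 * max(1, abs(dmax))) {
    return(out)  # flat derivative: no transition
  }
  # endpoint estimates come from shrunken windows and carry inflated
  # variance; peaks are only accepted strictly inside the scan
  interior <- 2:(n - 1L)
  interior <- interior[tc[interior] >= tc[1L] + smooth_window / 2 &
                       tc[interior] <= tc[n] - smooth_window / 2]
  is_peak <- interior[d[interior] > d[interior - 1L] &
                      d[interior] >= d[interior + 1L]]
  if (length(is_peak) > 0L) {
    prom <- .peak_prominence(d, is_peak)
    keep <- prom >= min_prominence * dmax
    if (any(keep)) {
      # refine each peak by the vertex of a local quadratic: the sample
      # argmax alone jitters with noise and grid spacing
      tm <- vapply(is_peak[keep], function(p) {
        sel <- which(tc >= tc[p] - smooth_window / 2 &
                     tc <= tc[p] + smooth_window / 2)
        if (length(sel) < 5L) return(tc[p])
        dx <- tc[sel] - tc[p]
        cf <- stats::lm.fit(cbind(1, dx, dx^2), d[sel])$coefficients
        if (!is.finite(cf[3L]) || cf[3L] >= 0) return(tc[p])
        vertex <- -cf[2L] / (2 * cf[3L])
        # keep the refinement local; fall back to the argmax otherwise
        if (abs(vertex) > smooth_window / 2) tc[p] else tc[p] + vertex
      }, numeric(1L))
      out <- data.frame(tm_c = tm, prominence = prom[keep],
                        kind = "peak", stringsAsFactors = FALSE)
      # merge refined peaks that collapsed onto the same transition
      out <- out[order(-out$prominence), , drop = FALSE]
      merged <- logical(nrow(out))
      for (i in seq_len(nrow(out))) {
        if (merged[i]) next
        merged <- merged | (abs(out$tm_c - out$tm_c[i]) < smooth_window / 2 &
                            seq_len(nrow(out)) > i)
      }
      out <- out[!merged, , drop = FALSE]
    }
  }
  # shoulder scan: second-derivative zero crossings with positive slope of
  # FIR, away from already-reported peaks
  d2 <- .local_poly_deriv(tc, d, smooth_window / 2, 1L)
  cross <- which(d2[-n] > 0 & d2[-1L] <= 0)
  for (i in cross) {
    t_sh <- tc[i]
    if (d[i] <= min_prominence * dmax) next
    if (nrow(out) > 0L && any(abs(out$tm_c - t_sh) < smooth_window)) next
    out <- rbind(out, data.frame(tm_c = t_sh, prominence = NA_real_,
                                 kind = "shoulder", stringsAsFactors = FALSE))
  }
  out <- out[order(out$tm_c), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## refine one transition temperature by fitting a logistic step over a
## local linear baseline to the FIR within +-window of the detected peak.
## The derivative locates and counts transitions, but its peak position is
## a statistically inefficient Tm estimator at realistic noise; the local
## model fit localizes the midpoint much more sharply. A neighboring
## transition's tail inside the window induces a small (<0.1 C at 10 C
## separation) bias, the price of robustness to spurious components.
.refine_tm_logistic <- function(curve, tm0, window = 5) {
  x0 <- curve$temp_c
  sel <- which(x0 >= tm0 - window & x0 <= tm0 + window)
  if (length(sel) < 8L) return(tm0)
  x <- x0[sel]
  y <- curve$fir[sel]
  fn <- function(th) {
    th[1L] + th[2L] * (x - tm0) +
      th[3L] * stats::plogis((x - th[4L]) / exp(th[5L])) - y
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(min(y), 0, max(y) - min(y), tm0, log(1.5)), fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 512)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4) return(tm0)
  tm <- fit$par[4L]
  if (!is.finite(tm) || abs(tm - tm0) > window / 2) tm0 else tm
}

#' Melting analysis of a thermal ramp
#'
#' Smoothed derivative, transition detection, local-logistic Tm
#' refinement, and aggregation-onset detection (when backscatter is
#' present) in one call. Transitions are located and counted on the
#' derivative; each peak's Tm is then sharpened by fitting a logistic step
#' with a local linear baseline to the FIR within `refine_window` of the
#' peak, which localizes the midpoint substantially better than the
#' derivative argmax under noise. Set `refine = FALSE` for raw
#' derivative-peak temperatures.
#'
#' @inheritParams fir_derivative
#' @inheritParams detect_transitions
#' @param refine Refine peak Tm values by a local logistic fit (default
#'   `TRUE`; shoulders are never refined).
#' @param refine_window Half-width in C of the refinement fit window
#'   (default 5, truncated at the midpoint to neighboring transitions).
#' @return A list with `derivative`, `transitions` and `aggregation_onset`
#'   (`NA` when no backscatter channel or no onset).
#' @export
melting_analysis <- function(curve, smooth_window = 2.5,
                             min_prominence = 0.1, refine = TRUE,
                             refine_window = 5) {
  deriv <- fir_derivative(curve, smooth_window)
  trans <- detect_transitions(deriv, min_prominence, smooth_window)
  if (refine && any(trans$kind == "peak")) {
    pk <- which(trans$kind == "peak")
    for (i in pk) {
      trans$tm_c[i] <- .refine_tm_logistic(curve, trans$tm_c[i],
                                           refine_window)
    }
    trans <- trans[order(trans$tm_c), , drop = FALSE]
    rownames(trans) <- NULL
  }
  onset <- if (is.null(curve$backscatter)) NA_real_ else
    aggregation_onset(curve)
  list(derivative = deriv, transitions = trans, aggregation_onset = onset)
}

#' Aggregation onset from backscattered light
#'
#' The onset is the lowest temperature at which backscatter exceeds
#' (baseline mean + `k_sigma` * baseline sd) and stays above that level for
#' at least 1 C of scan. The baseline is the first `baseline_window` C of
#' the scan. Returns `NA` when the threshold is never durably exceeded,
#' mirroring constructs protected from aggregation over the whole scan.
#'
#' @param curve A [thermal_ramp()] with a backscatter channel.
#' @param baseline_window Baseline span in C from the scan start (default 5).
#' @param k_sigma Threshold in baseline standard deviations (default 5).
#' @return Onset temperature in C, or `NA` if never exceeded. If the
#'   backscatter is already rising within the baseline window, the scan
#'   start is returned with a baseline-undefined warning.
#' @export
aggregation_onset <- function(curve, baseline_window = 5, k_sigma = 5) {
  stopifnot(inherits(curve, "thermal_ramp"))
  if (is.null(curve$backscatter)) {
    stop("no backscatter channel in this ramp", call. = FALSE)
  }
  .check_scalar(baseline_window, "baseline_window", positive = TRUE)
  .check_scalar(k_sigma, "k_sigma", positive = TRUE)
  tc <- curve$temp_c
  bs <- curve$backscatter
  base_idx <- which(tc <= tc[1L] + baseline_window)
  if (length(base_idx) < 4L) {
    stop("too few samples in the baseline window", call. = FALSE)
  }
  # baseline trend check: a drifting baseline makes the threshold meaningless
  dxb <- tc[base_idx] - tc[base_idx][1L]
  bfit <- stats::lm.fit(cbind(1, dxb), bs[base_idx])
  resid_sd <- stats::sd(bfit$residuals)
  trend <- abs(bfit$coefficients[2L]) * baseline_window
  if (resid_sd == 0) resid_sd <- .Machine$double.eps
  if (trend > 5 * resid_sd) {
    warning("backscatter rises within the baseline window; ",
            "baseline undefined, returning scan start", call. = FALSE)
    return(tc[1L])
  }
  thr <- mean(bs[base_idx]) + k_sigma * stats::sd(bs[base_idx])
  above <- bs > thr
  cand <- which(above)
  for (i in cand) {
    hold <- which(tc >= tc[i] & tc <= tc[i] + 1)
    if (all(above[hold])) return(tc[i])
  }
  NA_real_
}
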