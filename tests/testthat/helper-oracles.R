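# Independent oracles, coded separately from the package implementation.

# Literal transcription of the three-state fitting function: numerator of
# population-weighted baselines over the partition function, written with
# plain exponentials (no log-sum-exp rearrangement).
oracle_fir_three_state <- function(bN, sN, bI, sI, bD, sD,
                                   dG_I0, mI, dG_D0, mD, C, TK) {
  rt <- 1.9872e-3 * TK
  eI <- exp(-(dG_I0 + mI * C) / rt)
  eD <- exp(-(dG_D0 + mD * C) / rt)
  ((bN + sN * C) + (bI + sI * C) * eI + (bD + sD * C) * eD) / (1 + eI + eD)
}

# Closed-form two-state linear-extrapolation curve (N and I only).
oracle_fir_two_state <- function(bN, sN, bI, sI, dG_I0, mI, C, TK) {
  rt <- 1.9872e-3 * TK
  K <- exp(-(dG_I0 + mI * C) / rt)
  ((bN + sN * C) + (bI + sI * C) * K) / (1 + K)
}

# Bisection on the one-site mass balance ka = B / ((S - B) * (X - B));
# independent of the quadratic-root solver in the package.
oracle_bound_bisection <- function(s_tot, x_tot, ka, tol = 1e-15) {
  f <- function(b) ka * (s_tot - b) * (x_tot - b) - b
  lo <- 0
  hi <- min(s_tot, x_tot)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ITC heats through the bisection oracle, same displacement bookkeeping
# convention recomputed independently.
oracle_itc_heats <- function(cell_conc, syringe_conc, vols_analyzed,
                             priming, v0, n, ka, dh) {
  vols <- c(if (priming > 0) priming, vols_analyzed)
  m <- cell_conc
  x <- 0
  b_prev <- 0
  q <- numeric(length(vols))
  for (i in seq_along(vols)) {
    f <- 1 - vols[i] / v0
    m <- m * f
    x <- x * f + syringe_conc * vols[i] / v0
    b <- oracle_bound_bisection(n * m, x, ka)
    q[i] <- v0 * dh * (b - b_prev * (1 - vols[i] / (2 * v0)))
    b_prev <- b
  }
  if (priming > 0) q <- q[-1L] else q
}

# default four-construct truth values used across recovery tests
TRUTH_DG_I0 <- c("A1 short" = 2.5, "A1+OGly+C" = 2.7,
                 "A1+OGly+N" = 4.5, "A1+OGly+N+C" = 4.7)
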