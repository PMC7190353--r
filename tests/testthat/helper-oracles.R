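# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths.

# Direct evaluation of the WLC interpolation formula.
oracle_wlc <- function(Lambda, lp = 20, kBT = 4) {
  (kBT / lp) * (1 / (4 * (1 - Lambda)^2) + Lambda - 0.25)
}

# Plain bisection on the steady-state residual, independent of uniroot.
oracle_ss_rest_length <- function(lambda, s, tol = 1e-10) {
  g <- function(ell) {
    T <- oracle_wlc(lambda * s$ell0p / ell, s$wlc$persistence_length, s$wlc$kBT)
    beta <- 1 / s$wlc$kBT
    nu_u <- s$nu_u0 * exp(beta * T * s$dx_fu)
    nu_f <- s$nu_f0 * exp(-beta * T * s$dx_uf)
    ell - (nu_u * s$ell_u + nu_f * s$ell_f) / (nu_u + nu_f)
  }
  lo <- max(s$ell_f, lambda * s$ell0p * (1 + 1e-6))
  hi <- s$ell_u * (1 - 1e-9)
  if (g(lo) >= 0) return(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

default_geometry <- function() cantilever_geometry(k = 0.1, L0 = 150, radius = 0.5)
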