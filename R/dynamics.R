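# Tension-dependent unfolding/refolding kinetics: steady states, relaxation
# times and step-strain protocol simulation.

#' Tension-dependent unfolding and refolding rates
#'
#' Bell-type kinetics: tension tilts the folding energy landscape toward the
#' unfolded state, accelerating unfolding and hindering refolding,
#' \deqn{\nu_u = \nu_u(0)\,e^{\beta T \Delta x_{fu}}, \qquad
#'       \nu_f = \nu_f(0)\,e^{-\beta T \Delta x_{uf}}.}
#'
#' @param tension Element tension in pN (\eqn{\ge 0}). Vectorised.
#' @param species A [crosslinker_species()] object.
#' @return A list with numeric components `nu_u` and `nu_f` in 1/s.
#' @export
#' @examples
#' transition_rates(0, spectrin_species()) # zero-tension rates
transition_rates <- function(tension, species) {
  stopifnot(inherits(species, "crosslinker_species"))
  if (any(tension < 0)) stop("tension must be non-negative")
  beta <- 1 / species$wlc$kBT
  list(nu_u = species$nu_u0 * exp(beta * tension * species$dx_fu),
       nu_f = species$nu_f0 * exp(-beta * tension * species$dx_uf))
}

#' Rate of change of the rest length of an element
#'
#' The mean-field rate equation for the rest (contour) length,
#' \deqn{d\ell/dt = -\nu_f(T)(\ell - \ell_f) + \nu_u(T)(\ell_u - \ell),}
#' where \eqn{\ell - \ell_f} and \eqn{\ell_u - \ell} are proportional to the
#' number of unfolded and folded repeats and the rates are evaluated at the
#' instantaneous element tension.
#'
#' @param ell Current rest length in nm.
#' @param lambda Axon deformation \eqn{\lambda = 1 + \gamma}.
#' @param species A [crosslinker_species()] object.
#' @return d\eqn{\ell}/dt in nm/s.
#' @export
rest_length_rate <- function(ell, lambda, species) {
  stopifnot(inherits(species, "crosslinker_species"))
  T <- element_tension(lambda, ell, species$ell0p, species$wlc)
  r <- transition_rates(T, species)
  -r$nu_f * (ell - species$ell_f) + r$nu_u * (species$ell_u - ell)
}

# Steady-state residual g(ell) = ell - (nu_u ell_u + nu_f ell_f)/(nu_u+nu_f),
# written via the rate ratio so that it stays finite when the tension (and
# hence nu_u) overflows near full extension. g is monotone increasing in ell:
# tension falls with ell, so the target rest length falls as well.
.ss_residual <- function(ell, lambda, species) {
  T <- wlc_tension(pmin(lambda * species$ell0p / ell, .LAMBDA_MAX - 1e-12),
                   species$wlc)
  beta <- 1 / species$wlc$kBT
  ratio <- (species$nu_u0 / species$nu_f0) *
    exp(beta * T * (species$dx_fu + species$dx_uf)) # nu_u / nu_f
  target <- species$ell_u - (species$ell_u - species$ell_f) / (1 + ratio)
  ell - target
}

#' Steady-state rest length at fixed deformation
#'
#' Solves \eqn{\ell_{ss} = (\nu_u \ell_u + \nu_f \ell_f)/(\nu_u + \nu_f)}
#' self-consistently (the rates depend on \eqn{\ell_{ss}} through the WLC
#' tension) by root finding on the monotone residual, bracketed between
#' \eqn{\max(\ell_f, \lambda\ell_0')} and \eqn{\ell_u}. If the
#' self-consistent solution would fall below the bracket (possible at low
#' strain when refolding dominates), the result is clamped to the lower
#' bound and carries the attribute `clamped = TRUE`.
#'
#' @param lambda Axon deformation (scalar).
#' @param species A [crosslinker_species()] object.
#' @return Steady-state rest length in nm, residual below 1e-9 nm when not
#'   clamped.
#' @export
steady_state_rest_length <- function(lambda, species) {
  stopifnot(inherits(species, "crosslinker_species"),
            is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  if (lambda * species$ell0p >= species$ell_u)
    stop("protocol exceeds fully unfolded length")
  lo <- max(species$ell_f, lambda * species$ell0p * (1 + 1e-6))
  hi <- species$ell_u * (1 - 1e-9)
  if (.ss_residual(lo, lambda, species) >= 0)
    return(structure(lo, clamped = TRUE))
  root <- stats::uniroot(.ss_residual, c(lo, hi), lambda = lambda,
                         species = species, tol = 1e-12)$root
  structure(root, clamped = FALSE)
}

#' Steady-state tension versus strain
#'
#' Evaluates the equilibrium tension curve of an [axon_model()]: for each
#' strain on the grid, each species relaxes to its steady-state rest length
#' and the total tension is the copy-number-weighted sum of element
#' tensions. The curve is the locus passed through by the long-time tension
#' after each step of a step-strain protocol, and its secant modulus
#' decreases with strain (strain softening) because the rest length grows.
#'
#' @param gamma Numeric vector of strains (\eqn{\ge 0}).
#' @param model An [axon_model()] object.
#' @return A data frame with columns `gamma`, `tension_nN` and one
#'   `ell_ss_<species>` column (nm) per species.
#' @export
#' @examples
#' steady_state_tension_curve(c(0, 0.1), axon_model(spectrin_species()))
steady_state_tension_curve <- function(gamma, model) {
  stopifnot(inherits(model, "axon_model"), is.numeric(gamma))
  if (any(gamma < 0)) stop("strains must be non-negative")
  out <- data.frame(gamma = gamma, tension_nN = 0)
  for (s in model$species) {
    ells <- vapply(1 + gamma, function(l)
      as.numeric(steady_state_rest_length(l, s)), numeric(1))
    T <- element_tension(1 + gamma, ells, s$ell0p, s$wlc)
    out$tension_nN <- out$tension_nN + s$n * T / 1000
    out[[paste0("ell_ss_", s$name)]] <- ells
  }
  out
}

#' Analytic tension relaxation time after a small strain step
#'
#' Linearising the rest-length dynamics about the steady state at
#' deformation \eqn{\lambda} gives an exponential tension decay with
#' \deqn{\tau = \left[(\nu_u + \nu_f) + \frac{\nu_u \nu_f}{\nu_u + \nu_f}
#'   \frac{\ell_u - \ell_f}{\ell}\,\beta(\Delta x_{fu} + \Delta x_{uf})\,
#'   \Lambda K(\Lambda)\right]^{-1},}
#' with every strain-dependent quantity evaluated at the pre-step steady
#' state. The first term is the constant-rate limit; the second accounts for
#' the tension dependence of the rates and makes \eqn{\tau(\gamma)}
#' non-monotonic: refolding-limited growth at small strain, then decay as
#' unfolding accelerates.
#'
#' @param lambda Pre-step deformation (scalar).
#' @param species A [crosslinker_species()] object.
#' @return Relaxation time in s.
#' @export
relaxation_time_analytic <- function(lambda, species) {
  ell <- as.numeric(steady_state_rest_length(lambda, species))
  Lambda <- lambda * species$ell0p / ell
  T <- wlc_tension(Lambda, species$wlc)
  r <- transition_rates(T, species)
  K <- wlc_stiffness(Lambda, species$wlc)
  beta <- 1 / species$wlc$kBT
  denom <- (r$nu_u + r$nu_f) +
    (r$nu_u * r$nu_f / (r$nu_u + r$nu_f)) *
    ((species$ell_u - species$ell_f) / ell) *
    beta * (species$dx_fu + species$dx_uf) * Lambda * K
  1 / denom
}

#' Numeric tension relaxation time (independent of the analytic formula)
#'
#' Equilibrates the element at deformation \eqn{\lambda}, applies a small
#' strain increment, integrates the rest-length rate equation and fits a
#' single exponential (log-linear regression on the tension increment over
#' its mid-decay window) toward the new steady state. Serves as the
#' independent oracle for [relaxation_time_analytic()].
#'
#' @param lambda Pre-step deformation (scalar).
#' @param species A [crosslinker_species()] object.
#' @param delta_gamma Strain increment. The linearisation error in the
#'   fitted time constant is first order in `delta_gamma`; the default
#'   2e-4 keeps it well below 1 percent.
#' @param fit_window Fraction of the initial tension increment between
#'   which the log-linear fit is taken (default decay from 50 to 2 percent).
#' @return Fitted relaxation time in s.
#' @export
relaxation_time_numeric <- function(lambda, species, delta_gamma = 2e-4,
                                    fit_window = c(0.02, 0.5)) {
  stopifnot(delta_gamma > 0)
  ell0 <- as.numeric(steady_state_rest_length(lambda, species))
  lam2 <- lambda + delta_gamma
  ell_new <- as.numeric(steady_state_rest_length(lam2, species))
  T_new <- element_tension(lam2, ell_new, species$ell0p, species$wlc)
  # with tension-independent rates a strain step leaves the rest-length
  # fixed point untouched; expose the relaxation by perturbing the rest
  # length instead
  if (abs(ell_new - ell0) < 1e-9 * ell0)
    ell0 <- ell_new - 1e-4 * (species$ell_u - species$ell_f)
  # timescale guess from the bare rates at the pre-step steady state
  T0 <- element_tension(lambda, as.numeric(
    steady_state_rest_length(lambda, species)), species$ell0p, species$wlc)
  r0 <- transition_rates(T0, species)
  tmax <- 20 / (r0$nu_u + r0$nu_f)
  rhs <- function(t, y, p) {
    T <- element_tension(lam2, y[1], species$ell0p, species$wlc)
    r <- transition_rates(T, species)
    list(-r$nu_f * (y[1] - species$ell_f) + r$nu_u * (species$ell_u - y[1]))
  }
  inc <- NULL
  for (it in 1:12) {
    # log-spaced grid: resolves the decay whatever its timescale
    ts <- c(0, exp(seq(log(tmax * 1e-7), log(tmax), length.out = 800)))
    sol <- deSolve::ode(c(ell = ell0), ts, rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-13)
    Tt <- element_tension(lam2, sol[, 2], species$ell0p, species$wlc)
    inc <- Tt - T_new
    if (abs(inc[length(inc)]) < 0.1 * fit_window[1] * abs(inc[1])) break
    tmax <- tmax * 3
  }
  if (abs(inc[length(inc)]) >= fit_window[1] * abs(inc[1]))
    stop("relaxation did not converge within the integration horizon")
  sel <- which(abs(inc) > fit_window[1] * abs(inc[1]) &
               abs(inc) < fit_window[2] * abs(inc[1]))
  if (length(sel) < 5) stop("too few points in the exponential fit window")
  fit <- stats::lm(log(abs(inc[sel])) ~ ts[sel])
  -1 / stats::coef(fit)[[2]]
}

#' Simulate a step-strain protocol
#'
#' Initialises every species at its steady state for the strain of the
#' first protocol segment (zero if the protocol starts later than t = 0),
#' applies each strain step instantaneously (rest lengths are continuous,
#' tension jumps), and integrates the rest-length rate equations between
#' steps with an adaptive stiff-capable integrator. Tension relaxes
#' monotonically toward the steady-state value of the new strain after each
#' step.
#'
#' @param model An [axon_model()] object.
#' @param protocol A [strain_protocol()] object.
#' @param n_per_segment Output samples per constant-strain segment
#'   (log-spaced to resolve the fast post-step decay).
#' @param rtol,atol Relative and absolute integration tolerances; the
#'   defaults (1e-8, 1e-10 nm) are tight because the rates span seven
#'   orders of magnitude.
#' @param initial_ell Optional vector of initial rest lengths (nm), one per
#'   species. Default: the zero-strain equilibrium, so a protocol whose
#'   first step is at t = 0 shows the full tension jump and relaxation.
#' @return A `tension_trace` data frame with columns `t` (s), `gamma`,
#'   `tension_nN`, and one `ell_<species>` column (nm) per species. The
#'   model and protocol are attached as attributes.
#' @export
#' @examples
#' pr <- strain_protocol(0, 0.05, end_time = 50)
#' tr <- simulate_protocol(axon_model(spectrin_species()), pr,
#'                         n_per_segment = 50)
#' tail(tr, 2)
simulate_protocol <- function(model, protocol, n_per_segment = 200,
                              rtol = 1e-8, atol = 1e-10, initial_ell = NULL) {
  stopifnot(inherits(model, "axon_model"), inherits(protocol, "strain_protocol"))
  sp <- model$species
  nms <- vapply(sp, `[[`, character(1), "name")

  seg_start <- c(if (!length(protocol$step_times) ||
                     protocol$step_times[1] > 0) 0,
                 protocol$step_times)
  seg_gamma <- protocol_strain(protocol, seg_start)
  seg_end <- c(seg_start[-1], protocol$end_time)

  check_feasible <- function(lam, ell, t) {
    for (i in seq_along(sp)) {
      if (lam * sp[[i]]$ell0p >= ell[i] * (1 - 1e-12))
        stop(sprintf("species '%s' overstretched at t = %g s (strain step too large)",
                     sp[[i]]$name, t))
    }
  }

  rhs <- function(t, y, p) {
    d <- numeric(length(sp))
    for (i in seq_along(sp)) {
      T <- element_tension(p$lambda, y[i], sp[[i]]$ell0p, sp[[i]]$wlc)
      r <- transition_rates(T, sp[[i]])
      d[i] <- -r$nu_f * (y[i] - sp[[i]]$ell_f) + r$nu_u * (sp[[i]]$ell_u - y[i])
    }
    list(d)
  }

  ell <- if (is.null(initial_ell)) {
    vapply(sp, function(s)
      as.numeric(steady_state_rest_length(1, s)), numeric(1))
  } else {
    stopifnot(length(initial_ell) == length(sp))
    as.numeric(initial_ell)
  }

  rows <- vector("list", length(seg_start))
  for (k in seq_along(seg_start)) {
    lam <- 1 + seg_gamma[k]
    check_feasible(lam, ell, seg_start[k])
    W <- seg_end[k] - seg_start[k]
    ts <- unique(c(0, exp(seq(log(max(W * 1e-5, 1e-9)), log(W),
                              length.out = n_per_segment - 1))))
    sol <- deSolve::ode(ell, ts, rhs, parms = list(lambda = lam),
                        method = "lsoda", rtol = rtol, atol = atol)
    ellmat <- sol[, -1, drop = FALSE]
    Tmat <- vapply(seq_along(sp), function(i)
      element_tension(lam, ellmat[, i], sp[[i]]$ell0p, sp[[i]]$wlc),
      numeric(nrow(ellmat)))
    Tmat <- matrix(Tmat, nrow = nrow(ellmat))
    total <- as.numeric(Tmat %*% vapply(sp, `[[`, numeric(1), "n")) / 1000
    seg <- data.frame(t = seg_start[k] + sol[, 1], gamma = seg_gamma[k],
                      tension_nN = total)
    for (i in seq_along(sp)) seg[[paste0("ell_", nms[i])]] <- ellmat[, i]
    rows[[k]] <- seg
    ell <- ellmat[nrow(ellmat), ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("tension_trace", "data.frame"),
            model = model, protocol = protocol)
}
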