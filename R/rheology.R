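# Stretch-rheology pipeline: cantilever record -> strain/force/tension,
# steady-state tensions, rest tension, effective Young's moduli, softening
# curve, and double-exponential relaxation fits.

#' Cantilever and axon geometry
#'
#' Geometry of the lateral-pull experiment: a calibrated cantilever of force
#' constant `k` deflects the mid-point of an axon of initial length `L0`
#' sideways. The cross-sectional area is fixed at \eqn{\pi r^2}; the small
#' thinning of a stretched axon is neglected (see [radius_thinning()] for
#' the constant-volume estimate of its size).
#'
#' @param k Cantilever force constant in nN/um (equivalently pN/nm).
#' @param L0 Initial axon length in um.
#' @param radius Axon radius in um.
#' @return An object of class `cantilever_geometry` with area `A` in um^2.
#' @export
cantilever_geometry <- function(k, L0, radius) {
  stopifnot(is.numeric(k), is.numeric(L0), is.numeric(radius),
            length(k) == 1, length(L0) == 1, length(radius) == 1)
  if (k <= 0 || L0 <= 0 || radius <= 0) stop("geometry parameters must be > 0")
  structure(list(k = k, L0 = L0, radius = radius, A = pi * radius^2),
            class = "cantilever_geometry")
}

#' @export
print.cantilever_geometry <- function(x, ...) {
  cat(sprintf("Cantilever geometry: k = %g nN/um, L0 = %g um, radius = %g um (A = %.4g um^2)\n",
              x$k, x$L0, x$radius, x$A))
  invisible(x)
}

#' Strain from mid-point displacement
#'
#' The axon is pulled laterally at its mid-point; deflecting the tip by `d`
#' stretches the two half-lengths, giving
#' \deqn{\gamma = \left(\sqrt{L_0^2 + 4d^2} - L_0\right)/L_0,}
#' which is quadratic in `d` for small deflections.
#'
#' @param d Tip displacement in um (\eqn{\ge 0}). Vectorised.
#' @param L0 Initial axon length in um.
#' @return Strain (dimensionless).
#' @export
strain_from_displacement <- function(d, L0) {
  if (any(d < 0)) stop("displacement must be non-negative")
  if (any(L0 <= 0)) stop("L0 must be > 0")
  (sqrt(L0^2 + 4 * d^2) - L0) / L0
}

#' Force on the cantilever
#'
#' The cantilever base is driven to `D` while its tip lags at `d`; the
#' bending `D - d` times the force constant gives the force magnitude
#' (tensile force on the axon reported positive).
#'
#' @param D Piezo (base) displacement in um.
#' @param d Tip displacement in um.
#' @param k Force constant in nN/um.
#' @return Force in nN.
#' @export
cantilever_force <- function(D, d, k) {
  if (any(D < d)) stop("tip displacement exceeds base displacement (D < d)")
  if (any(k <= 0)) stop("force constant must be > 0")
  k * (D - d)
}

#' Axial tension from force and pulling geometry
#'
#' The force applied at the mid-point is balanced by the axial tension in
#' the two axon halves, \eqn{F = 2 \mathcal{T} \sin\theta} with
#' \eqn{\sin\theta = d/\sqrt{d^2 + (L_0/2)^2}}, so
#' \eqn{\mathcal{T} = F/(2\sin\theta)}. Undefined at `d = 0`.
#'
#' @param F Force in nN.
#' @param d Tip displacement in um (> 0 where `F` > 0).
#' @param L0 Initial axon length in um.
#' @return Tension in nN.
#' @export
axial_tension <- function(F, d, L0) {
  if (any(L0 <= 0)) stop("L0 must be > 0")
  if (any(d < 0)) stop("displacement must be non-negative")
  if (any(d == 0 & F != 0)) stop("singular geometry: d = 0 with non-zero force")
  out <- numeric(length(F * d)) # recycle
  F <- rep_len(F, length(out)); d <- rep_len(d, length(out))
  L0 <- rep_len(L0, length(out))
  nz <- d > 0
  out[nz] <- F[nz] * sqrt(d[nz]^2 + (L0[nz] / 2)^2) / (2 * d[nz])
  out
}

#' Experimental-style force record
#'
#' Container for a time series of piezo displacement `D` and cantilever tip
#' displacement `d` with its geometry. `d <= D` must hold pointwise (the
#' cantilever bends backward under load).
#'
#' @param t Times in s (strictly increasing).
#' @param D Piezo displacement in um.
#' @param d Tip displacement in um.
#' @param geometry A [cantilever_geometry()] object.
#' @return An object of class `force_record` (a data frame with attribute
#'   `geometry`).
#' @export
force_record <- function(t, D, d, geometry) {
  stopifnot(inherits(geometry, "cantilever_geometry"),
            length(t) == length(D), length(D) == length(d))
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(d < 0) || any(D < 0)) stop("displacements must be non-negative")
  if (any(d > D)) stop("tip displacement exceeds base displacement (d > D)")
  structure(data.frame(t = t, D = D, d = d),
            class = c("force_record", "data.frame"), geometry = geometry)
}

#' Convert a force record to a tension trace
#'
#' Computes strain, force and axial tension sample-wise from the pulling
#' geometry. Samples with `d = 0` have undefined tension (the force makes a
#' zero angle with the axon) and are dropped with a warning.
#'
#' @param record A [force_record()] object.
#' @return A `tension_trace` data frame with columns `t`, `gamma`,
#'   `tension_nN` (plus `F_nN`), carrying the geometry as an attribute.
#' @export
record_to_trace <- function(record) {
  stopifnot(inherits(record, "force_record"))
  g <- attr(record, "geometry")
  keep <- record$d > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) with d = 0 (tension undefined)",
                    sum(!keep)))
    record <- record[keep, , drop = FALSE]
  }
  if (!nrow(record)) stop("no usable samples in force record")
  F <- cantilever_force(record$D, record$d, g$k)
  out <- data.frame(t = record$t,
                    gamma = strain_from_displacement(record$d, g$L0),
                    tension_nN = axial_tension(F, record$d, g$L0),
                    F_nN = F)
  structure(out, class = c("tension_trace", "data.frame"), geometry = g)
}

#' Detect constant-strain windows between strain steps
#'
#' Median-smooths the strain channel, marks sample-to-sample strain changes
#' exceeding `threshold` as steps (the smallest protocol step of interest is
#' 0.01, five times the default threshold), and returns the constant-strain
#' window following each step.
#'
#' @param trace A `tension_trace` data frame (columns `t`, `gamma`,
#'   `tension_nN`).
#' @param threshold Minimal strain change recognised as a step.
#' @param smooth_window Running-median window (samples, odd).
#' @return A data frame with one row per step: `t_step`, `gamma_before`,
#'   `gamma_after`, `i_start`, `i_end` (window index range). Zero rows if no
#'   steps are found.
#' @export
segment_steps <- function(trace, threshold = 0.002, smooth_window = 5) {
  stopifnot(is.data.frame(trace), all(c("t", "gamma") %in% names(trace)))
  n <- nrow(trace)
  empty <- data.frame(t_step = numeric(0), gamma_before = numeric(0),
                      gamma_after = numeric(0), i_start = integer(0),
                      i_end = integer(0))
  if (n < 2) return(empty)
  g <- if (n > smooth_window) {
    as.numeric(stats::runmed(trace$gamma, k = smooth_window))
  } else trace$gamma
  jump <- which(abs(diff(g)) > threshold) + 1L
  if (!length(jump)) return(empty)
  # collapse runs of consecutive jump indices into single steps
  first <- jump[c(TRUE, diff(jump) > 1)]
  last <- jump[c(diff(jump) > 1, TRUE)]
  starts <- last
  ends <- c(first[-1] - 1L, n)
  out <- data.frame(t_step = trace$t[first],
                    gamma_before = g[pmax(first - 1L, 1L)],
                    gamma_after = g[ends],
                    i_start = starts, i_end = ends)
  # a record that opens already under load (gamma > threshold at the first
  # sample) begins mid-protocol: its leading segment is the window of an
  # unobserved step at the start of the record
  if (g[1] > threshold && first[1] > 1L) {
    lead <- data.frame(t_step = trace$t[1], gamma_before = NA_real_,
                       gamma_after = g[1], i_start = 1L,
                       i_end = first[1] - 1L)
    out <- rbind(lead, out)
  }
  out
}

#' Steady-state tension of a constant-strain window
#'
#' Mean tension over the final `tail_fraction` of the window's time span
#' (robust to non-uniform sampling). A window whose
#' tail still drifts (linear trend over the tail exceeding 1 percent of the
#' mean with p < 0.01) is flagged as non-stationary via the `nonstationary`
#' attribute.
#'
#' @param trace A `tension_trace` data frame.
#' @param window One row of [segment_steps()] output (or a list with
#'   `i_start`, `i_end`).
#' @param tail_fraction Fraction of the window used (default 0.1).
#' @return Steady-state tension in nN with attribute `nonstationary`.
#' @export
steady_state_tension <- function(trace, window, tail_fraction = 0.1) {
  i0 <- window$i_start[1]; i1 <- window$i_end[1]
  if (i1 - i0 + 1 < 10) stop("window too short for steady-state estimate")
  tspan <- trace$t[i1] - trace$t[i0]
  idx <- which(trace$t >= trace$t[i1] - tail_fraction * tspan)
  idx <- idx[idx >= i0 & idx <= i1]
  if (length(idx) < 3) idx <- (i1 - 2):i1
  y <- trace$tension_nN[idx]; tt <- trace$t[idx]
  est <- mean(y)
  nonstat <- FALSE
  if (stats::sd(y) > 0 && length(unique(tt)) > 2) {
    fit <- stats::lm(y ~ tt)
    drift <- abs(stats::coef(fit)[[2]]) * (max(tt) - min(tt))
    p <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 4]),
                  error = function(e) 1)
    nonstat <- is.finite(p) && p < 0.01 && drift > 0.01 * abs(est)
  }
  structure(est, nonstationary = nonstat)
}

#' Extrapolate the rest tension at zero strain
#'
#' Least-squares line through the `n_points` smallest-strain
#' (strain, steady-state tension) pairs; the intercept estimates the
#' tension of the unstretched axon.
#'
#' @param gamma Strains.
#' @param tension Steady-state tensions in nN.
#' @param n_points Number of smallest-strain pairs used (default 3; all
#'   pairs if fewer).
#' @return Rest tension in nN.
#' @export
rest_tension_extrapolate <- function(gamma, tension, n_points = 3) {
  stopifnot(length(gamma) == length(tension))
  if (length(gamma) < 2) stop("need at least 2 (strain, tension) pairs")
  ord <- order(gamma)
  use <- ord[seq_len(min(n_points, length(gamma)))]
  if (length(use) < 2) stop("need at least 2 pairs for extrapolation")
  stats::coef(stats::lm(tension[use] ~ gamma[use]))[[1]]
}

#' Effective Young's modulus
#'
#' Treats the anisotropic axon as a uniform rod:
#' \eqn{E = (\mathcal{T}_{ss} - \mathcal{T}_0)/(A \gamma)}, in kPa
#' (1 nN/um^2 = 1 kPa).
#'
#' @param tension_ss Steady-state tension in nN.
#' @param tension_0 Rest tension in nN.
#' @param area Cross-sectional area in um^2.
#' @param gamma Strain (> 0).
#' @return Modulus in kPa.
#' @export
youngs_modulus <- function(tension_ss, tension_0, area, gamma) {
  if (any(gamma <= 0)) stop("strain must be > 0")
  if (any(area <= 0)) stop("area must be > 0")
  (tension_ss - tension_0) / (area * gamma)
}

#' Fit a double-exponential relaxation
#'
#' Fits \eqn{A e^{-(t - t_{step})/\tau_1} + B e^{-(t - t_{step})/\tau_2} + C}
#' by bounded Levenberg-Marquardt least squares with multistart. Initial
#' guesses come from the tail mean (offset) and log-linear peeling of the
#' slow component; further starts are log-spaced over the window span
#' because bi-exponential fits are notoriously multimodal. `tau1 >= tau2`
#' is enforced by sorting after the fit. Nearly single-exponential data
#' (vanishing amplitude or indistinguishable time constants) set the
#' `degenerate` flag.
#'
#' @param t Times in s.
#' @param tension Tension samples in nN (same length as `t`, >= 20 samples).
#' @param t_step Step time subtracted from `t` (default 0).
#' @param n_starts Number of multistart fits (default 8).
#' @return An object of class `relaxation_fit`: list with `A`, `B`, `C`,
#'   `tau1`, `tau2`, `residual_norm`, `degenerate`.
#' @export
#' @examples
#' t <- seq(0, 300, length.out = 200)
#' y <- 2 * exp(-t / 60) + exp(-t / 5) + 5
#' fit_double_exponential(t, y)
fit_double_exponential <- function(t, tension, t_step = 0, n_starts = 8) {
  stopifnot(length(t) == length(tension))
  if (length(t) < 20) stop("need at least 20 samples for a bi-exponential fit")
  tt <- t - t_step
  if (any(tt < 0)) stop("samples before t_step")
  y <- tension
  span <- max(tt) - min(tt)
  dt <- stats::median(diff(sort(tt)))
  C0 <- mean(y[tt >= min(tt) + 0.9 * span])
  rng <- diff(range(y))
  if (rng == 0) {
    return(structure(list(A = 0, B = 0, C = y[1], tau1 = NA_real_,
                          tau2 = NA_real_, residual_norm = 0,
                          degenerate = TRUE),
                     class = "relaxation_fit"))
  }
  # log-linear peeling: slow tau from the tail of the de-offset signal
  ypos <- y - C0
  tail_i <- tt > span / 3 & ypos > 0
  tau1g <- span / 3
  if (sum(tail_i) > 5) {
    sl <- stats::coef(stats::lm(log(ypos[tail_i]) ~ tt[tail_i]))[[2]]
    if (is.finite(sl) && sl < 0) tau1g <- -1 / sl
  }
  starts <- expand.grid(tau1 = tau1g * c(0.5, 1, 2),
                        tau2 = exp(seq(log(dt), log(span / 3), length.out = 3)))
  extra <- data.frame(tau1 = exp(seq(log(2 * dt), log(span), length.out = 4)),
                      tau2 = exp(seq(log(dt), log(span / 4), length.out = 4)))
  starts <- rbind(starts, extra)
  starts <- starts[starts$tau1 > starts$tau2, , drop = FALSE]
  resid_fn <- function(p) {
    y - (p[1] * exp(-tt / p[4]) + p[2] * exp(-tt / p[5]) + p[3])
  }
  best <- NULL
  for (i in seq_len(min(nrow(starts), n_starts))) {
    p0 <- c(A = max(rng / 2, 1e-8), B = max(rng / 2, 1e-8),
            C = max(C0, 0), tau1 = starts$tau1[i], tau2 = starts$tau2[i])
    f <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      lower = c(0, 0, 0, dt / 2, dt / 2),
      upper = c(10 * rng, 10 * rng, Inf, 10 * span, 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (!inherits(f, "try-error") && f$info %in% 1:4) {
      rss <- sum(f$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best))
    stop("bi-exponential fit failed to converge from any start")
  cf <- best$fit$par
  if (cf[["tau1"]] < cf[["tau2"]])
    cf[c("A", "B", "tau1", "tau2")] <- cf[c("B", "A", "tau2", "tau1")]
  degenerate <- (min(cf[["A"]], cf[["B"]]) < 1e-3 * rng) ||
    (cf[["tau1"]] < 1.05 * cf[["tau2"]])
  structure(list(A = cf[["A"]], B = cf[["B"]], C = cf[["C"]],
                 tau1 = cf[["tau1"]], tau2 = cf[["tau2"]],
                 residual_norm = sqrt(best$rss), degenerate = degenerate),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("Bi-exponential fit: A = %.4g, B = %.4g, C = %.4g nN; tau1 = %.4g s, tau2 = %.4g s\n",
              x$A, x$B, x$C, x$tau1, x$tau2))
  cat(sprintf("  residual norm %.3g%s\n", x$residual_norm,
              if (x$degenerate) " (degenerate: effectively single-exponential)" else ""))
  invisible(x)
}

#' Softening curve: per-step steady-state tension, modulus and relaxation
#'
#' Runs the full per-record analysis: detects strain steps, estimates the
#' steady-state tension of each constant-strain window, extrapolates the
#' rest tension from the smallest strains, computes the effective Young's
#' modulus per step, and (optionally) fits the post-step relaxation with a
#' double exponential.
#'
#' @param trace A `tension_trace` data frame (see [record_to_trace()] or
#'   [simulate_protocol()]).
#' @param geometry A [cantilever_geometry()] object (for the area); taken
#'   from the trace attribute when omitted.
#' @param tail_fraction Passed to [steady_state_tension()].
#' @param n_extrap Passed to [rest_tension_extrapolate()].
#' @param fit_relaxation Fit each window with [fit_double_exponential()]?
#' @param T0 Optional known rest tension in nN. By default the rest tension
#'   is extrapolated from the smallest-strain steps; note that a linear
#'   extrapolation of a concave (softening) tension-strain curve
#'   systematically overestimates the rest tension, which can suppress the
#'   modulus of the smallest-strain step.
#' @return A `softening_table` data frame with one row per step: `gamma`,
#'   `Tss_nN`, `E_kPa`, `tau1_s`, `tau2_s`, `A_nN`, `B_nN`, `C_nN`,
#'   `nonstationary`, `degenerate`; rest tension in attribute `T0_nN`.
#' @export
softening_curve <- function(trace, geometry = attr(trace, "geometry"),
                            tail_fraction = 0.1, n_extrap = 3,
                            fit_relaxation = TRUE, T0 = NULL) {
  if (is.null(geometry) || !inherits(geometry, "cantilever_geometry"))
    stop("a cantilever_geometry is required (for the cross-sectional area)")
  if (!is.data.frame(trace) || !nrow(trace)) stop("empty trace")
  steps <- segment_steps(trace)
  if (nrow(steps) < 2) stop("need at least 2 detected strain steps")
  rows <- lapply(seq_len(nrow(steps)), function(i) {
    w <- steps[i, ]
    Tss <- steady_state_tension(trace, w, tail_fraction)
    fit <- NULL
    if (fit_relaxation && (w$i_end - w$i_start + 1) >= 20) {
      idx <- w$i_start:w$i_end
      fit <- tryCatch(
        fit_double_exponential(trace$t[idx], trace$tension_nN[idx],
                               t_step = trace$t[idx][1]),
        error = function(e) NULL)
    }
    data.frame(gamma = w$gamma_after, Tss_nN = as.numeric(Tss),
               tau1_s = if (!is.null(fit)) fit$tau1 else NA_real_,
               tau2_s = if (!is.null(fit)) fit$tau2 else NA_real_,
               A_nN = if (!is.null(fit)) fit$A else NA_real_,
               B_nN = if (!is.null(fit)) fit$B else NA_real_,
               C_nN = if (!is.null(fit)) fit$C else NA_real_,
               nonstationary = attr(Tss, "nonstationary"),
               degenerate = if (!is.null(fit)) fit$degenerate else NA)
  })
  out <- do.call(rbind, rows)
  if (is.null(T0))
    T0 <- rest_tension_extrapolate(out$gamma, out$Tss_nN, n_points = n_extrap)
  out$E_kPa <- youngs_modulus(out$Tss_nN, T0, geometry$A, out$gamma)
  out <- out[, c("gamma", "Tss_nN", "E_kPa", "tau1_s", "tau2_s",
                 "A_nN", "B_nN", "C_nN", "nonstationary", "degenerate")]
  structure(out, class = c("softening_table", "data.frame"), T0_nN = T0)
}

#' Analyze a raw force record end to end
#'
#' Convenience wrapper: [record_to_trace()] then [softening_curve()].
#'
#' @param record A [force_record()] object.
#' @param ... Passed to [softening_curve()].
#' @return A `softening_table` (see [softening_curve()]).
#' @export
analyze_record <- function(record, ...) {
  trace <- record_to_trace(record)
  softening_curve(trace, attr(record, "geometry"), ...)
}
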