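# Seeded generators for every input the pipeline consumes, with attached
# ground truth so downstream results can be checked without magic numbers.

# Run an expression with a temporary RNG state when a seed is given.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Step-strain protocol with equilibrating wait times
#'
#' Builds the conventional multi-step stretch protocol: successive up-steps
#' to the given strains, each held for `wait_factor` times the analytic
#' relaxation time at that strain (so steady state is reached before the
#' next step; the steady-state locus property needs waits of at least five
#' relaxation times). The first step is applied at t = 0.
#'
#' @param model An [axon_model()] object (the slowest species sets the
#'   waits).
#' @param gammas Target strains of the successive steps.
#' @param wait_factor Wait time per step in units of the relaxation time
#'   (default 6).
#' @return A [strain_protocol()] object.
#' @export
default_step_protocol <- function(model = axon_model(spectrin_species()),
                                  gammas = c(0.05, 0.10, 0.15, 0.20),
                                  wait_factor = 6) {
  stopifnot(inherits(model, "axon_model"), wait_factor > 0)
  waits <- vapply(gammas, function(g)
    wait_factor * max(vapply(model$species, function(s)
      relaxation_time_analytic(1 + g, s), numeric(1))), numeric(1))
  t_step <- cumsum(c(0, waits[-length(waits)]))
  strain_protocol(t_step, gammas, end_time = sum(waits))
}

#' Generate a synthetic cantilever force record
#'
#' Simulates the crosslinker model under a step-strain protocol, then
#' inverts the pulling geometry to obtain the measured channels: the tip
#' displacement from the strain, \eqn{d = (L_0/2)\sqrt{(1+\gamma)^2 - 1}},
#' the force from the tension, \eqn{F = 2\mathcal{T}\sin\theta}, and the
#' piezo position \eqn{D = d + F/k}. Gaussian measurement noise is added to
#' the tip-displacement channel (where instrument noise enters in the real
#' apparatus), and clipped at the physical bound `d <= D`.
#'
#' @param model An [axon_model()] object. For realistic force magnitudes
#'   use a few hundred copies per cross-section, e.g.
#'   `axon_model(spectrin_species(n = 300))`.
#' @param protocol A [strain_protocol()] object.
#' @param geometry A [cantilever_geometry()] object.
#' @param noise_sd Standard deviation of additive Gaussian noise on `d`,
#'   in um (default 0, noiseless).
#' @param seed Integer seed for reproducibility (RNG state is restored).
#' @param n_per_segment Passed to [simulate_protocol()].
#' @return A [force_record()] with attribute `ground_truth`: a list with
#'   the model, protocol, geometry, noiseless trace and the steady-state
#'   tension at each protocol strain.
#' @export
generate_force_record <- function(model, protocol, geometry, noise_sd = 0,
                                  seed = NULL, n_per_segment = 200) {
  stopifnot(inherits(geometry, "cantilever_geometry"), noise_sd >= 0)
  trace <- simulate_protocol(model, protocol, n_per_segment = n_per_segment)
  # drop the pre-step sample of each instantaneous jump so time is strictly
  # increasing in the record
  keep <- c(diff(trace$t) > 1e-8, TRUE)
  tr <- trace[keep, , drop = FALSE]
  lam <- 1 + tr$gamma
  d <- (geometry$L0 / 2) * sqrt(lam^2 - 1)
  sin_theta <- ifelse(d > 0, d / sqrt(d^2 + (geometry$L0 / 2)^2), 0)
  F <- 2 * tr$tension_nN * sin_theta
  D <- d + F / geometry$k
  if (noise_sd > 0)
    d <- with_seed(seed, pmin(pmax(d + stats::rnorm(length(d), 0, noise_sd), 0), D))
  gt <- list(model = model, protocol = protocol, geometry = geometry,
             trace = trace,
             Tss_nN = steady_state_tension_curve(protocol$strains,
                                                 model)$tension_nN)
  rec <- force_record(tr$t, D, d, geometry)
  attr(rec, "ground_truth") <- gt
  rec
}

#' Generate a synthetic spectrin line-scan intensity profile
#'
#' A train of Gaussian peaks (the point-spread-function-blurred actin
#' rings) at the given spacing, on a constant baseline, with additive
#' Gaussian noise. The `disorder` parameter jitters each peak position with
#' standard deviation `disorder * period`, emulating the loss of the
#' periodic lattice after actin disruption; reducing `amplitude` at fixed
#' absolute noise emulates spectrin knockdown under background-limited
#' imaging.
#'
#' @param period Peak spacing in nm (default 190).
#' @param peak_sigma Gaussian peak width in nm (default 40, a STED-scale
#'   point spread function).
#' @param amplitude Peak amplitude in arbitrary units (default 1).
#' @param baseline Constant baseline intensity (default 0.5).
#' @param noise_sd Additive Gaussian noise, absolute units (default 0.1).
#' @param length Profile length in nm (default 20000; twenty 1-um
#'   segments).
#' @param dx Sampling step in nm (default 10, well below the period).
#' @param disorder Peak-position jitter in units of the period (default 0).
#' @param seed Integer seed (RNG state restored).
#' @return An [intensity_profile()] with attribute `ground_truth`.
#' @export
generate_intensity_profile <- function(period = 190, peak_sigma = 40,
                                       amplitude = 1, baseline = 0.5,
                                       noise_sd = 0.1, length = 20000,
                                       dx = 10, disorder = 0, seed = NULL) {
  if (length < 5 * period) stop("profile must span at least 5 periods")
  if (dx > period / 5) stop("sampling step too coarse for the period")
  if (amplitude < 0 || baseline < 0 || noise_sd < 0 || disorder < 0)
    stop("amplitude, baseline, noise_sd and disorder must be non-negative")
  with_seed(seed, {
    x <- seq(0, length, by = dx)
    centers <- seq(-2 * period, length + 2 * period, by = period)
    if (disorder > 0)
      centers <- centers + stats::rnorm(base::length(centers), 0,
                                        disorder * period)
    I <- baseline
    if (amplitude > 0)
      I <- I + amplitude *
        rowSums(exp(-outer(x, centers, "-")^2 / (2 * peak_sigma^2)))
    else I <- rep(baseline, base::length(x))
    if (noise_sd > 0) I <- I + stats::rnorm(base::length(x), 0, noise_sd)
    prof <- intensity_profile(x, pmax(I, 0))
    attr(prof, "ground_truth") <- list(period = period,
                                       peak_sigma = peak_sigma,
                                       amplitude = amplitude,
                                       baseline = baseline,
                                       noise_sd = noise_sd,
                                       disorder = disorder, seed = seed)
    prof
  })
}

#' Generate a synthetic bi-exponential relaxation trace
#'
#' Exact model-class data for validating [fit_double_exponential()]:
#' \eqn{A e^{-t/\tau_1} + B e^{-t/\tau_2} + C} sampled uniformly, with
#' optional multiplicative or additive Gaussian noise.
#'
#' @param A,B,C Amplitudes and offset in nN.
#' @param tau1,tau2 Time constants in s, `tau1 >= tau2 > 0`.
#' @param n Number of samples (default 500).
#' @param span Record length in s (default `5 * tau1`).
#' @param noise `"multiplicative"` (relative sd) or `"additive"`
#'   (absolute sd, nN).
#' @param noise_sd Noise scale (default 0, noiseless).
#' @param t_step Step time offset added to the time axis.
#' @param seed Integer seed (RNG state restored).
#' @return A data frame `t`, `tension_nN` with attribute `ground_truth`.
#' @export
generate_relaxation_trace <- function(A = 2, B = 1, C = 5, tau1 = 60,
                                      tau2 = 5, n = 500, span = 5 * tau1,
                                      noise = c("multiplicative", "additive"),
                                      noise_sd = 0, t_step = 0, seed = NULL) {
  noise <- match.arg(noise)
  if (!(tau1 >= tau2 && tau2 > 0)) stop("need tau1 >= tau2 > 0")
  if (A < 0 || B < 0 || C < 0 || noise_sd < 0)
    stop("amplitudes, offset and noise_sd must be non-negative")
  t <- seq(0, span, length.out = n)
  y <- A * exp(-t / tau1) + B * exp(-t / tau2) + C
  if (noise_sd > 0) {
    y <- with_seed(seed, {
      eps <- stats::rnorm(n, 0, noise_sd)
      if (noise == "multiplicative") y * (1 + eps) else y + eps
    })
  }
  out <- data.frame(t = t + t_step, tension_nN = y)
  attr(out, "ground_truth") <- list(A = A, B = B, C = C, tau1 = tau1,
                                    tau2 = tau2, noise = noise,
                                    noise_sd = noise_sd, t_step = t_step,
                                    seed = seed)
  out
}
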