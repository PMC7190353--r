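# Crosslinker species, axon model and strain protocol containers.

#' Define a crosslinker species
#'
#' A species is one type of crosslinking protein spanning the axonal
#' cross-section (spectrin tetramers, tau dimers, ...). Its rest (contour)
#' length interpolates between a fully folded value `ell_f` and a fully
#' unfolded value `ell_u` as repeat domains unfold; unfolding and refolding
#' rates are tension-dependent with Bell-type reaction-coordinate lengths
#' `dx_fu` (folded to unfolded) and `dx_uf` (unfolded to folded).
#'
#' @param name Species label, used for trace column names.
#' @param ell_f Fully folded rest length in nm.
#' @param ell_u Fully unfolded rest length in nm (> `ell_f`).
#' @param ell0p Initial end-to-end length \eqn{\ell_0'} in nm at zero strain.
#' @param dx_fu Unfolding reaction-coordinate length in nm (\eqn{\ge 0}).
#' @param dx_uf Refolding reaction-coordinate length in nm (\eqn{\ge 0}).
#' @param nu_u0 Zero-tension unfolding rate in 1/s.
#' @param nu_f0 Zero-tension refolding rate in 1/s.
#' @param n Copy number per axonal cross-section (\eqn{\ge 1}).
#' @param wlc A [wlc_params()] object.
#' @return An object of class `crosslinker_species`.
#' @seealso [spectrin_species()] for literature defaults.
#' @export
crosslinker_species <- function(name, ell_f, ell_u, ell0p, dx_fu, dx_uf,
                                nu_u0, nu_f0, n = 1, wlc = wlc_params()) {
  stopifnot(is.character(name), length(name) == 1, inherits(wlc, "wlc_params"))
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(sprintf("%s must be a finite number", what))
    x
  }
  ell_f <- num1(ell_f, "ell_f"); ell_u <- num1(ell_u, "ell_u")
  ell0p <- num1(ell0p, "ell0p")
  dx_fu <- num1(dx_fu, "dx_fu"); dx_uf <- num1(dx_uf, "dx_uf")
  nu_u0 <- num1(nu_u0, "nu_u0"); nu_f0 <- num1(nu_f0, "nu_f0")
  n <- num1(n, "n")
  if (!(ell_f > 0 && ell_u > ell_f)) stop("need 0 < ell_f < ell_u")
  if (ell0p <= 0) stop("ell0p must be > 0")
  if (nu_u0 <= 0 || nu_f0 <= 0) stop("zero-tension rates must be > 0")
  if (dx_fu < 0 || dx_uf < 0) stop("reaction-coordinate lengths must be >= 0")
  if (n < 1) stop("copy number n must be >= 1")
  structure(list(name = name, ell_f = ell_f, ell_u = ell_u, ell0p = ell0p,
                 dx_fu = dx_fu, dx_uf = dx_uf, nu_u0 = nu_u0, nu_f0 = nu_f0,
                 n = n, wlc = wlc),
            class = "crosslinker_species")
}

#' @export
print.crosslinker_species <- function(x, ...) {
  cat(sprintf("Crosslinker species '%s' (n = %g per cross-section)\n", x$name, x$n))
  cat(sprintf("  rest length: folded %g nm, unfolded %g nm; ell0' = %g nm\n",
              x$ell_f, x$ell_u, x$ell0p))
  cat(sprintf("  rates: nu_u(0) = %g /s, nu_f(0) = %g /s; dx_fu = %g nm, dx_uf = %g nm\n",
              x$nu_u0, x$nu_f0, x$dx_fu, x$dx_uf))
  print(x$wlc)
  invisible(x)
}

#' Spectrin tetramer species with literature parameter values
#'
#' Default parameterisation of the axonal alpha/beta-spectrin tetramer:
#' persistence length 20 nm, initial end-to-end length 170 nm (the ring
#' spacing is ~190 nm and the tetramer spans slightly less), folded rest
#' length 200 nm, fully unfolded rest length 1200 nm, unfolding and
#' refolding reaction-coordinate lengths 2.5 nm and 15 nm, zero-tension
#' unfolding rate 1e-5 /s and refolding rate 100 /s, thermal energy
#' 4 pN nm.
#'
#' @param n Copy number per cross-section. Default 1 (a single element);
#'   the cross-section of a mature axon holds on the order of a few hundred
#'   tetramers (see [spectrin_count()]).
#' @return A [crosslinker_species()] object.
#' @export
#' @examples
#' spectrin_species()
spectrin_species <- function(n = 1) {
  crosslinker_species("spectrin",
                      ell_f = 200, ell_u = 1200, ell0p = 170,
                      dx_fu = 2.5, dx_uf = 15,
                      nu_u0 = 1e-5, nu_f0 = 100,
                      n = n, wlc = wlc_params(20, 4))
}

#' Axon cross-section model
#'
#' A parallel arrangement of one or more crosslinker species piercing a
#' cross-section of a homogeneous cylindrical axon. Total tension is the
#' copy-number-weighted sum of element tensions; there is no mechanical
#' coupling between species beyond the shared strain.
#'
#' @param species A [crosslinker_species()] object or a list of them.
#' @param label Model label.
#' @return An object of class `axon_model`.
#' @export
axon_model <- function(species, label = "axon") {
  if (inherits(species, "crosslinker_species")) species <- list(species)
  if (!is.list(species) || length(species) < 1 ||
      !all(vapply(species, inherits, logical(1), "crosslinker_species")))
    stop("species must be one or more crosslinker_species objects")
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("species names must be unique")
  structure(list(species = species, label = label), class = "axon_model")
}

#' @export
print.axon_model <- function(x, ...) {
  cat(sprintf("Axon model '%s' with %d species: %s\n", x$label,
              length(x$species),
              paste(vapply(x$species, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Step-strain protocol
#'
#' An ordered sequence of instantaneous strain steps applied to the axon,
#' each held until the next step (and the last until `end_time`). Down-steps
#' are permitted, so cyclic protocols can be expressed.
#'
#' @param step_times Strictly increasing step times in s.
#' @param strains Target strain \eqn{\gamma \ge 0} after each step.
#' @param end_time End of the simulated record in s (> last step time).
#' @return An object of class `strain_protocol`.
#' @export
#' @examples
#' strain_protocol(c(0, 100), c(0.05, 0.10), end_time = 250)
strain_protocol <- function(step_times, strains, end_time) {
  stopifnot(is.numeric(step_times), is.numeric(strains),
            length(step_times) == length(strains),
            is.numeric(end_time), length(end_time) == 1)
  if (length(step_times) > 0) {
    if (any(diff(step_times) <= 0)) stop("step times must be strictly increasing")
    if (any(strains < 0)) stop("strains must be non-negative")
    if (end_time <= step_times[length(step_times)])
      stop("end_time must exceed the last step time")
  } else if (end_time <= 0) stop("end_time must be > 0")
  structure(list(step_times = as.numeric(step_times),
                 strains = as.numeric(strains),
                 end_time = as.numeric(end_time)),
            class = "strain_protocol")
}

#' @export
print.strain_protocol <- function(x, ...) {
  cat(sprintf("Strain protocol: %d step(s), end time %g s\n",
              length(x$step_times), x$end_time))
  if (length(x$step_times))
    print(data.frame(t_step_s = x$step_times, gamma = x$strains))
  invisible(x)
}

# Piecewise-constant strain of a protocol at times t (gamma = 0 before the
# first step).
protocol_strain <- function(protocol, t) {
  stopifnot(inherits(protocol, "strain_protocol"))
  if (!length(protocol$step_times)) return(rep(0, length(t)))
  idx <- findInterval(t, protocol$step_times)
  c(0, protocol$strains)[idx + 1]
}
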