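# Order-of-magnitude estimators for the axonal cross-section: spectrin
# copy number and tension bound, microtubule sliding, tau dimer stretch,
# constant-volume radius thinning.

#' Axon envelope parameters
#'
#' Geometric and molecular scales entering the back-of-the-envelope
#' estimators.
#'
#' @param diameter Axon diameter in um (default 1, a mature axon).
#' @param spectrin_width Width of one spectrin molecule in nm (default 10).
#' @param junction_width Width of an actin-spectrin junction in nm
#'   (default 35; each junction anchors one alpha and one beta spectrin).
#' @param plateau_force Unfolding plateau force of a spectrin tetramer in
#'   pN (default 30).
#' @param mt_length Average microtubule length in um (default 4).
#' @param axon_length Axon length in um (default 200).
#' @param tau_rest_length Relaxed tau-tau dimer length in nm (default 80).
#' @return An object of class `axon_envelope`.
#' @export
axon_envelope <- function(diameter = 1, spectrin_width = 10,
                          junction_width = 35, plateau_force = 30,
                          mt_length = 4, axon_length = 200,
                          tau_rest_length = 80) {
  vals <- c(diameter = diameter, spectrin_width = spectrin_width,
            junction_width = junction_width, plateau_force = plateau_force,
            mt_length = mt_length, axon_length = axon_length,
            tau_rest_length = tau_rest_length)
  if (any(vals <= 0)) stop("all envelope parameters must be > 0")
  structure(as.list(vals), class = "axon_envelope")
}

.round_mode <- function(x, mode) {
  switch(mode,
         signif1 = signif(x, 1),
         nearest10 = 10 * round(x / 10),
         none = x,
         stop("unknown rounding mode"))
}

#' Number of spectrin molecules in a cross-section
#'
#' The circumference \eqn{\pi d} divided by the lateral footprint of one
#' molecule (or one actin-spectrin junction) gives the maximal number of
#' spectrins piercing a cylindrical cross-section,
#' `round(pi * diameter / width) * per_unit`. The two conventional
#' roundings are one significant figure (molecule-width estimate) and
#' nearest ten (junction-based estimate with 2 spectrins per junction).
#'
#' @param diameter_um Axon diameter in um.
#' @param width_nm Footprint width in nm (molecule or junction).
#' @param per_unit Spectrin molecules per footprint unit (default 1; use 2
#'   for junctions).
#' @param rounding One of `"signif1"`, `"nearest10"`, `"none"`.
#' @return Estimated count.
#' @export
#' @examples
#' spectrin_count(1, 10)                              # about 300
#' spectrin_count(1, 35, per_unit = 2, "nearest10")   # 180
spectrin_count <- function(diameter_um, width_nm, per_unit = 1,
                           rounding = c("signif1", "nearest10", "none")) {
  rounding <- match.arg(rounding)
  if (diameter_um <= 0 || width_nm <= 0 || per_unit <= 0)
    stop("all inputs must be > 0")
  .round_mode(pi * diameter_um * 1000 / width_nm * per_unit, rounding)
}

#' Upper bound on the spectrin contribution to axonal tension
#'
#' If every spectrin in the cross-section sits on its unfolding plateau,
#' the total tension is the copy number times the plateau force.
#'
#' @param count Number of spectrin molecules (\eqn{\ge 0}).
#' @param plateau_force_pN Plateau force in pN (default 30).
#' @return Tension in nN.
#' @export
#' @examples
#' spectrin_tension_bound(300) # 9 nN
spectrin_tension_bound <- function(count, plateau_force_pN = 30) {
  if (any(count < 0)) stop("count must be non-negative")
  count * plateau_force_pN / 1000
}

#' Relative sliding between adjacent microtubules under stretch
#'
#' Under affine deformation of a bundle of microtubules of length
#' `mt_length_um` spanning an axon of length `L0_um`, the extra length
#' \eqn{\gamma L_0} is shared among \eqn{n = L_0/\ell_{MT}} serial
#' microtubules, so the relative sliding is
#' \eqn{\delta x = \gamma\,\ell_{MT}} (independent of the axon length).
#'
#' @param L0_um Axon length in um.
#' @param gamma Applied strain.
#' @param mt_length_um Average microtubule length in um.
#' @return Sliding \eqn{\delta x} in nm.
#' @export
#' @examples
#' microtubule_sliding(200, 0.1, 4) # 400 nm
microtubule_sliding <- function(L0_um, gamma, mt_length_um) {
  if (any(L0_um <= 0) || any(mt_length_um <= 0)) stop("lengths must be > 0")
  if (any(gamma < 0)) stop("strain must be non-negative")
  n <- L0_um / mt_length_um
  gamma * L0_um / n * 1000
}

#' Stretch of a tau dimer bridging sliding microtubules
#'
#' A crosslinking tau dimer of relaxed length `l0_nm` anchored midway
#' between two microtubules sliding by \eqn{\delta x} is stretched by
#' \eqn{\sqrt{l_0^2 + (\delta x/2)^2} - l_0}.
#'
#' @param l0_nm Relaxed dimer length in nm.
#' @param dx_nm Microtubule sliding in nm (\eqn{\ge 0}).
#' @return Stretch in nm.
#' @export
#' @examples
#' tau_dimer_stretch(80, 400) # ~135 nm
tau_dimer_stretch <- function(l0_nm, dx_nm) {
  if (any(l0_nm <= 0)) stop("rest length must be > 0")
  if (any(dx_nm < 0)) stop("sliding must be non-negative")
  sqrt(l0_nm^2 + (dx_nm / 2)^2) - l0_nm
}

#' Constant-volume estimate of radius thinning under stretch
#'
#' First-order incompressibility gives a fractional radius change of
#' \eqn{\Delta r / r_0 = -\gamma/2}.
#'
#' @param gamma Applied strain (\eqn{\ge 0}).
#' @return A list with `fraction` (signed) and `magnitude`.
#' @export
#' @examples
#' radius_thinning(0.14) # magnitude 0.07
radius_thinning <- function(gamma) {
  if (any(gamma < 0)) stop("strain must be non-negative")
  list(fraction = -0.5 * gamma, magnitude = 0.5 * gamma)
}

#' All envelope estimates as a labeled table
#'
#' @param envelope An [axon_envelope()] object.
#' @param gamma Strain used for the sliding/stretch/thinning rows
#'   (default 0.1).
#' @return A data frame with columns `quantity`, `value`, `unit`.
#' @export
envelope_estimates <- function(envelope = axon_envelope(), gamma = 0.1) {
  stopifnot(inherits(envelope, "axon_envelope"))
  n_w <- spectrin_count(envelope$diameter, envelope$spectrin_width,
                        rounding = "signif1")
  n_j <- spectrin_count(envelope$diameter, envelope$junction_width,
                        per_unit = 2, rounding = "nearest10")
  dx <- microtubule_sliding(envelope$axon_length, gamma, envelope$mt_length)
  data.frame(
    quantity = c("spectrin count (molecule width)",
                 "spectrin count (junction width)",
                 "spectrin tension bound (upper count)",
                 "spectrin tension bound (junction count)",
                 "microtubule sliding",
                 "tau dimer stretch",
                 "radius thinning magnitude"),
    value = c(n_w, n_j,
              spectrin_tension_bound(n_w, envelope$plateau_force),
              spectrin_tension_bound(n_j, envelope$plateau_force),
              dx,
              tau_dimer_stretch(envelope$tau_rest_length, dx),
              radius_thinning(gamma)$magnitude),
    unit = c("molecules", "molecules", "nN", "nN", "nm", "nm", "")
  )
}
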