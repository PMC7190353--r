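# Worm-like-chain elasticity of a single crosslinking element.
#
# Internal unit system: pN, nm, s. Total axonal tension is reported in nN
# (1 nN = 1000 pN) at table/file interfaces only.

#' Worm-like-chain parameters
#'
#' Bundles the persistence length and thermal energy of a crosslinking
#' element. The inverse thermal energy \eqn{\beta = 1/k_BT} converts a
#' tension times a reaction-coordinate length into a dimensionless Boltzmann
#' exponent, so both quantities are kept in the pN/nm unit system.
#'
#' @param persistence_length Persistence length \eqn{\ell_p} in nm. The
#'   default 20 nm is the literature value for the spectrin tetramer.
#' @param kBT Thermal energy \eqn{k_BT} in pN nm (default 4, room
#'   temperature).
#' @return An object of class `wlc_params`.
#' @export
#' @examples
#' wlc_params()
wlc_params <- function(persistence_length = 20, kBT = 4) {
  stopifnot(is.numeric(persistence_length), length(persistence_length) == 1,
            is.numeric(kBT), length(kBT) == 1)
  if (persistence_length <= 0) stop("persistence_length must be > 0")
  if (kBT <= 0) stop("kBT must be > 0")
  structure(list(persistence_length = persistence_length, kBT = kBT),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC parameters: lp = %g nm, kBT = %g pN nm\n",
              x$persistence_length, x$kBT))
  invisible(x)
}

# Guard band below full extension: beyond this the WLC force diverges and
# the ODE right-hand side would propagate NaN/Inf.
.LAMBDA_MAX <- 1 - 1e-9

.check_Lambda <- function(Lambda) {
  if (any(!is.finite(Lambda))) stop("extension ratio must be finite")
  if (any(Lambda < 0)) stop("extension ratio must be non-negative")
  if (any(Lambda >= .LAMBDA_MAX)) stop("extension exceeds contour length")
  invisible(Lambda)
}

#' Worm-like-chain tension
#'
#' Interpolation formula for the entropic tension of a worm-like chain at
#' relative extension \eqn{\Lambda} (end-to-end length over contour length):
#' \deqn{T(\Lambda) = \frac{1}{\beta \ell_p}\left[\frac{1}{4(1-\Lambda)^2}
#'   + \Lambda - \frac{1}{4}\right].}
#' The tension vanishes at \eqn{\Lambda = 0} and diverges as
#' \eqn{\Lambda \to 1}.
#'
#' @param Lambda Relative extension, \eqn{0 \le \Lambda < 1}. Vectorised.
#' @param params A [wlc_params()] object.
#' @return Tension in pN.
#' @export
#' @examples
#' wlc_tension(0.5, wlc_params(20, 4)) # 0.25 pN
wlc_tension <- function(Lambda, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"))
  .check_Lambda(Lambda)
  pref <- params$kBT / params$persistence_length
  pref * (1 / (4 * (1 - Lambda)^2) + Lambda - 0.25)
}

#' Worm-like-chain differential stiffness
#'
#' Analytic derivative \eqn{K(\Lambda) = dT/d\Lambda} of [wlc_tension()]:
#' \deqn{K(\Lambda) = \frac{1}{\beta \ell_p}\left[\frac{1}{2(1-\Lambda)^3}
#'   + 1\right].}
#'
#' @inheritParams wlc_tension
#' @return Stiffness in pN (per unit \eqn{\Lambda}).
#' @export
wlc_stiffness <- function(Lambda, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"))
  .check_Lambda(Lambda)
  pref <- params$kBT / params$persistence_length
  pref * (1 / (2 * (1 - Lambda)^3) + 1)
}

#' Tension of a crosslinking element at a given axon deformation
#'
#' Under the affine assumption the end-to-end extension of an element is
#' \eqn{\lambda \ell_0'} where \eqn{\lambda = 1 + \gamma} is the axon
#' deformation and \eqn{\ell_0'} the initial (zero-strain) end-to-end
#' length. The element tension is the WLC tension at
#' \eqn{\Lambda = \lambda \ell_0' / \ell} where \eqn{\ell} is the current
#' rest (contour) length. Because \eqn{\ell_0'} is generally comparable to
#' the folded contour length, the element is under tension already at
#' \eqn{\lambda = 1} (pre-tension).
#'
#' @param lambda Axon deformation \eqn{\lambda = 1 + \gamma} (dimensionless,
#'   \eqn{\ge 0}).
#' @param ell Current rest/contour length in nm (> 0).
#' @param ell0p Initial end-to-end length \eqn{\ell_0'} in nm (\eqn{\ge 0}).
#' @param params A [wlc_params()] object.
#' @return Tension in pN.
#' @export
#' @examples
#' element_tension(1, 200, 170) # ~2.342 pN of pre-tension
element_tension <- function(lambda, ell, ell0p, params = wlc_params()) {
  if (any(lambda < 0)) stop("deformation lambda must be non-negative")
  if (any(ell <= 0)) stop("rest length must be > 0")
  if (any(ell0p < 0)) stop("initial end-to-end length must be non-negative")
  Lambda <- lambda * ell0p / ell
  if (any(Lambda >= .LAMBDA_MAX)) stop("overstretched element")
  wlc_tension(Lambda, params)
}
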