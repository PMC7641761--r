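#' Worm-like-chain parameters for double-stranded DNA
#'
#' Container for the three polymer constants used by the worm-like-chain
#' (WLC) force-extension model: the persistence length \eqn{P}, the helical
#' rise per base pair, and the thermal energy \eqn{k_B T}.
#'
#' Defaults are the conventional room-temperature values for B-form dsDNA:
#' \eqn{P = 50} nm, 0.34 nm/bp, \eqn{k_B T = 4.11} pN nm.
#'
#' @param persistence_length Persistence length in nm. Must be > 0.
#' @param rise_per_bp Contour length per base pair in nm/bp. Must be > 0.
#' @param thermal_energy Thermal energy in pN nm. Must be > 0.
#'
#' @return An object of class `wlc_params`.
#' @examples
#' wlc_params()
#' wlc_params(persistence_length = 45)
#' @export
wlc_params <- function(persistence_length = 50,
                       rise_per_bp = 0.34,
                       thermal_energy = 4.11) {
  stopifnot(
    "persistence_length must be a single positive number" =
      is.numeric(persistence_length) && length(persistence_length) == 1L &&
      is.finite(persistence_length) && persistence_length > 0,
    "rise_per_bp must be a single positive number" =
      is.numeric(rise_per_bp) && length(rise_per_bp) == 1L &&
      is.finite(rise_per_bp) && rise_per_bp > 0,
    "thermal_energy must be a single positive number" =
      is.numeric(thermal_energy) && length(thermal_energy) == 1L &&
      is.finite(thermal_energy) && thermal_energy > 0
  )
  structure(
    list(persistence_length = persistence_length,
         rise_per_bp = rise_per_bp,
         thermal_energy = thermal_energy),
    class = "wlc_params"
  )
}

#' Geometry of the molecular forceps DNA construct
#'
#' The forceps construct mimics a double-strand break: two linear dsDNA arms
#' face each other tip-to-tip and are held by a dsDNA bridge covalently
#' anchored a short distance from each tip.  Each arm carries a handle
#' (tether) for attachment to the bead or surface.  When the two tips
#' synapse, the tension path shortcuts through the tips and the bridge loops
#' out of the tether, so the bridge bypass length
#' `bridge_length - 2 * anchor_offset` disappears from the measured
#' end-to-end extension.
#'
#' @param arm_length Length of each arm in bp (default 1500).
#' @param bridge_length Length of the bridge in bp (6000 or 610 in the
#'   standard constructs).
#' @param anchor_offset Distance of each bridge anchor from its tip in bp
#'   (default 57).
#' @param tether_length Length of each bead/surface handle in bp
#'   (default 1000).
#'
#' @return An object of class `forceps_construct`.
#' @examples
#' forceps_construct(bridge_length = 6000)
#' forceps_construct(bridge_length = 610)
#' @export
forceps_construct <- function(arm_length = 1500,
                              bridge_length = 6000,
                              anchor_offset = 57,
                              tether_length = 1000) {
  fields <- c(arm_length = arm_length, bridge_length = bridge_length,
              anchor_offset = anchor_offset, tether_length = tether_length)
  if (!all(vapply(fields, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0 && v == round(v),
    logical(1L))))
    stop("all forceps_construct fields must be positive integers",
         call. = FALSE)
  if (bridge_length < 2 * anchor_offset)
    stop("bridge_length must be at least 2 * anchor_offset", call. = FALSE)
  structure(
    list(arm_length = as.integer(arm_length),
         bridge_length = as.integer(bridge_length),
         anchor_offset = as.integer(anchor_offset),
         tether_length = as.integer(tether_length)),
    class = "forceps_construct"
  )
}

#' @export
print.forceps_construct <- function(x, ...) {
  cat("Molecular forceps construct:\n")
  cat(sprintf("  arms:    2 x %d bp (blunt tips face-to-face)\n", x$arm_length))
  cat(sprintf("  bridge:  %d bp, anchored %d bp from each tip (bypass %d bp)\n",
              x$bridge_length, x$anchor_offset, bridge_bypass_bp(x)))
  cat(sprintf("  tethers: 2 x %d bp\n", x$tether_length))
  invisible(x)
}

#' Bridge bypass length of a forceps construct
#'
#' Base pairs removed from the tension path when the two tips synapse:
#' `bridge_length - 2 * anchor_offset`.
#'
#' @param construct A [forceps_construct()].
#' @return Bypass length in bp.
#' @export
bridge_bypass_bp <- function(construct) {
  stopifnot(inherits(construct, "forceps_construct"))
  construct$bridge_length - 2L * construct$anchor_offset
}

#' Contour length (bp) of the open-construct tension path
#'
#' In the open (unsynapsed) state tension runs through both tethers, both
#' arms and the whole bridge.
#'
#' @param construct A [forceps_construct()].
#' @return Path length in bp.
#' @export
open_path_bp <- function(construct) {
  stopifnot(inherits(construct, "forceps_construct"))
  2L * construct$tether_length + 2L * construct$arm_length +
    construct$bridge_length
}

# Marko-Siggia interpolation residual: g(x) = x + 1/(4(1-x)^2) - 1/4 - FP/kT
ms_residual <- function(x, force, params) {
  x + 1 / (4 * (1 - x)^2) - 0.25 -
    force * params$persistence_length / params$thermal_energy
}

#' Relative WLC extension at a given force
#'
#' Solves the Marko-Siggia interpolation formula
#' \deqn{\frac{F P}{k_B T} = x + \frac{1}{4(1-x)^2} - \frac{1}{4}}
#' for the fractional extension \eqn{x = \ell/L_0 \in [0, 1)} by bracketed
#' bisection.  The left side is strictly increasing on \eqn{[0, 1)}, so the
#' root is unique; bisection is run to an interval width of 1e-9.
#'
#' @param force Stretching force in pN (scalar or vector, each >= 0).
#' @param params A [wlc_params()] object.
#'
#' @return Fractional extension(s) in `[0, 1)`; 0 at zero force.
#' @examples
#' wlc_relative_extension(1.4)      # ~0.8766 for standard dsDNA
#' wlc_relative_extension(0)        # exactly 0
#' @export
wlc_relative_extension <- function(force, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"),
            is.numeric(force), all(is.finite(force)))
  if (any(force < 0))
    stop("force must be non-negative", call. = FALSE)
  vapply(force, function(f) {
    if (f == 0) return(0)
    lo <- 0
    hi <- 1 - 1e-12
    # residual is negative at lo (for f > 0) and positive at hi
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (ms_residual(mid, f, params) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1L))
}

#' Expected extension change upon end synapsis
#'
#' Predicts the rip amplitude \eqn{\Delta l} observed when a synapsed
#' forceps construct ruptures at force \eqn{F}: the WLC fractional extension
#' at that force times the contour length of the bridge bypass,
#' \deqn{\Delta l = x(F) \cdot r \cdot (L_{bridge} - 2 \, d_{anchor})}
#' with \eqn{r} the rise per bp.  Tip/nick elasticity and handle compliance
#' are ignored; the amplitude reflects only the bridge segment that loops
#' out of the tension path.
#'
#' @param construct A [forceps_construct()].
#' @param force Pulling force in pN.
#' @param params A [wlc_params()] object.
#'
#' @return Expected amplitude in nm.
#' @examples
#' # ~1754 nm for the 6 kbp bridge at 1.4 pN
#' expected_amplitude(forceps_construct(bridge_length = 6000), 1.4)
#' # ~148 nm for the 610 bp bridge
#' expected_amplitude(forceps_construct(bridge_length = 610), 1.4)
#' @export
expected_amplitude <- function(construct, force, params = wlc_params()) {
  stopifnot(inherits(construct, "forceps_construct"))
  wlc_relative_extension(force, params) * params$rise_per_bp *
    bridge_bypass_bp(construct)
}

#' Open-construct extension at a given force
#'
#' Extension of the full (unsynapsed) tension path, used as the high-force
#' baseline of simulated traces.
#'
#' @inheritParams expected_amplitude
#' @return Extension in nm.
#' @export
open_extension <- function(construct, force, params = wlc_params()) {
  stopifnot(inherits(construct, "forceps_construct"))
  wlc_relative_extension(force, params) * params$rise_per_bp *
    open_path_bp(construct)
}
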