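#' Two-level force-modulation protocol
#'
#' One pulling cycle holds the construct at a low force (letting the two DNA
#' ends meet) and then at a high force (testing whether synapsis was
#' established).  Defaults follow the standard protocol: ~120 s at 0.01 pN
#' and ~120 s at 1.4 pN.
#'
#' @param low_force Low force in pN (default 0.01).
#' @param high_force High force in pN (default 1.4).
#' @param low_duration Low-force phase duration in s (default 120).
#' @param high_duration High-force phase duration in s (default 120).
#' @param n_cycles Number of pulling cycles (>= 1).
#' @param sampling_rate Bead-tracking rate in Hz (default 30).
#'
#' @return An object of class `force_protocol`.
#' @export
force_protocol <- function(low_force = 0.01, high_force = 1.4,
                           low_duration = 120, high_duration = 120,
                           n_cycles = 10, sampling_rate = 30) {
  stopifnot(
    "need high_force > low_force >= 0" =
      is.numeric(low_force) && is.numeric(high_force) &&
      low_force >= 0 && high_force > low_force,
    "durations must be positive" =
      low_duration > 0 && high_duration > 0,
    "n_cycles must be >= 1" =
      is.numeric(n_cycles) && n_cycles >= 1 && n_cycles == round(n_cycles),
    "sampling_rate must be positive" = sampling_rate > 0
  )
  structure(
    list(low_force = low_force, high_force = high_force,
         low_duration = low_duration, high_duration = high_duration,
         n_cycles = as.integer(n_cycles), sampling_rate = sampling_rate),
    class = "force_protocol"
  )
}

#' Kinetic preset for one experimental condition
#'
#' Generative parameters of the per-cycle event model: with probability
#' `p_specific` a low-force dwell ends in specific tip-to-tip synapsis
#' (rupture amplitude centred on the WLC expectation, exponential lifetime
#' `tau_specific`); with probability `p_nonspecific` it ends in a
#' surface-proximal nonspecific interaction (its own amplitude peak and
#' lifetime law).  Otherwise the cycle is empty.
#'
#' @param name Condition label.
#' @param p_specific Probability a cycle yields a specific synaptic event.
#' @param tau_specific Mean specific lifetime at high force, s.
#' @param p_nonspecific Probability of a nonspecific event.
#' @param amp_nonspecific_mean,amp_nonspecific_sd Nonspecific amplitude peak
#'   (nm).
#' @param amp_specific_sd Molecule-to-molecule spread of the specific
#'   amplitude around the WLC expectation (nm).
#' @param tau_nonspecific Mean nonspecific lifetime, s (default 2; only the
#'   amplitudes of this class are analyzed downstream).
#'
#' @return An object of class `kinetic_preset`.
#' @export
kinetic_preset <- function(name, p_specific, tau_specific,
                           p_nonspecific = 0,
                           amp_nonspecific_mean = 387,
                           amp_nonspecific_sd = 54,
                           amp_specific_sd = 101,
                           tau_nonspecific = 2) {
  stopifnot(
    "probabilities must lie in [0, 1]" =
      p_specific >= 0 && p_specific <= 1 &&
      p_nonspecific >= 0 && p_nonspecific <= 1,
    "p_specific + p_nonspecific must be <= 1" =
      p_specific + p_nonspecific <= 1,
    "tau_specific must be > 0" = tau_specific > 0,
    "tau_nonspecific must be > 0" = tau_nonspecific > 0,
    "amplitude sds must be >= 0" =
      amp_nonspecific_sd >= 0 && amp_specific_sd >= 0
  )
  structure(
    list(name = as.character(name), p_specific = p_specific,
         tau_specific = tau_specific, p_nonspecific = p_nonspecific,
         amp_nonspecific_mean = amp_nonspecific_mean,
         amp_nonspecific_sd = amp_nonspecific_sd,
         amp_specific_sd = amp_specific_sd,
         tau_nonspecific = tau_nonspecific),
    class = "kinetic_preset"
  )
}

#' Bead-tracking noise model
#'
#' Additive Gaussian noise per sample, with a larger spread at low force
#' (where the bead fluctuates more), plus an optional linear drift.
#'
#' @param extension_noise_sd_high Noise SD at high force, nm (default 15).
#' @param extension_noise_sd_low Noise SD at low force, nm (default 60).
#' @param drift_rate Linear drift in nm/s (default 0).
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(extension_noise_sd_high = 15,
                        extension_noise_sd_low = 60,
                        drift_rate = 0) {
  stopifnot("noise sds must be >= 0" =
              extension_noise_sd_high >= 0 && extension_noise_sd_low >= 0)
  structure(
    list(extension_noise_sd_high = extension_noise_sd_high,
         extension_noise_sd_low = extension_noise_sd_low,
         drift_rate = drift_rate),
    class = "noise_model"
  )
}

#' Condition presets for the seven standard assay conditions
#'
#' Generative parameters for the synthetic trace generator, one per
#' experimental condition (NHEJ component mix and bridge length).  Event
#' probabilities are the observed per-cycle rates (synaptic and nonspecific
#' events divided by pulling cycles), lifetimes are the fitted mean
#' lifetimes, and amplitude spreads are the fitted peak standard deviations
#' for each condition.  These are generative inputs for recovery tests, not
#' measurements.
#'
#' Each preset bundles a [kinetic_preset()], a [forceps_construct()] with
#' the condition's bridge length, and the condition's number of pulling
#' cycles.
#'
#' @param name Optional single preset name; if missing, all presets are
#'   returned as a named list.
#'
#' @return A list with elements `kinetics`, `construct`, `n_cycles`,
#'   `high_force`, `bridge_kbp` (or a named list of such lists).
#' @examples
#' names(condition_presets())
#' condition_presets("DPK+LINP1_6kbp")$kinetics$tau_specific
#' @export
condition_presets <- function(name = NULL) {
  make <- function(bridge_bp, n_cycles, n_specific, n_nonspecific,
                   tau, amp_sp_sd, amp_ns_mean = 387, amp_ns_sd = 54,
                   label) {
    list(
      kinetics = kinetic_preset(
        name = label,
        p_specific = n_specific / n_cycles,
        tau_specific = tau,
        p_nonspecific = n_nonspecific / n_cycles,
        amp_nonspecific_mean = amp_ns_mean,
        amp_nonspecific_sd = amp_ns_sd,
        amp_specific_sd = amp_sp_sd
      ),
      construct = forceps_construct(bridge_length = bridge_bp),
      n_cycles = as.integer(n_cycles),
      high_force = 1.4,
      bridge_kbp = bridge_bp / 1000
    )
  }
  presets <- list(
    # 6 kbp bridge: DNA-PK + full-length LINP1
    "DPK+LINP1_6kbp" = make(6000, 6964, 95, 431, 4.1, 101, 387, 54,
                            "DPK+LINP1_6kbp"),
    # 6 kbp bridge: DNA-PK + PAXX (specific events rare)
    "DPK+PAXX_6kbp" = make(6000, 7037, 10, 415, 4.9, 57, 433, 56,
                           "DPK+PAXX_6kbp"),
    # 610 bp bridge conditions
    "DPK+LINP1_0.6kbp" = make(610, 4823, 357, 202, 4.8, 20,
                              label = "DPK+LINP1_0.6kbp"),
    "DPK+PAXX_0.6kbp" = make(610, 3562, 725, 128, 2.3, 11,
                             label = "DPK+PAXX_0.6kbp"),
    "DPK+PAXX+XLF+LX4_0.6kbp" = make(610, 1587, 356, 0, 63, 10,
                                     label = "DPK+PAXX+XLF+LX4_0.6kbp"),
    "DPK+PAXX+XLF+LX4+SL2_0.6kbp" = make(610, 6657, 22, 30, 7.6, 19,
                                         label = "DPK+PAXX+XLF+LX4+SL2_0.6kbp"),
    "DPK+PAXX+XLF+LX4+BT_0.6kbp" = make(610, 571, 8, 4, 1.8, 12,
                                        label = "DPK+PAXX+XLF+LX4+BT_0.6kbp")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown condition preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Binding presets for the MST titrations
#'
#' Generative parameters of the standard ligand titrations: the apparent
#' dissociation constant and Hill coefficient for Ku binding to a 50 bp
#' dsDNA duplex (cooperative, two Ku per duplex) and to full-length LINP1
#' RNA (single-site).
#'
#' @param name Optional single preset name.
#' @return A list with `model`, `kd` (molar), `hill_h` (or a named list).
#' @examples
#' binding_presets("FL-LINP1")$kd
#' @export
binding_presets <- function(name = NULL) {
  presets <- list(
    "d50-DNA" = list(model = "hill", kd = 19e-9, hill_h = 1.75),
    "FL-LINP1" = list(model = "single_site", kd = 740e-9, hill_h = 1)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown binding preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Default 16-point MST titration series
#'
#' A 1:1 dilution series from 93 uM down to 2.8 nM (16 points), matching
#' the standard thermophoresis ligand titration.
#'
#' @param top Top concentration in molar (default 93e-6).
#' @param n Number of points (default 16).
#' @return Concentrations in molar, increasing order.
#' @export
default_titration <- function(top = 93e-6, n = 16) {
  stopifnot(top > 0, n >= 2)
  sort(top / 2^(seq_len(n) - 1))
}
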