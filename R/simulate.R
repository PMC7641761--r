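#' Simulate a magnetic-tweezer forceps trace with planted ground truth
#'
#' Generates a bead-extension time series under the two-level
#' force-modulation protocol.  At most one end-binding event is decided per
#' pulling cycle, at force-up: with probability `p_specific` a specific
#' tip-to-tip synapsis (amplitude drawn around the WLC expectation,
#' exponential lifetime `tau_specific`); with probability `p_nonspecific` a
#' surface-proximal nonspecific event with its own amplitude peak and
#' lifetime.  An event whose drawn lifetime exceeds the high-force phase is
#' planted as censored: the extension deficit persists to the end of the
#' cycle with no rupture step.
#'
#' The high-force baseline is the open-construct WLC extension; the
#' low-force level is the open-construct extension at the low force (events
#' are latent at low force and manifest only as a deficit at force-up).
#' Gaussian noise is added per sample with force-level-dependent SD, plus
#' optional linear drift.
#'
#' @param construct A [forceps_construct()].
#' @param protocol A [force_protocol()].
#' @param kinetics A [kinetic_preset()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical inputs and seed give an identical
#'   trace.
#' @param params A [wlc_params()] object.
#'
#' @return An object of class `tweezer_trace`: a list with
#'   \describe{
#'     \item{data}{data.frame with `time_s`, `extension_nm`, `force_pN`}
#'     \item{truth}{data.frame of planted events: `cycle`, `class`,
#'       `amplitude_nm`, `duration_s`, `censored`}
#'     \item{baseline_nm}{open-construct extension at high force}
#'     \item{protocol, construct, kinetics, noise, seed}{inputs}
#'   }
#' @examples
#' pre <- condition_presets("DPK+LINP1_0.6kbp")
#' tr <- simulate_trace(pre$construct,
#'                      force_protocol(n_cycles = 5, sampling_rate = 10),
#'                      pre$kinetics, noise_model(), seed = 1)
#' nrow(tr$truth)
#' @export
simulate_trace <- function(construct, protocol, kinetics,
                           noise = noise_model(), seed,
                           params = wlc_params()) {
  stopifnot(inherits(construct, "forceps_construct"),
            inherits(protocol, "force_protocol"),
            inherits(kinetics, "kinetic_preset"),
            inherits(noise, "noise_model"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required", call. = FALSE)
  if (kinetics$p_specific + kinetics$p_nonspecific > 1)
    stop("p_specific + p_nonspecific must be <= 1", call. = FALSE)
  set.seed(as.integer(seed))

  rate <- protocol$sampling_rate
  n_low <- round(protocol$low_duration * rate)
  n_high <- round(protocol$high_duration * rate)
  n_cyc <- protocol$n_cycles
  cyc_len <- n_low + n_high
  n <- n_cyc * cyc_len

  baseline <- open_extension(construct, protocol$high_force, params)
  low_level <- open_extension(construct, protocol$low_force, params)
  delta_exp <- expected_amplitude(construct, protocol$high_force, params)

  force <- rep(c(rep(protocol$low_force, n_low),
                 rep(protocol$high_force, n_high)), n_cyc)
  ext <- rep(c(rep(low_level, n_low), rep(baseline, n_high)), n_cyc)
  time <- (seq_len(n) - 1L) / rate

  # per-cycle event draws (vectorized; fixed draw order for determinism)
  u <- stats::runif(n_cyc)
  cls <- ifelse(u < kinetics$p_specific, "specific",
                ifelse(u < kinetics$p_specific + kinetics$p_nonspecific,
                       "nonspecific", "none"))
  i_sp <- which(cls == "specific")
  i_ns <- which(cls == "nonspecific")
  amp <- dur <- rep(NA_real_, n_cyc)
  amp[i_sp] <- stats::rnorm(length(i_sp), delta_exp, kinetics$amp_specific_sd)
  dur[i_sp] <- stats::rexp(length(i_sp), 1 / kinetics$tau_specific)
  amp[i_ns] <- stats::rnorm(length(i_ns), kinetics$amp_nonspecific_mean,
                            kinetics$amp_nonspecific_sd)
  dur[i_ns] <- stats::rexp(length(i_ns), 1 / kinetics$tau_nonspecific)

  i_ev <- sort(c(i_sp, i_ns))
  censored <- logical(n_cyc)
  for (i in i_ev) {
    n_bound <- min(n_high, ceiling(dur[i] * rate))
    censored[i] <- dur[i] > protocol$high_duration
    if (n_bound > 0) {
      start <- (i - 1L) * cyc_len + n_low + 1L
      idx <- start:(start + n_bound - 1L)
      ext[idx] <- ext[idx] - amp[i]
    }
  }

  sd_vec <- rep(c(rep(noise$extension_noise_sd_low, n_low),
                  rep(noise$extension_noise_sd_high, n_high)), n_cyc)
  ext <- ext + stats::rnorm(n) * sd_vec + noise$drift_rate * time

  truth <- data.frame(
    cycle = i_ev,
    class = cls[i_ev],
    amplitude_nm = amp[i_ev],
    duration_s = dur[i_ev],
    censored = censored[i_ev],
    stringsAsFactors = FALSE
  )

  structure(
    list(data = data.frame(time_s = time, extension_nm = ext,
                           force_pN = force),
         truth = truth,
         baseline_nm = baseline,
         protocol = protocol, construct = construct,
         kinetics = kinetics, noise = noise,
         seed = as.integer(seed)),
    class = "tweezer_trace"
  )
}

#' @export
print.tweezer_trace <- function(x, ...) {
  cat(sprintf(
    "Tweezer trace: %d samples, %d cycles (%.3g/%.3g pN), %d planted events\n",
    nrow(x$data), x$protocol$n_cycles, x$protocol$low_force,
    x$protocol$high_force, nrow(x$truth)))
  invisible(x)
}

#' Simulate a rupture-amplitude sample from the two-peak mixture
#'
#' Draws the two-Gaussian amplitude mixture used to test the deconvolution:
#' specific amplitudes around the WLC expectation for the given construct
#' and force, nonspecific amplitudes around the surface-proximal peak.
#'
#' @param n_specific,n_nonspecific Number of draws from each component.
#' @param kinetics A [kinetic_preset()] providing the peak SDs and the
#'   nonspecific mean.
#' @param construct A [forceps_construct()].
#' @param force Pulling force in pN (default 1.4).
#' @param seed Integer seed.
#' @param params A [wlc_params()].
#'
#' @return Numeric vector of amplitudes (nm) with attribute `component`
#'   ("specific"/"nonspecific") giving the generative labels.
#' @export
simulate_amplitude_sample <- function(n_specific, n_nonspecific, kinetics,
                                      construct, force = 1.4, seed,
                                      params = wlc_params()) {
  stopifnot(inherits(kinetics, "kinetic_preset"),
            inherits(construct, "forceps_construct"),
            n_specific >= 0, n_nonspecific >= 0)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  mu_sp <- expected_amplitude(construct, force, params)
  amps <- c(stats::rnorm(n_specific, mu_sp, kinetics$amp_specific_sd),
            stats::rnorm(n_nonspecific, kinetics$amp_nonspecific_mean,
                         kinetics$amp_nonspecific_sd))
  attr(amps, "component") <- rep(c("specific", "nonspecific"),
                                 c(n_specific, n_nonspecific))
  amps
}

#' Simulate an MST-style binding titration
#'
#' Evaluates the fractional saturation \eqn{\theta} on a titration series
#' and adds Gaussian noise:
#' \deqn{\theta = \frac{L}{K_d + L}} (single-site) or
#' \deqn{\theta = \frac{L^h}{K_d^h + L^h}} (Hill).
#'
#' @param model `"single_site"` or `"hill"`.
#' @param kd Dissociation constant in molar (> 0).
#' @param hill_h Hill coefficient (> 0; ignored for single-site).
#' @param titration Ligand concentrations in molar (default: 16-point 1:1
#'   dilution series from 93 uM, [default_titration()]).
#' @param noise_frac SD of the additive Gaussian noise, in signal units.
#' @param seed Integer seed.
#'
#' @return A data.frame of class `binding_curve` with columns
#'   `concentration_M`, `signal` and attributes `model`, `kd`, `hill_h`.
#' @examples
#' bc <- simulate_binding_curve("single_site", kd = 740e-9,
#'                              noise_frac = 0, seed = 1)
#' bc$signal[which.min(abs(bc$concentration_M - 740e-9))]
#' @export
simulate_binding_curve <- function(model = c("single_site", "hill"),
                                   kd, hill_h = 1,
                                   titration = default_titration(),
                                   noise_frac = 0.02, seed) {
  model <- match.arg(model)
  if (!is.numeric(kd) || length(kd) != 1L || kd <= 0)
    stop("kd must be a single positive concentration", call. = FALSE)
  stopifnot("hill_h must be > 0" = hill_h > 0,
            "titration must be nonempty and positive" =
              length(titration) > 0 && all(titration > 0),
            "noise_frac must be >= 0" = noise_frac >= 0)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  h <- if (model == "single_site") 1 else hill_h
  theta <- titration^h / (kd^h + titration^h)
  signal <- theta + stats::rnorm(length(titration), 0, noise_frac)
  out <- data.frame(concentration_M = titration, signal = signal)
  class(out) <- c("binding_curve", "data.frame")
  attr(out, "model") <- model
  attr(out, "kd") <- kd
  attr(out, "hill_h") <- h
  out
}
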