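#' Segment a trace into pulling cycles
#'
#' Splits the force channel into high-force phases (one pulling cycle per
#' high phase) and estimates the open-construct baseline extension as the
#' median of the top quartile of all high-force extension samples — a
#' robust estimate of the open state even when a fifth of cycles carry
#' events.
#'
#' @param trace A [simulate_trace()] result, or any list with a `data`
#'   data.frame holding `time_s`, `extension_nm`, `force_pN`.
#' @param baseline `"global"` (default, one baseline for the whole
#'   molecule) or `"per_cycle"` (top-quartile median within each cycle;
#'   useful when drift is present).
#'
#' @return A data.frame of class `pulling_cycles` with columns `index`,
#'   `high_start`, `high_end` (sample indices of the high-force phase) and
#'   `baseline_extension` (nm).  Empty if the force channel never changes
#'   level.
#' @export
segment_cycles <- function(trace, baseline = c("global", "per_cycle")) {
  baseline <- match.arg(baseline)
  d <- trace$data
  stopifnot(is.data.frame(d),
            all(c("time_s", "extension_nm", "force_pN") %in% names(d)))
  lv <- sort(unique(d$force_pN))
  if (length(lv) < 2L) {
    out <- data.frame(index = integer(0), high_start = integer(0),
                      high_end = integer(0), baseline_extension = numeric(0))
    class(out) <- c("pulling_cycles", "data.frame")
    return(out)
  }
  if (length(lv) > 2L)
    stop("force channel must take exactly two levels", call. = FALSE)
  is_high <- d$force_pN == lv[2L]
  r <- rle(is_high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  out <- data.frame(index = seq_along(hi),
                    high_start = starts[hi],
                    high_end = ends[hi])
  top_quartile_median <- function(x) stats::median(x[x >= stats::quantile(x, 0.75)])
  if (baseline == "global") {
    out$baseline_extension <- top_quartile_median(d$extension_nm[is_high])
  } else {
    out$baseline_extension <- vapply(seq_len(nrow(out)), function(i)
      top_quartile_median(d$extension_nm[out$high_start[i]:out$high_end[i]]),
      numeric(1L))
  }
  class(out) <- c("pulling_cycles", "data.frame")
  out
}

# odd moving-median window of about `seconds` at `rate` Hz, clamped to n
smooth_window_k <- function(seconds, rate, n) {
  k <- round(seconds * rate)
  if (k %% 2 == 0) k <- k + 1
  k <- max(1L, min(k, if (n %% 2 == 1) n else n - 1L))
  as.integer(k)
}

#' Detect end-binding events in the high-force phases
#'
#' A pulling cycle contains an end-binding event when, at force-up, the
#' (median-smoothed) extension starts below `baseline - k_detect * noise_sd`
#' — i.e. the bead fails to recover the open-construct extension because the
#' DNA ends are synapsed.  The event ruptures at the first durable recovery:
#' the first sample at which the smoothed extension re-enters the baseline
#' band and stays there for at least `dwell_min` samples.  The rupture time
#' is placed midway between the last bound and first recovered sample, so
#' the reported duration is unbiased with respect to sampling.  If no
#' recovery occurs before the end of the phase the event is censored: its
#' amplitude is still measured from the plateau but its duration is
#' undefined.
#'
#' @param trace A trace as accepted by [segment_cycles()].
#' @param cycles A `pulling_cycles` data.frame from [segment_cycles()].
#' @param k_detect Detection threshold in units of `noise_sd` below
#'   baseline (default 5).
#' @param noise_sd Per-sample extension noise SD at high force, nm.  If
#'   `NULL`, taken from the trace's noise model when present, otherwise
#'   estimated as the MAD of the high-force samples above baseline minus
#'   their median.
#' @param dwell_min Hysteresis: number of consecutive above-threshold
#'   samples required to call a recovery durable (default 3).
#' @param smooth_window_s Width of the centered moving-median smoother in
#'   seconds (default 0.5); smoothing is applied within each high phase so
#'   the force step itself never leaks into the estimate.
#'
#' @return A data.frame of class `end_binding_events` with columns
#'   `cycle_index`, `delta_l_nm`, `t_synapsis_s` (NA when censored),
#'   `censored`, `specificity` (NA until [classify_events()]).
#' @export
detect_events <- function(trace, cycles, k_detect = 5, noise_sd = NULL,
                          dwell_min = 3, smooth_window_s = 0.5) {
  stopifnot(inherits(cycles, "pulling_cycles"))
  if (nrow(cycles) == 0L)
    stop("cycles must be nonempty", call. = FALSE)
  d <- trace$data
  if (is.null(noise_sd)) {
    noise_sd <- if (!is.null(trace$noise)) {
      trace$noise$extension_noise_sd_high
    } else {
      hi <- unlist(mapply(function(s, e) d$extension_nm[s:e],
                          cycles$high_start, cycles$high_end,
                          SIMPLIFY = FALSE))
      stats::mad(hi[hi >= stats::median(hi)])
    }
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)

  rate <- 1 / stats::median(diff(d$time_s[seq_len(min(1000L, nrow(d)))]))
  res <- vector("list", nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    s <- cycles$high_start[i]
    e <- cycles$high_end[i]
    base <- cycles$baseline_extension[i]
    thr <- base - k_detect * noise_sd
    seg <- d$extension_nm[s:e]
    k <- smooth_window_k(smooth_window_s, rate, length(seg))
    # endrule "keep" leaves the first/last samples raw: a synaptic event
    # lasting less than one smoothing window still registers at force-up,
    # so short dwell times are not truncated away
    sm <- if (k > 1L) stats::runmed(seg, k, endrule = "keep") else seg
    if (sm[1L] >= thr) next  # open from the start: no event this cycle

    above <- sm >= thr
    ra <- rle(above)
    rend <- cumsum(ra$lengths)
    rstart <- rend - ra$lengths + 1L
    durable <- which(ra$values & ra$lengths >= dwell_min)
    if (length(durable) == 0L) {
      # no durable recovery before phase end: censored event
      res[[i]] <- data.frame(
        cycle_index = cycles$index[i],
        delta_l_nm = base - mean(sm[!above]),
        t_synapsis_s = NA_real_,
        censored = TRUE
      )
    } else {
      r <- rstart[durable[1L]]  # first sample of the durable recovery
      plateau <- seq_len(r - 1L)
      res[[i]] <- data.frame(
        cycle_index = cycles$index[i],
        delta_l_nm = base - mean(sm[plateau]),
        # midpoint between last bound and first recovered sample
        t_synapsis_s = (d$time_s[s + r - 1L] + d$time_s[s + r - 2L]) / 2 -
          d$time_s[s],
        censored = FALSE
      )
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(cycle_index = integer(0), delta_l_nm = numeric(0),
                      t_synapsis_s = numeric(0), censored = logical(0))
  out$specificity <- rep(NA_character_, nrow(out))
  class(out) <- c("end_binding_events", "data.frame")
  out
}

#' Classify events as specific synapsis by the 3-sigma amplitude rule
#'
#' An event is specific tip-to-tip synapsis when its rupture amplitude lies
#' within three standard deviations of the expected extension change at the
#' pulling force; otherwise it is a nonspecific (surface-proximal) event.
#' Only specific, uncensored events feed lifetime estimation.
#'
#' @param events An `end_binding_events` data.frame from [detect_events()].
#' @param expected Expected amplitude in nm (from [expected_amplitude()]).
#' @param sigma Standard deviation of the specific amplitude peak, nm.
#'
#' @return The events with `specificity` filled in
#'   (`"specific"`/`"nonspecific"`).  Idempotent.
#' @examples
#' ev <- data.frame(cycle_index = 1:2, delta_l_nm = c(1737, 387),
#'                  t_synapsis_s = c(5, 1), censored = FALSE,
#'                  specificity = NA_character_)
#' class(ev) <- c("end_binding_events", "data.frame")
#' classify_events(ev, expected = 1754, sigma = 101)$specificity
#' @export
classify_events <- function(events, expected, sigma) {
  stopifnot(inherits(events, "end_binding_events"),
            "expected must be > 0" = is.numeric(expected) && expected > 0,
            "sigma must be > 0" = is.numeric(sigma) && sigma > 0)
  events$specificity <- ifelse(
    abs(events$delta_l_nm - expected) <= 3 * sigma, "specific", "nonspecific")
  events
}
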