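#' Two-component Gaussian deconvolution of rupture amplitudes
#'
#' Maximum-likelihood fit of a two-component Gaussian mixture to raw
#' rupture amplitudes by expectation-maximization, separating the specific
#' (tip-to-tip, WLC-scale) peak from the nonspecific (surface-proximal)
#' peak.  Fitting on raw values avoids any dependence on histogram bin
#' width; a least-squares histogram mode is available for visual parity
#' with binned data.
#'
#' Initialization is deterministic: the sample is split at the median and
#' at nine further quantiles (10 restarts), each seeding component means,
#' SDs and weights from the two sides of the split; the restart with the
#' best log-likelihood wins, ties broken by the lower sum of component SDs.
#' Component event counts are the rounded sums of posterior
#' responsibilities.
#'
#' @param amplitudes Rupture amplitudes in nm (>= 20 values).
#' @param init Optional length-2 numeric vector of initial means,
#'   replacing the quantile-split restarts.
#' @param method `"em"` (default) or `"histogram"` (least squares on a
#'   binned histogram, Sturges bins).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#'
#' @return An object of class `amplitude_fit`: list with `peak1_mean`,
#'   `peak1_sd`, `peak1_n` (larger-mean peak), `peak2_mean`, `peak2_sd`,
#'   `peak2_n`, `n_total`, `converged`, `loglik`.  Peaks are reported in
#'   descending mean order, so when a WLC expectation applies the specific
#'   peak is `peak1`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(95, 1737, 101), rnorm(395, 387, 54))
#' fit_double_gaussian(x)
#' @export
fit_double_gaussian <- function(amplitudes, init = NULL,
                                method = c("em", "histogram"),
                                max_iter = 500, tol = 1e-8) {
  method <- match.arg(method)
  x <- as.numeric(amplitudes)
  n <- length(x)
  if (n < 20L)
    stop("insufficient data: need at least 20 amplitudes", call. = FALSE)
  if (diff(range(x)) == 0) {
    # fully degenerate sample: both components collapse on the value
    return(new_amplitude_fit(x[1L], 0, n, x[1L], 0, 0, n, TRUE, NA_real_))
  }
  if (method == "histogram") return(fit_double_gaussian_hist(x))

  starts <- if (!is.null(init)) {
    stopifnot(length(init) == 2L)
    list(split_init(x, means = sort(init)))
  } else {
    qs <- c(0.5, 0.3, 0.7, 0.2, 0.8, 0.4, 0.6, 0.1, 0.9, 0.25)
    lapply(stats::quantile(x, qs, names = FALSE),
           function(q) split_init(x, cut = q))
  }
  best <- NULL
  for (st in starts) {
    if (is.null(st)) next
    fit <- em_two_gaussian(x, st, max_iter, tol)
    if (is.null(best) ||
        fit$loglik > best$loglik + 1e-9 ||
        (abs(fit$loglik - best$loglik) <= 1e-9 &&
         sum(fit$sd) < sum(best$sd)))
      best <- fit
  }
  ord <- order(best$mu, decreasing = TRUE)
  n1 <- round(sum(best$resp[, ord[1L]]))
  new_amplitude_fit(best$mu[ord[1L]], best$sd[ord[1L]], n1,
                    best$mu[ord[2L]], best$sd[ord[2L]], n - n1,
                    n, best$converged, best$loglik)
}

new_amplitude_fit <- function(m1, s1, n1, m2, s2, n2, n, conv, ll) {
  structure(
    list(peak1_mean = m1, peak1_sd = s1, peak1_n = as.integer(n1),
         peak2_mean = m2, peak2_sd = s2, peak2_n = as.integer(n2),
         n_total = as.integer(n), converged = conv, loglik = ll),
    class = "amplitude_fit"
  )
}

# initial parameters from a two-group split of x (at a cut value or
# around given means)
split_init <- function(x, cut = NULL, means = NULL) {
  g <- if (!is.null(cut)) x <= cut
       else abs(x - means[1L]) <= abs(x - means[2L])
  if (sum(g) < 2L || sum(!g) < 2L) return(NULL)
  sd_floor <- max(1e-8, 1e-4 * stats::sd(x))
  list(mu = c(mean(x[g]), mean(x[!g])),
       sd = pmax(c(stats::sd(x[g]), stats::sd(x[!g])), sd_floor),
       w = c(mean(g), 1 - mean(g)),
       sd_floor = sd_floor)
}

em_two_gaussian <- function(x, st, max_iter, tol) {
  mu <- st$mu; s <- st$sd; w <- st$w
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], s[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], s[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    resp <- cbind(d1 / tot, d2 / tot)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    mu <- colSums(resp * x) / nk
    s <- pmax(sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk),
              st$sd_floor)
    w <- nk / n
  }
  list(mu = mu, sd = s, w = w, loglik = ll_old, resp = resp,
       converged = converged)
}

# least-squares double Gaussian on a binned histogram (visual-parity mode)
fit_double_gaussian_hist <- function(x) {
  h <- graphics::hist(x, breaks = "Sturges", plot = FALSE)
  mids <- h$mids
  cnt <- h$counts
  em <- fit_double_gaussian(x, method = "em")  # starting values from EM
  bw <- diff(h$breaks[1:2])
  df <- data.frame(mids = mids, cnt = cnt)
  fit <- try(minpack.lm::nlsLM(
    cnt ~ a1 * exp(-(mids - m1)^2 / (2 * s1^2)) +
      a2 * exp(-(mids - m2)^2 / (2 * s2^2)),
    data = df,
    start = list(a1 = em$peak1_n * bw / (em$peak1_sd * sqrt(2 * pi) + 1e-9),
                 m1 = em$peak1_mean, s1 = max(em$peak1_sd, bw / 2),
                 a2 = em$peak2_n * bw / (em$peak2_sd * sqrt(2 * pi) + 1e-9),
                 m2 = em$peak2_mean, s2 = max(em$peak2_sd, bw / 2)),
    lower = c(0, min(x), 1e-6, 0, min(x), 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    em$converged <- FALSE
    return(em)
  }
  p <- stats::coef(fit)
  n1 <- p[["a1"]] * p[["s1"]] * sqrt(2 * pi) / bw
  n2 <- p[["a2"]] * p[["s2"]] * sqrt(2 * pi) / bw
  if (p[["m1"]] >= p[["m2"]])
    new_amplitude_fit(p[["m1"]], p[["s1"]], round(n1),
                      p[["m2"]], p[["s2"]], round(n2),
                      length(x), TRUE, NA_real_)
  else
    new_amplitude_fit(p[["m2"]], p[["s2"]], round(n2),
                      p[["m1"]], p[["s1"]], round(n1),
                      length(x), TRUE, NA_real_)
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat("Two-Gaussian amplitude fit (n =", x$n_total, "events)\n")
  cat(sprintf("  peak 1: %.0f nm (sd %.0f, n = %d)\n",
              x$peak1_mean, x$peak1_sd, x$peak1_n))
  cat(sprintf("  peak 2: %.0f nm (sd %.0f, n = %d)\n",
              x$peak2_mean, x$peak2_sd, x$peak2_n))
  if (!isTRUE(x$converged)) cat("  (not converged)\n")
  invisible(x)
}

#' Exponential lifetime estimate from synaptic dwell times
#'
#' The mean lifetime of the specific synaptic state under an exponential
#' dwell-time law.  The default estimator is the arithmetic mean of the
#' uncensored durations — the exponential maximum-likelihood estimate —
#' with `sem = mean / sqrt(n)` (the MLE standard error).  Events that did
#' not rupture within their pulling cycle (censored) are excluded entirely
#' by default, since their lifetime is unknown; an optional
#' censoring-aware mode adds the censored observation times to the
#' numerator only (total time at risk over observed ruptures), which is
#' the censored-exponential MLE.  The censoring-aware mode is not the
#' default and is never used by the condition summaries.
#'
#' @param durations Uncensored dwell times in s (>= 1 value).
#' @param censored_durations Observation times of censored events, s.
#' @param include_censored If `TRUE`, use the censoring-aware estimator.
#'
#' @return An object of class `lifetime_fit`: `mean_lifetime` (s), `sem`
#'   (s), `n` (uncensored events used), `n_censored`.
#' @examples
#' fit_exponential_lifetime(rexp(95, 1 / 4.1))
#' @export
fit_exponential_lifetime <- function(durations,
                                     censored_durations = numeric(0),
                                     include_censored = FALSE) {
  durations <- as.numeric(durations)
  durations <- durations[!is.na(durations)]
  if (length(durations) < 1L)
    stop("insufficient data: need at least one uncensored duration",
         call. = FALSE)
  n <- length(durations)
  m <- if (include_censored) {
    (sum(durations) + sum(censored_durations)) / n
  } else {
    mean(durations)
  }
  structure(
    list(mean_lifetime = m, sem = m / sqrt(n), n = n,
         n_censored = length(censored_durations),
         include_censored = include_censored),
    class = "lifetime_fit"
  )
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Synaptic lifetime: %.2f +/- %.2f s (SEM, n = %d%s)\n",
              x$mean_lifetime, x$sem, x$n,
              if (x$n_censored > 0)
                sprintf("; %d censored %s", x$n_censored,
                        if (x$include_censored) "included" else "excluded")
              else ""))
  invisible(x)
}

#' Fit a binding curve with the single-site or Hill model
#'
#' Nonlinear least squares of the fractional-saturation model
#' \deqn{signal = low + (high - low) \cdot \frac{L^h}{K_d^h + L^h}}
#' with \eqn{h = 1} fixed for the single-site model.  \eqn{K_d} is fitted
#' on a log scale (bounded above by ten times the top concentration) and
#' \eqn{h \in (0, 6]}; optimization uses bounded Levenberg-Marquardt.
#'
#' Because the titration signal here is normalized fraction bound, the
#' plateaus default to `baselines = "fixed"` (low = 0, high = 1), the
#' standard treatment for normalized thermophoresis data; with only a
#' couple of points below 20% saturation in a 16-point series, freeing
#' the lower plateau mostly trades baseline against Hill slope and
#' inflates the variance of \eqn{h}.  Use `baselines = "free"` for
#' un-normalized signals.
#'
#' @param curve A `binding_curve` data.frame (columns `concentration_M`,
#'   `signal`), e.g. from [simulate_binding_curve()] or [read_binding_curve()].
#' @param model `"single_site"` or `"hill"`.
#' @param baselines `"fixed"` (0/1, default) or `"free"` (fitted plateaus).
#'
#' @return An object of class `binding_fit`: `kd` (molar), `hill_h`,
#'   `baseline_low`, `baseline_high`, `converged`, `model`, `n`,
#'   `residual_sd`.
#' @examples
#' bc <- simulate_binding_curve("single_site", kd = 740e-9,
#'                              noise_frac = 0, seed = 1)
#' fit_binding(bc, "single_site")$kd * 1e9  # nM
#' @export
fit_binding <- function(curve, model = c("single_site", "hill"),
                        baselines = c("fixed", "free")) {
  model <- match.arg(model)
  baselines <- match.arg(baselines)
  stopifnot(is.data.frame(curve),
            all(c("concentration_M", "signal") %in% names(curve)))
  L <- curve$concentration_M
  y <- curve$signal
  if (length(L) < 6L)
    stop("insufficient data: need at least 6 titration points",
         call. = FALSE)
  if (any(L <= 0)) stop("concentrations must be positive", call. = FALSE)

  lo0 <- min(y); hi0 <- max(y)
  # start Kd at the concentration nearest half-signal
  lkd0 <- log10(L[which.min(abs(y - (lo0 + hi0) / 2))])
  lkd_bounds <- c(log10(min(L)) - 6, log10(10 * max(L)))
  free_h <- model == "hill"
  free_base <- baselines == "free"
  par0 <- c(list(lkd = lkd0),
            if (free_h) list(h = 1),
            if (free_base) list(lo = lo0, hi = hi0))
  lower <- c(lkd_bounds[1L], if (free_h) 1e-3,
             if (free_base) c(-Inf, -Inf))
  upper <- c(lkd_bounds[2L], if (free_h) 6,
             if (free_base) c(Inf, Inf))
  predict_y <- function(p) {
    h <- if (free_h) p$h else 1
    lo <- if (free_base) p$lo else 0
    hi <- if (free_base) p$hi else 1
    lo + (hi - lo) * L^h / ((10^p$lkd)^h + L^h)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) y - predict_y(p),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  converged <- fit$info %in% 1:3
  if (!converged)
    stop("binding fit failed to converge: ", fit$message, call. = FALSE)
  p <- fit$par
  rsd <- stats::sd(fit$fvec)
  if (diff(range(y)) < 3 * rsd)
    stop("unidentifiable fit: no transition in the data ",
         "(signal range < 3 x residual sd)", call. = FALSE)
  structure(
    list(kd = 10^p$lkd,
         hill_h = if (free_h) p$h else 1,
         baseline_low = if (free_base) p$lo else 0,
         baseline_high = if (free_base) p$hi else 1,
         converged = converged, model = model, baselines = baselines,
         n = length(L), residual_sd = rsd),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("%s binding fit (n = %d): Kd = %.3g M",
              if (x$model == "hill") "Hill" else "Single-site", x$n, x$kd))
  if (x$model == "hill") cat(sprintf(", h = %.2f", x$hill_h))
  cat("\n")
  invisible(x)
}
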