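#' Mode of a log-normal distribution from linear-space moments
#'
#' Cluster-size histograms are summarised by the mode of a fitted
#' log-normal distribution. When the fit is reported through its
#' linear-space mean `mu_lin` and standard deviation `sigma_lin`, these
#' are converted to log-space parameters by moment matching,
#' \deqn{\sigma_{\log}^2 = \ln(1 + (\sigma/\mu)^2), \qquad
#'       \mu_{\log} = \ln\mu - \sigma_{\log}^2 / 2,}
#' and the mode is \eqn{d = e^{\mu_{\log} - \sigma_{\log}^2}}. With the
#' printed nanocluster parameters (88, 24) nm and (123, 46) nm this gives
#' modal diameters of 79 nm and 101 nm after rounding.
#'
#' @param mu_lin linear-space mean (same units as the data).
#' @param sigma_lin linear-space standard deviation.
#' @return The mode, in the units of `mu_lin`.
#' @examples
#' lognormal_mode(88, 24)   # ~ 79
#' lognormal_mode(123, 46)  # ~ 101
#' @export
lognormal_mode <- function(mu_lin, sigma_lin) {
  p <- lognormal_moment_params(mu_lin, sigma_lin)
  exp(p$mu_log - p$sigma_log^2)
}

#' Log-space parameters of a log-normal from linear-space moments
#'
#' @inheritParams lognormal_mode
#' @return A list with `mu_log` and `sigma_log`.
#' @export
lognormal_moment_params <- function(mu_lin, sigma_lin) {
  if (!is.numeric(mu_lin) || any(mu_lin <= 0))
    stop("'mu_lin' must be positive", call. = FALSE)
  if (any(sigma_lin < 0))
    stop("'sigma_lin' must be non-negative", call. = FALSE)
  s2 <- log(1 + (sigma_lin / mu_lin)^2)
  list(mu_log = log(mu_lin) - s2 / 2, sigma_log = sqrt(s2))
}

#' Fit a log-normal distribution to samples or binned frequencies
#'
#' For raw samples the log-space maximum-likelihood estimates are the mean
#' and standard deviation of the log values. For binned relative
#' frequencies (`mids` + `freq`) the log-normal density is fitted by
#' weighted least squares. Both routes report log-space and linear-space
#' parameters and the mode.
#'
#' @param samples positive sample values; or `NULL` when fitting bins.
#' @param mids,freq bin midpoints and relative frequencies (used when
#'   `samples` is `NULL`).
#' @return An object of class `lognormal_fit` with `mu_log`, `sigma_log`,
#'   `mu_lin`, `sigma_lin`, `mode`, `n`, `method`.
#' @export
fit_lognormal <- function(samples = NULL, mids = NULL, freq = NULL) {
  if (!is.null(samples)) {
    samples <- as.numeric(samples)
    bad <- which(!is.finite(samples) | samples <= 0)
    if (length(bad))
      stop("non-positive sample(s) at index ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    if (length(samples) < 10L)
      stop("need at least 10 samples", call. = FALSE)
    lx <- log(samples)
    mu_log <- mean(lx)
    sigma_log <- stats::sd(lx)
    n <- length(samples)
    method <- "mle"
  } else {
    if (is.null(mids) || is.null(freq) || length(mids) != length(freq))
      stop("give 'samples', or matching 'mids' and 'freq'", call. = FALSE)
    ok <- freq > 0 & mids > 0
    if (sum(ok) < 4L) stop("too few populated bins", call. = FALSE)
    df <- data.frame(x = mids[ok], y = freq[ok] / sum(freq[ok]))
    m0 <- sum(df$x * df$y); v0 <- sum(df$x^2 * df$y) - m0^2
    p0 <- lognormal_moment_params(m0, sqrt(max(v0, 1e-12)))
    fit <- minpack.lm::nlsLM(
      y ~ A * stats::dlnorm(x, mu, s), data = df,
      start = list(A = mean(diff(mids)), mu = p0$mu_log,
                   s = max(p0$sigma_log, 0.05)),
      lower = c(1e-12, -Inf, 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    cf <- stats::coef(fit)
    mu_log <- unname(cf["mu"]); sigma_log <- unname(cf["s"])
    n <- sum(ok)
    method <- "binned_ls"
  }
  mu_lin <- exp(mu_log + sigma_log^2 / 2)
  sigma_lin <- mu_lin * sqrt(exp(sigma_log^2) - 1)
  structure(list(mu_log = mu_log, sigma_log = sigma_log, mu_lin = mu_lin,
                 sigma_lin = sigma_lin,
                 mode = exp(mu_log - sigma_log^2), n = n, method = method),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "lognormal_fit (%s): mu = %.4g, sigma = %.4g (linear), mode = %.4g\n",
    x$method, x$mu_lin, x$sigma_lin, x$mode))
  invisible(x)
}

#' Dark-time statistics of a binding-event series
#'
#' Computes the dark intervals between successive bright (binding) events
#' of one cluster and the mean dark time `tau_D`. Bright frames are first
#' collapsed into events (runs of consecutive frames); the dark interval
#' between events ending at frame f1 and starting at f2 is
#' `(f2 - f1 - 1) / frame_rate`. The mean dark time is estimated by
#' fitting the exponential CDF `1 - exp(-t / tau)` to the empirical
#' cumulative distribution of intervals (least squares); the interval mean
#' (the MLE) is reported alongside as a cross-check. The qPAINT index is
#' `1 / tau_D`, proportional to the number of docking strands.
#'
#' @param frames integer frames at which the cluster was bright.
#' @param frame_rate acquisition rate, Hz.
#' @return An object of class `dark_time_stats`: `intervals` (s),
#'   `tau_d` (CDF fit, s), `tau_d_mle` (interval mean, s),
#'   `qpaint_index` (1/s), `n_events`.
#' @export
dark_times <- function(frames, frame_rate = 10) {
  frames <- sort(unique(as.integer(frames)))
  if (length(frames) < 2L)
    stop("dark times need at least 2 bright events", call. = FALSE)
  runs <- merge_runs(frames, 0)
  if (nrow(runs) < 2L)
    stop("dark times need at least 2 bright events", call. = FALSE)
  gaps_frames <- runs[-1, 1] - runs[-nrow(runs), 2] - 1
  intervals <- gaps_frames / frame_rate
  intervals <- intervals[intervals > 0]
  if (!length(intervals))
    stop("no positive dark intervals", call. = FALSE)
  tau_mle <- mean(intervals)
  tau_cdf <- fit_exp_cdf(intervals, tau_mle)
  structure(list(intervals = intervals, tau_d = tau_cdf,
                 tau_d_mle = tau_mle, qpaint_index = 1 / tau_cdf,
                 n_events = nrow(runs), frame_rate = frame_rate),
            class = "dark_time_stats")
}

# least-squares fit of 1 - exp(-t/tau) to the empirical CDF
fit_exp_cdf <- function(x, tau0) {
  xs <- sort(x)
  Fe <- seq_along(xs) / length(xs)
  obj <- function(tau) sum((Fe - (1 - exp(-xs / tau)))^2)
  stats::optimize(obj, interval = c(tau0 / 50, tau0 * 50))$minimum
}

#' qPAINT copy number from cluster and calibration index distributions
#'
#' The qPAINT index (inverse mean dark time) of a cluster is proportional
#' to its number of docking strands. The copy number is the ratio of the
#' modes of log-normal fits to the cluster and calibration (single
#' docking-site antibody complex) index distributions:
#' `n = mode(cluster) / mode(calibration)`.
#'
#' @param cluster_indices qPAINT indices of the clusters of interest, 1/s.
#' @param calibration_indices qPAINT indices of calibration complexes.
#' @return An object of class `qpaint_result` with `cluster_mode`,
#'   `calibration_mode`, `n` and both fits.
#' @export
copy_number <- function(cluster_indices, calibration_indices) {
  fc <- fit_lognormal(cluster_indices)
  f0 <- fit_lognormal(calibration_indices)
  if (f0$mode <= 0)
    stop("calibration mode must be positive", call. = FALSE)
  structure(list(cluster_mode = fc$mode, calibration_mode = f0$mode,
                 n = fc$mode / f0$mode, cluster_fit = fc,
                 calibration_fit = f0),
            class = "qpaint_result")
}

#' qPAINT copy number from reported log-normal moments
#'
#' Applies the moment-conversion mode to linear-space (mu, sigma) pairs of
#' the cluster and calibration index distributions and returns the mode
#' ratio, for use when only fitted moments (not raw indices) are
#' available.
#'
#' @param mu_cluster,sigma_cluster linear-space moments of the cluster
#'   qPAINT-index distribution, 1/s.
#' @param mu_cal,sigma_cal moments of the calibration distribution.
#' @return A list with `cluster_mode`, `calibration_mode` and `n`.
#' @export
copy_number_from_moments <- function(mu_cluster, sigma_cluster,
                                     mu_cal, sigma_cal) {
  mc <- lognormal_mode(mu_cluster, sigma_cluster)
  m0 <- lognormal_mode(mu_cal, sigma_cal)
  list(cluster_mode = mc, calibration_mode = m0, n = mc / m0)
}

#' @export
print.qpaint_result <- function(x, ...) {
  cat(sprintf(
    "qPAINT: cluster mode %.3g / calibration mode %.3g -> n = %.2f\n",
    x$cluster_mode, x$calibration_mode, x$n))
  invisible(x)
}
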