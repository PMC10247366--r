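#' Waiting-time sample for vesiculation kinetics
#'
#' Bundles uncensored vesicle-formation waiting times with the horizons of
#' replicates that never transitioned (right-censored observations).
#'
#' @param times uncensored waiting times, ns; all positive.
#' @param censored_horizons horizons of censored replicates, ns.
#' @param temperature simulation temperature, K.
#' @param label free-text condition label.
#' @return An object of class `waiting_time_sample`.
#' @export
waiting_time_sample <- function(times, censored_horizons = numeric(0),
                                temperature = 300, label = "") {
  times <- as.numeric(times); censored_horizons <- as.numeric(censored_horizons)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("waiting times must be finite and positive", call. = FALSE)
  if (any(!is.finite(censored_horizons)) || any(censored_horizons <= 0))
    stop("censoring horizons must be finite and positive", call. = FALSE)
  structure(list(times = times, censored_horizons = censored_horizons,
                 temperature = temperature, label = label),
            class = "waiting_time_sample")
}

#' Collect transition records into a waiting-time sample
#'
#' @param records list of [classify_transition()] results sharing one
#'   temperature.
#' @param label condition label.
#' @return A [waiting_time_sample()].
#' @export
as_waiting_time_sample <- function(records, label = "") {
  stopifnot(length(records) > 0)
  temps <- vapply(records, function(r) r$temperature, numeric(1))
  if (length(unique(temps)) > 1L)
    stop("records mix temperatures; split per condition first",
         call. = FALSE)
  cen <- vapply(records, function(r) r$censored, logical(1))
  waiting_time_sample(
    times = vapply(records[!cen], function(r) r$waiting_time, numeric(1)),
    censored_horizons = vapply(records[cen], function(r) r$horizon,
                               numeric(1)),
    temperature = temps[1], label = label)
}

#' Fit the Poisson-with-lag (shifted exponential) vesiculation model
#'
#' Models vesicle-formation waiting times as a Poisson process with rate
#' `k'` preceded by a constant lag `tau` needed for closure of the curved
#' disc: the waiting-time density is `p(t) = k' exp(-k'(t - tau))` for
#' `t > tau`. The overall vesiculation rate is `k = 1/(t' + tau)` with
#' `t' = 1/k'`.
#'
#' Two estimators are provided. `"mle"` uses the closed-form maximum
#' likelihood estimates `tau = min(t)` and
#' `k' = n_u / (sum_u (t_i - tau) + sum_c (h_j - tau)_+)`, where censored
#' replicates contribute their exposure beyond the lag (survival terms).
#' The minimum-order-statistic estimate of `tau` carries the known positive
#' bias of order `1/(n k')`; it is reported uncorrected. `"cdf_ls"` fits
#' the model CDF `1 - exp(-k'(t - tau))` to the empirical CDF of the
#' uncensored times by least squares with `tau` constrained to at most
#' `min(t)`.
#'
#' @param sample a [waiting_time_sample()].
#' @param method `"mle"` (default) or `"cdf_ls"`.
#' @return An object of class `shifted_exp_fit` with `k_prime`, `tau`,
#'   `t_prime`, `k_overall`, `loglik`, `n_uncensored`, `n_censored`,
#'   `method`.
#' @examples
#' fit_shifted_exponential(waiting_time_sample(c(2, 3, 4, 5)))
#' @export
fit_shifted_exponential <- function(sample, method = c("mle", "cdf_ls")) {
  stopifnot(inherits(sample, "waiting_time_sample"))
  method <- match.arg(method)
  t_u <- sample$times; h_c <- sample$censored_horizons
  if (length(t_u) == 0L)
    stop("all observations are censored; cannot fit", call. = FALSE)
  if (method == "mle") {
    if (length(t_u) < 2L)
      stop("mle requires at least 2 uncensored times", call. = FALSE)
    tau <- min(t_u)
    expo <- sum(t_u - tau) + sum(pmax(h_c - tau, 0))
    if (expo <= 0)
      stop("zero exposure beyond the lag; degenerate sample", call. = FALSE)
    k_prime <- length(t_u) / expo
  } else {
    if (length(t_u) < 5L)
      stop("cdf_ls requires at least 5 uncensored times", call. = FALSE)
    ts <- sort(t_u)
    ecdf_v <- seq_along(ts) / length(ts)
    tau0 <- min(ts) * 0.95
    k0 <- 1 / max(mean(ts) - tau0, .Machine$double.eps)
    df <- data.frame(t = ts, F = ecdf_v)
    fit <- minpack.lm::nlsLM(
      F ~ pmax(0, 1 - exp(-k * (t - tau))), data = df,
      start = list(k = k0, tau = tau0),
      lower = c(1e-12, 0), upper = c(Inf, min(ts)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    k_prime <- unname(cf["k"]); tau <- unname(cf["tau"])
  }
  ll <- length(t_u) * log(k_prime) - k_prime * sum(pmax(t_u - tau, 0)) -
    k_prime * sum(pmax(h_c - tau, 0))
  structure(list(k_prime = k_prime, tau = tau, t_prime = 1 / k_prime,
                 k_overall = 1 / (1 / k_prime + tau), loglik = ll,
                 n_uncensored = length(t_u), n_censored = length(h_c),
                 method = method, label = sample$label,
                 temperature = sample$temperature),
            class = "shifted_exp_fit")
}

#' @export
print.shifted_exp_fit <- function(x, ...) {
  cat(sprintf(paste0("shifted_exp_fit (%s): k' = %.4g 1/ns, tau = %.4g ns,",
                     " k = %.4g 1/ns\n"),
              x$method, x$k_prime, x$tau, x$k_overall))
  cat(sprintf("  n = %d uncensored + %d censored\n",
              x$n_uncensored, x$n_censored))
  invisible(x)
}

#' Vesiculation acceleration factor relative to a reference rate
#'
#' Ratio of a system's overall vesiculation rate to a reference rate; the
#' default reference 0.0018 1/ns is the maximum-likelihood rate of the
#' non-ubiquitinated RHD bicelle.
#'
#' @param fit a [fit_shifted_exponential()] result, or a bare overall rate
#'   `k` in 1/ns.
#' @param k_ref reference rate, 1/ns.
#' @return An object of class `acceleration_result` with `k_sys`, `k_ref`
#'   and `acc = k_sys / k_ref`.
#' @export
acceleration_factor <- function(fit, k_ref = 0.0018) {
  if (!is.numeric(k_ref) || length(k_ref) != 1L || k_ref <= 0)
    stop("'k_ref' must be a positive rate", call. = FALSE)
  k_sys <- if (inherits(fit, "shifted_exp_fit")) fit$k_overall
           else as.numeric(fit)
  if (!is.finite(k_sys) || k_sys <= 0)
    stop("system rate must be positive", call. = FALSE)
  structure(list(k_sys = k_sys, k_ref = k_ref, acc = k_sys / k_ref),
            class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf("acceleration: k_sys = %.4g / k_ref = %.4g -> acc = %.3f\n",
              x$k_sys, x$k_ref, x$acc))
  invisible(x)
}

#' Count successful vesicle closures among replicates
#'
#' Summarises how many replicates of one condition closed into vesicles
#' within the simulated timescale (uncensored transition records).
#'
#' @param records list of [classify_transition()] results sharing one
#'   temperature.
#' @return A list with `n_total`, `n_closed`, `fraction` and `temperature`.
#' @export
closure_count <- function(records) {
  if (length(records) == 0L)
    stop("empty record list", call. = FALSE)
  temps <- vapply(records, function(r) r$temperature, numeric(1))
  if (length(unique(temps)) > 1L)
    stop("records mix temperatures; closure counts are per condition",
         call. = FALSE)
  closed <- sum(!vapply(records, function(r) r$censored, logical(1)))
  list(n_total = length(records), n_closed = closed,
       fraction = closed / length(records), temperature = temps[1])
}

#' Read waiting times from CSV
#'
#' Expects columns `time_ns, censored, horizon_ns` and optionally
#' `temperature_K, label`; censored rows (censored = 1) use `horizon_ns`.
#'
#' @param path CSV path.
#' @return A [waiting_time_sample()] (or a list of them when several labels
#'   are present).
#' @export
read_waiting_times_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ns", "censored", "horizon_ns")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$temperature_K)) df$temperature_K <- 300
  if (is.null(df$label)) df$label <- ""
  mk <- function(d)
    waiting_time_sample(d$time_ns[d$censored == 0],
                        d$horizon_ns[d$censored == 1],
                        temperature = d$temperature_K[1], label = d$label[1])
  out <- lapply(split(df, df$label), mk)
  if (length(out) == 1L) out[[1]] else out
}
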