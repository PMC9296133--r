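#' Normalize a FRAP intensity series to the prebleach level
#'
#' Divides all intensities by the mean of the prebleach frames and re-zeroes
#' time at the first post-bleach frame.
#'
#' @param raw data frame with columns `time_s` and `intensity` (and
#'   optionally `phase` in `"pre"`/`"post"`), or a numeric intensity vector.
#' @param n_prebleach number of leading prebleach frames; taken from the
#'   `phase` column when present.
#' @param time_step_s frame interval, required when `raw` is a bare vector.
#' @return object of class `frap_curve`: list with `times_s` (post-bleach,
#'   from 0), `normalized` (post-bleach), `pre_normalized`, `n_prebleach`,
#'   `prebleach_mean`.
#' @export
normalize_frap <- function(raw, n_prebleach = NULL, time_step_s = NULL) {
  if (is.numeric(raw)) {
    if (is.null(time_step_s))
      .stop_class("time_step_s required for a bare intensity vector",
                  "nedyn_input_error")
    raw <- data.frame(time_s = (seq_along(raw) - 1) * time_step_s,
                      intensity = raw)
  }
  if (!all(c("time_s", "intensity") %in% names(raw)))
    .stop_class("need columns time_s and intensity", "nedyn_input_error")
  if (is.null(n_prebleach)) {
    if (!"phase" %in% names(raw))
      .stop_class("n_prebleach not given and no phase column", "nedyn_input_error")
    n_prebleach <- sum(raw$phase == "pre")
  }
  n <- nrow(raw)
  if (n_prebleach < 1) .stop_class("need >= 1 prebleach frame", "nedyn_input_error")
  if (n <= n_prebleach)
    .stop_class("series has no post-bleach frames", "nedyn_input_error")
  pre <- raw$intensity[seq_len(n_prebleach)]
  pre_mean <- mean(pre)
  if (pre_mean <= 0)
    .stop_class("prebleach mean is not positive", "nedyn_normalization_error")
  post <- (n_prebleach + 1):n
  structure(list(times_s = raw$time_s[post] - raw$time_s[post[1]],
                 normalized = raw$intensity[post] / pre_mean,
                 pre_normalized = pre / pre_mean,
                 n_prebleach = n_prebleach, prebleach_mean = pre_mean),
            class = "frap_curve")
}

#' Fit the single-exponential FRAP recovery model
#'
#' Least-squares fit of f(t) = A * (1 - exp(-tau * t)) to the normalized
#' post-bleach intensities: A is the mobile fraction, tau the recovery rate,
#' T1/2 = ln(2)/tau the half-time and 1 - A the immobile fraction. The
#' upper bound on A is 1.5 rather than 1 so that noise near full recovery
#' is not clipped; fitted values above 1 are flagged. If the default start
#' (A from the tail of the curve, tau = 1/median(t)) fails, a multistart
#' over five decades of tau is attempted.
#'
#' @param curve a [normalize_frap()] result.
#' @param A_max upper bound for the mobile fraction.
#' @param init optional named list with starting `A` and `tau`.
#' @param offset if `TRUE`, fit f(t) = b + A * (1 - exp(-tau * t)) with a
#'   free baseline b (incomplete bleaching); the printed model (b = 0) is
#'   the default.
#' @return object of class `frap_fit`: list with `A`, `tau`, `t_half`,
#'   `immobile`, `rss`, `converged`, `se_A`, `se_tau`, `flag_A_above_1`,
#'   and `offset_b` when `offset = TRUE`.
#' @export
fit_recovery <- function(curve, A_max = 1.5, init = NULL, offset = FALSE) {
  stopifnot(inherits(curve, "frap_curve"))
  t <- curve$times_s; y <- curve$normalized
  if (length(t) < 4)
    .stop_class("need >= 4 post-bleach points", "nedyn_input_error")
  if (length(unique(t)) < 2)
    .stop_class("need >= 2 distinct times", "nedyn_input_error")
  A0 <- if (!is.null(init$A)) init$A else
    min(max(mean(tail(y, 3)), 0.01), A_max)
  tau0 <- if (!is.null(init$tau)) init$tau else 1 / median(t[t > 0])
  one_fit <- function(A_start, tau_start) {
    tryCatch({
      if (offset) {
        minpack.lm::nlsLM(y ~ b + A * (1 - exp(-tau * t)),
                          start = list(A = A_start, tau = tau_start, b = min(y)),
                          lower = c(0, 1e-10, -0.5), upper = c(A_max, Inf, 0.5),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ A * (1 - exp(-tau * t)),
                          start = list(A = A_start, tau = tau_start),
                          lower = c(0, 1e-10), upper = c(A_max, Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
  }
  fit <- one_fit(A0, tau0)
  if (is.null(fit)) {
    for (mult in 10^(-2:2)) {
      fit <- one_fit(A0, tau0 * mult)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    .stop_class("recovery fit did not converge after multistart", "nedyn_fit_error")
  cf <- coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  structure(list(A = unname(cf["A"]), tau = unname(cf["tau"]),
                 t_half = log(2) / unname(cf["tau"]),
                 immobile = 1 - unname(cf["A"]),
                 rss = sum(residuals(fit)^2), converged = TRUE,
                 se_A = unname(ses["A"]), se_tau = unname(ses["tau"]),
                 flag_A_above_1 = unname(cf["A"]) > 1,
                 offset_b = if (offset) unname(cf["b"]) else NULL),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile A = %.3f (se %.3g), tau = %.4g /s, T1/2 = %.3g s, immobile = %.3f, rss = %.3g\n",
              x$A, x$se_A, x$tau, x$t_half, x$immobile, x$rss))
  invisible(x)
}

#' Summarize a set of FRAP fits
#'
#' Arithmetic mean and sample standard deviation of the mobile fraction,
#' rate and half-time over converged fits; non-converged fits are excluded
#' and counted.
#'
#' @param fits list of [fit_recovery()] results (entries may be `NULL` for
#'   failed fits).
#' @return data frame with one row per parameter (`A`, `tau`, `t_half`):
#'   `mean`, `sd` (`NA` for a single fit), `n`; attribute `n_excluded`.
#' @export
summarize_fits <- function(fits) {
  ok <- Filter(function(f) !is.null(f) && isTRUE(f$converged), fits)
  if (!length(ok))
    .stop_class("no converged fits to summarize", "nedyn_summary_error")
  grab <- function(field) vapply(ok, `[[`, numeric(1), field)
  out <- do.call(rbind, lapply(c("A", "tau", "t_half"), function(p) {
    v <- grab(p)
    data.frame(parameter = p, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_, n = length(v))
  }))
  attr(out, "n_excluded") <- length(fits) - length(ok)
  out
}
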