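# Classification cutoffs: uniform (a fixed z value) or dynamically tailored
# to a person's diurnal rhythm through a single-harmonic cosinor regression
#   theta_i = beta0 + beta1 sin(2*pi/24 * HOUR_i) + beta2 cos(2*pi/24 * HOUR_i) + r_i
# fitted to all previously observed scores of that person.

#' Cutoff specification
#'
#' @param kind `"uniform"` (one z cutoff for everyone at all times) or
#'   `"dynamic"` (person- and time-of-day-specific: cosinor prediction plus
#'   `delta_sd` residual SDs).
#' @param uniform_z Uniform cutoff on the z metric (default 1.0, roughly the
#'   85th percentile of the norming population).
#' @param delta_sd Dynamic-cutoff offset in within-person residual SDs
#'   (default 0.5, a common minimally-important-difference benchmark).
#' @param daytime `(start_hour, end_hour)` half-open daytime window during
#'   which dynamic classification is made (default `c(6, 18)`).
#' @param run_in_days Initial days used only to accumulate cutoff-estimation
#'   data, never for classification (default 2).
#' @export
cutoff_spec <- function(kind = c("uniform", "dynamic"), uniform_z = 1.0,
                        delta_sd = 0.5, daytime = c(6, 18), run_in_days = 2L) {
  kind <- match.arg(kind)
  if (length(daytime) != 2L || daytime[2] <= daytime[1]) {
    stop_jita("`daytime` must be (start_hour, end_hour) with end > start",
              "jitaema_argument_error")
  }
  if (delta_sd < 0) stop_jita("`delta_sd` must be >= 0", "jitaema_argument_error")
  run_in_days <- as.integer(run_in_days)
  if (run_in_days < 0L) stop_jita("`run_in_days` must be >= 0", "jitaema_argument_error")
  structure(list(kind = kind, uniform_z = uniform_z, delta_sd = delta_sd,
                 daytime = as.numeric(daytime), run_in_days = run_in_days),
            class = "cutoff_spec")
}

cosinor_design <- function(hours) {
  x <- 2 * pi * hours / 24
  cbind(1, sin(x), cos(x))
}

#' Fit a cosinor (diurnal rhythm) regression
#'
#' Ordinary least squares of the state values on the sine and cosine of
#' clock time; the residual SD uses denominator `n - 3` (model degrees of
#' freedom).
#'
#' @param hours Clock times in `[0, 24)`.
#' @param thetas State values (same length).
#' @return A `cosinor_fit` with `beta0`, `beta1`, `beta2`, `resid_sd`,
#'   `n_obs`.
#' @examples
#' h <- 0:23
#' fit_cosinor(h, 0.3 + 0.4 * sin(2 * pi * h / 24) - 0.2 * cos(2 * pi * h / 24))
#' @export
fit_cosinor <- function(hours, thetas) {
  if (length(hours) != length(thetas)) {
    stop_jita("`hours` and `thetas` must have equal length", "jitaema_argument_error")
  }
  n <- length(hours)
  if (n < 3L) {
    stop_jita(sprintf("need at least 3 observations, got %d", n),
              "jitaema_singular_fit")
  }
  X <- cosinor_design(hours)
  qrx <- qr(X)
  if (qrx$rank < 3L) {
    stop_jita("rank-deficient cosinor design (need >= 3 distinct hours in general position)",
              "jitaema_singular_fit")
  }
  beta <- qr.coef(qrx, thetas)
  resid <- thetas - drop(X %*% beta)
  resid_sd <- if (n > 3L) sqrt(sum(resid^2) / (n - 3)) else 0
  structure(list(beta0 = beta[[1]], beta1 = beta[[2]], beta2 = beta[[3]],
                 resid_sd = resid_sd, n_obs = n),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> beta0 = %.4f, beta1 = %.4f, beta2 = %.4f, resid_sd = %.4f (n = %d)\n",
              x$beta0, x$beta1, x$beta2, x$resid_sd, x$n_obs))
  invisible(x)
}

#' Predict from a cosinor fit
#'
#' @param fit A `cosinor_fit` (or anything with `beta0`, `beta1`, `beta2`).
#' @param hour Clock time(s); the prediction is 24-periodic.
#' @export
predict_cosinor <- function(fit, hour) {
  x <- 2 * pi * hour / 24
  fit$beta0 + fit$beta1 * sin(x) + fit$beta2 * cos(x)
}

#' Dynamically tailored classification cutoff
#'
#' Fits a cosinor model to a person's previously observed state values
#' (everything up to, and excluding, the current prompt — including run-in
#' and nighttime prompts) and returns the predicted level at the current
#' hour plus `delta_sd` residual SDs. When the fit is singular or there are
#' fewer than 3 observations, falls back to
#' `mean(history) + delta_sd * sd(history)`.
#'
#' @param hours,thetas Observation history (hours of day and observed state
#'   values), current prompt excluded.
#' @param current_hour Hour of the prompt being classified.
#' @param spec A [cutoff_spec()] (its `delta_sd` is used).
#' @return The cutoff (latent z units).
#' @export
dynamic_cutoff <- function(hours, thetas, current_hour, spec = cutoff_spec("dynamic")) {
  if (length(thetas) == 0L) {
    stop_jita("empty history: callers must guarantee a run-in before classification",
              "jitaema_argument_error")
  }
  fit <- tryCatch(fit_cosinor(hours, thetas),
                  jitaema_singular_fit = function(e) NULL)
  if (is.null(fit)) {
    s <- if (length(thetas) > 1L) stats::sd(thetas) else 0
    return(mean(thetas) + spec$delta_sd * s)
  }
  predict_cosinor(fit, current_hour) + spec$delta_sd * fit$resid_sd
}

#' Is a prompt eligible for classification?
#'
#' Under a dynamic cutoff, prompts during the run-in days or outside the
#' half-open daytime window `[start_hour, end_hour)` are not classified
#' (they still contribute to cutoff estimation). Uniform cutoffs classify
#' every prompt.
#'
#' @param day Study day (1-based).
#' @param hour Hour of day.
#' @param spec A [cutoff_spec()].
#' @export
is_classifiable <- function(day, hour, spec) {
  stopifnot(inherits(spec, "cutoff_spec"))
  if (spec$kind == "uniform") return(rep_len(TRUE, max(length(day), length(hour))))
  day > spec$run_in_days & hour >= spec$daytime[1] & hour < spec$daytime[2]
}
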