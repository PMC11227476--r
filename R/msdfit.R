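#' Fit diffusion models to trajectory MSD data
#'
#' The central model-fitting interface of the package. Computes the ensemble
#' mean-squared-displacement curve of a set of trajectories (or accepts a
#' precomputed `msd_curve`) and fits two models to the same curve,
#' independently:
#' \describe{
#'   \item{diffusion}{\eqn{MSD(\Delta t) = 2 d D \Delta t}, a weighted
#'     least-squares slope through the origin giving the diffusion
#'     coefficient \eqn{D} (µm²/s).}
#'   \item{anomalous}{\eqn{MSD(\Delta t) = \Gamma \Delta t^\alpha}, a
#'     weighted log–log regression giving the anomalous exponent
#'     \eqn{\alpha} (\eqn{\alpha < 1} constrained, \eqn{\alpha \approx 1}
#'     Brownian, \eqn{\alpha > 1} directed) and generalized coefficient
#'     \eqn{\Gamma} (µm²/s^\eqn{\alpha}).}
#' }
#' Weights are the per-lag pair counts.
#'
#' @param x a `chromo_tracks` data frame or an `msd_curve`.
#' @param dims dimensionality (default taken from `x`).
#' @param max_lag optional maximum lag in frames for tracks input.
#' @param ... unused.
#' @return an object of class `"msd_fit"` with components `curve`, `D`,
#'   `alpha`, `Gamma`, `dims`, `n_tracks`, `diffusion` and `anomalous`
#'   (full fit details).
#' @seealso [msd()], [fit_diffusion()], [fit_anomalous()]
#' @examples
#' sp <- motion_spec("brownian", D = 8.32e-5, dims = 3)
#' tr <- simulate_tracks(sp, 200, seed = 1)
#' fit <- msd_fit(tr)
#' coef(fit)
#' @export
msd_fit <- function(x, ...) UseMethod("msd_fit")

#' @rdname msd_fit
#' @export
msd_fit.chromo_tracks <- function(x, max_lag = NULL, ...) {
  curve <- msd(x, mode = "ensemble", max_lag = max_lag)
  msd_fit.msd_curve(curve, ...)
}

#' @rdname msd_fit
#' @export
msd_fit.msd_curve <- function(x, dims = attr(x, "dims"), ...) {
  dfit <- fit_diffusion(x, dims = dims)
  afit <- tryCatch(fit_anomalous(x), error = function(e) NULL)
  structure(list(curve = x, dims = dims,
                 n_tracks = attr(x, "n_tracks"),
                 D = dfit$D,
                 alpha = if (is.null(afit)) NA_real_ else afit$alpha,
                 Gamma = if (is.null(afit)) NA_real_ else afit$Gamma,
                 diffusion = dfit, anomalous = afit,
                 call = match.call()),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, digits = 4, ...) {
  cat("MSD model fit (", x$dims, "D, ",
      if (!is.null(x$n_tracks)) paste0(x$n_tracks, " tracks, ") else "",
      nrow(x$curve), " lags)\n", sep = "")
  cat(sprintf("  diffusion:  D = %s um^2/s  (MSD = %d D dt)%s\n",
              format(x$D, digits = digits), 2 * x$dims,
              if (x$diffusion$flag != "ok") paste0(" [", x$diffusion$flag, "]") else ""))
  cat(sprintf("  anomalous:  alpha = %s,  Gamma = %s um^2/s^alpha\n",
              format(x$alpha, digits = digits),
              format(x$Gamma, digits = digits)))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(D = object$D, alpha = object$alpha, Gamma = object$Gamma)
}

#' @export
summary.msd_fit <- function(object, ...) {
  rss_lin <- sum(object$curve$n_pairs * object$diffusion$residuals^2)
  rss_log <- if (is.null(object$anomalous)) NA_real_
             else sum(object$anomalous$residuals^2)
  out <- list(fit = object, coef = coef(object),
              rss_diffusion = rss_lin, rss_anomalous_log = rss_log,
              lag_range_s = range(object$curve$lag_s))
  class(out) <- "summary.msd_fit"
  out
}

#' @export
print.summary.msd_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  lag range: %g - %g s\n", x$lag_range_s[1], x$lag_range_s[2]))
  cat(sprintf("  weighted RSS (diffusion, um^4): %.3g;  RSS (anomalous, log): %.3g\n",
              x$rss_diffusion, x$rss_anomalous_log))
  invisible(x)
}

#' @export
predict.msd_fit <- function(object, lag_s = object$curve$lag_s,
                            model = c("anomalous", "diffusion"), ...) {
  model <- match.arg(model)
  if (model == "diffusion") object$diffusion$slope * lag_s
  else object$Gamma * lag_s^object$alpha
}

#' @export
residuals.msd_fit <- function(object, model = c("anomalous", "diffusion"), ...) {
  model <- match.arg(model)
  object$curve$msd_um2 - predict(object, model = model)
}

#' @export
plot.msd_fit <- function(x, log = "", ...) {
  cv <- x$curve
  graphics::plot(cv$lag_s, cv$msd_um2, pch = 16, log = log,
                 xlab = expression(Delta * t ~ "(s)"),
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  lag_fine <- seq(min(cv$lag_s), max(cv$lag_s), length.out = 200)
  graphics::lines(lag_fine, predict(x, lag_fine, model = "diffusion"),
                  col = "steelblue", lwd = 2)
  graphics::lines(lag_fine, predict(x, lag_fine, model = "anomalous"),
                  col = "firebrick", lwd = 2, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("diffusion: D = %.3g", x$D),
                              sprintf("anomalous: alpha = %.3g", x$alpha)),
                   col = c("steelblue", "firebrick"), lty = c(1, 2), lwd = 2)
  invisible(x)
}

#' @export
simulate.msd_fit <- function(object, nsim = 1, seed = NULL,
                             n_frames = 12L, dt = NULL, ...) {
  if (is.null(dt)) dt <- attr(object$curve, "dt")
  ## anomalous model: per-axis MSD 2 D* dt^alpha with 2 d D* = Gamma
  Dstar <- object$Gamma / (2 * object$dims)
  sp <- motion_spec("anomalous", D = Dstar, alpha = object$alpha,
                    dims = object$dims, dt = dt, n_frames = n_frames)
  simulate_tracks(sp, n_tracks = nsim, seed = seed)
}
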