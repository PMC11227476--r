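#' Motion model specification for synthetic trajectories
#'
#' Describes the stochastic motion model used by [simulate_tracks()]. The
#' anomalous model is fractional Brownian motion parameterized so that the
#' per-axis mean squared displacement is \eqn{2 D \Delta t^\alpha}; a
#' d-dimensional track therefore has MSD \eqn{2 d D \Delta t^\alpha}
#' (\eqn{6 D \Delta t^\alpha} in 3D). Brownian motion is the special case
#' \eqn{\alpha = 1}, directed motion adds a constant drift velocity on top of
#' a Brownian component, and immobile tracks have \eqn{D = 0}.
#'
#' @param model one of `"anomalous"`, `"brownian"`, `"directed"`, `"immobile"`.
#' @param D generalized diffusion coefficient (µm²/s^alpha); must be >= 0.
#' @param alpha anomalous exponent in (0, 2]; forced to 1 for brownian and
#'   directed models.
#' @param drift drift velocity vector (µm/s), directed model only.
#' @param dims spatial dimensionality, 2 or 3.
#' @param dt frame interval in seconds (default 10 s, the acquisition
#'   interval the generator emulates).
#' @param n_frames number of frames per track (default 12).
#' @return an object of class `"motion_spec"`.
#' @export
motion_spec <- function(model = c("anomalous", "brownian", "directed", "immobile"),
                        D = 8.32e-5, alpha = 1, drift = NULL,
                        dims = 3, dt = 10, n_frames = 12) {
  model <- match.arg(model)
  if (model == "brownian" || model == "directed") alpha <- 1
  if (model == "immobile") { D <- 0; alpha <- 1 }
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("D must be a single non-negative number")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 2)
    stop("alpha must lie in (0, 2]")
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (dt <= 0) stop("dt must be positive")
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (model == "directed") {
    if (is.null(drift)) stop("directed model requires a drift vector")
    if (length(drift) != dims) stop("drift must have length dims")
  } else drift <- rep(0, dims)
  structure(list(model = model, D = D, alpha = alpha, drift = drift,
                 dims = as.integer(dims), dt = dt,
                 n_frames = as.integer(n_frames)),
            class = "motion_spec")
}

#' Exact covariance of fractional Gaussian increments
#'
#' Covariance matrix of the per-axis step increments of fractional Brownian
#' motion with per-axis MSD \eqn{2 D \Delta t^\alpha}, for `n` consecutive
#' steps of duration `dt`. Used both by the Cholesky track synthesizer and as
#' an independent closed-form oracle in the test suite.
#'
#' @param n number of increments.
#' @param D generalized diffusion coefficient (µm²/s^alpha).
#' @param alpha anomalous exponent in (0, 2].
#' @param dt step duration (s).
#' @return an `n` x `n` covariance matrix.
#' @export
fgn_covariance <- function(n, D, alpha, dt) {
  k <- abs(outer(seq_len(n), seq_len(n), "-"))
  D * dt^alpha * ((k + 1)^alpha + abs(k - 1)^alpha - 2 * k^alpha)
}

## lower-triangular Cholesky factor of the increment covariance; exactness
## over speed is deliberate (n_frames stays in the hundreds).
fgn_chol <- function(n, D, alpha, dt) {
  if (n == 0L) return(matrix(0, 0, 0))
  S <- fgn_covariance(n, D, alpha, dt)
  t(chol(S + diag(1e-14 * max(diag(S), 1), n)))
}

#' Simulate ground-truthed chromatin trajectories
#'
#' Draws `n_tracks` trajectories from the motion model in `spec`. Anomalous
#' tracks are exact fractional Brownian motion obtained by Cholesky
#' factorization of the closed-form increment covariance; Brownian tracks are
#' the \eqn{\alpha = 1} special case (independent Gaussian steps), directed
#' tracks add `drift * t`, and immobile tracks are constant. Start positions
#' are drawn uniformly inside `start_region` (an axis-aligned ellipsoid).
#' Tracks are not reflected at the region boundary; over the short durations
#' simulated here this keeps the ensemble MSD exactly equal to the model's
#' closed form.
#'
#' @param spec a [motion_spec()].
#' @param n_tracks number of trajectories (>= 1).
#' @param start_region list with `center` and `semiaxes` (µm, length `dims`)
#'   defining the ellipsoid of start positions, or `NULL` for all tracks
#'   starting at the origin.
#' @param seed optional integer seed for reproducibility.
#' @return a `chromo_tracks` data frame with columns `track_id`, `frame`,
#'   `x_um`, `y_um` (and `z_um` when `dims == 3`), with attributes `dt` and
#'   `dims`.
#' @export
simulate_tracks <- function(spec, n_tracks, start_region = NULL, seed = NULL) {
  stopifnot(inherits(spec, "motion_spec"))
  if (n_tracks < 1) stop("n_tracks must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  d <- spec$dims
  nf <- spec$n_frames
  ns <- nf - 1L

  starts <- if (is.null(start_region)) {
    matrix(0, n_tracks, d)
  } else {
    sample_ellipsoid(n_tracks, start_region$center, start_region$semiaxes)
  }

  ## increments: ns x (n_tracks * d), one column per track x axis
  if (spec$D == 0) {
    inc <- matrix(0, ns, n_tracks * d)
  } else if (spec$alpha == 1) {
    inc <- matrix(stats::rnorm(ns * n_tracks * d,
                               sd = sqrt(2 * spec$D * spec$dt)),
                  ns, n_tracks * d)
  } else {
    L <- fgn_chol(ns, spec$D, spec$alpha, spec$dt)
    inc <- L %*% matrix(stats::rnorm(ns * n_tracks * d), ns, n_tracks * d)
  }

  tvec <- (seq_len(nf) - 1) * spec$dt
  pos <- vector("list", d)
  for (ax in seq_len(d)) {
    cols <- seq.int(ax, by = d, length.out = n_tracks)
    cum <- rbind(0, apply(inc[, cols, drop = FALSE], 2L, cumsum))
    cum <- cum + matrix(starts[, ax], nf, n_tracks, byrow = TRUE)
    if (spec$drift[ax] != 0) cum <- cum + tvec * spec$drift[ax]
    pos[[ax]] <- cum
  }

  out <- data.frame(
    track_id = rep(seq_len(n_tracks), each = nf),
    frame    = rep(seq_len(nf), n_tracks),
    x_um     = as.vector(pos[[1]]),
    y_um     = as.vector(pos[[2]])
  )
  if (d == 3L) out$z_um <- as.vector(pos[[3]])
  as_chromo_tracks(out, dt = spec$dt, dims = d)
}

## uniform sample inside an axis-aligned ellipsoid (rejection from the cube)
sample_ellipsoid <- function(n, center, semiaxes) {
  d <- length(semiaxes)
  out <- matrix(NA_real_, n, d)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    u <- matrix(stats::runif(m * d, -1, 1), m, d)
    keep <- rowSums(u^2) <= 1
    u <- u[keep, , drop = FALSE]
    take <- min(nrow(u), n - got)
    if (take > 0) out[got + seq_len(take), ] <- u[seq_len(take), , drop = FALSE]
    got <- got + take
  }
  sweep(sweep(out, 2L, semiaxes, "*"), 2L, center, "+")
}

#' @rdname simulate_tracks
#' @param x a data frame with track columns.
#' @param dt frame interval (s).
#' @param dims dimensionality (2 or 3).
#' @export
as_chromo_tracks <- function(x, dt, dims = if ("z_um" %in% names(x)) 3L else 2L) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(x)))
  if (dims == 3L && !"z_um" %in% names(x))
    stop("dims = 3 requires a z_um column")
  attr(x, "dt") <- dt
  attr(x, "dims") <- as.integer(dims)
  class(x) <- unique(c("chromo_tracks", class(x)))
  x
}

track_coord_cols <- function(dims) c("x_um", "y_um", "z_um")[seq_len(dims)]

#' Build a per-frame affine series describing global cell motion
#'
#' Convenience constructor for rigid-body (translation + rotation) motion
#' accumulating linearly over frames; frame 1 is always the identity.
#'
#' @param n_frames number of frames.
#' @param translation_per_frame 2-vector, µm per frame.
#' @param rotation_per_frame rotation about `center`, degrees per frame.
#' @param center rotation center (µm).
#' @return list of per-frame lists with elements `A` (2x2) and `b` (offset).
#' @export
affine_series <- function(n_frames, translation_per_frame = c(0, 0),
                          rotation_per_frame = 0, center = c(0, 0)) {
  lapply(seq_len(n_frames), function(t) {
    th <- (t - 1) * rotation_per_frame * pi / 180
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    b <- center - A %*% center + (t - 1) * translation_per_frame
    list(A = A, b = as.vector(b))
  })
}

#' Smooth sinusoidal deformation field
#'
#' A band-limited analytic displacement field used to emulate slow nuclear
#' deformation: \eqn{u_x = a_x \sin(2\pi y/\lambda)\, s(t)},
#' \eqn{u_y = a_y \sin(2\pi x/\lambda)\, s(t)} with a linear temporal ramp
#' \eqn{s(t) = (t-1)/(T-1)} so that frame 1 is undeformed.
#'
#' @param amplitude 2-vector of displacement amplitudes (µm).
#' @param wavelength spatial period (µm).
#' @param n_frames number of frames.
#' @return an object of class `"deformation_field"`; calling
#'   `eval_deformation(field, xy, frame)` returns per-point displacements.
#' @export
sinusoidal_deformation <- function(amplitude, wavelength, n_frames) {
  structure(list(amplitude = amplitude, wavelength = wavelength,
                 n_frames = as.integer(n_frames)),
            class = "deformation_field")
}

#' @rdname sinusoidal_deformation
#' @param field a `deformation_field`.
#' @param xy n x 2 matrix of positions (µm).
#' @param frame frame index (1-based).
#' @export
eval_deformation <- function(field, xy, frame) {
  if (is.null(field)) return(matrix(0, nrow(xy), 2))
  ramp <- if (field$n_frames > 1) (frame - 1) / (field$n_frames - 1) else 0
  w <- 2 * pi / field$wavelength
  cbind(field$amplitude[1] * sin(w * xy[, 2]),
        field$amplitude[2] * sin(w * xy[, 1])) * ramp
}

#' Apply global cell motion to trajectories
#'
#' Moves every track position by the per-frame affine transform followed by
#' the smooth deformation field (composition order fixed to match the
#' registration model: affine first, then non-rigid). Frame 1 is left
#' unchanged by construction. Only x and y are moved; the shallow z range of
#' the emulated acquisition carries no global motion.
#'
#' @param tracks a `chromo_tracks` data frame.
#' @param affine list of per-frame `list(A, b)` transforms (µm), or `NULL`.
#' @param deformation a [sinusoidal_deformation()] or `NULL`.
#' @return tracks with moved coordinates; the input (true) coordinates are
#'   kept in attribute `"true_tracks"`.
#' @export
apply_global_motion <- function(tracks, affine = NULL, deformation = NULL) {
  stopifnot(inherits(tracks, "chromo_tracks"))
  true <- tracks
  if (!is.null(affine)) {
    for (tr in affine) {
      if (abs(det(tr$A)) < 1e-12) stop("non-invertible affine transform")
    }
  }
  xy <- as.matrix(tracks[, c("x_um", "y_um")])
  for (f in sort(unique(tracks$frame))) {
    idx <- tracks$frame == f
    p <- xy[idx, , drop = FALSE]
    if (!is.null(affine)) {
      tr <- affine[[f]]
      p <- t(tr$A %*% t(p) + tr$b)
    }
    p <- p + eval_deformation(deformation, p, f)
    xy[idx, ] <- p
  }
  tracks$x_um <- xy[, 1]
  tracks$y_um <- xy[, 2]
  attr(tracks, "true_tracks") <- true
  attr(tracks, "affine") <- affine
  attr(tracks, "deformation") <- deformation
  tracks
}
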