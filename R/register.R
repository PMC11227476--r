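#' Estimate a 2D affine transform between two frames
#'
#' Classical intensity-based affine registration: minimizes the mean squared
#' intensity difference between the reference and the warped moving frame
#' over a multi-resolution pyramid (coarse-to-fine, Nelder–Mead at each
#' level). The transform is parameterized as rotation, log-scales, shear and
#' translation about the image center; the returned transform maps
#' reference pixel coordinates to moving-frame coordinates
#' (`out(x) = moving(A x + b)`), so warping the moving frame by it aligns
#' it to the reference. If no parameter set improves on the identity (flat
#' or incompatible images) the identity is returned with a warning.
#'
#' @param reference,moving 2D matrices of the same size.
#' @param levels pyramid scales, coarse to fine.
#' @param maxit Nelder–Mead iterations per level.
#' @return list with `A` (2x2), `b` (length-2 offset, pixels, about the
#'   image center), `mse` and `mse_identity`.
#' @export
estimate_affine <- function(reference, moving,
                            levels = c(0.25, 0.5, 1), maxit = 300) {
  stopifnot(all(dim(reference) == dim(moving)))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    warning("flat image: returning identity transform")
    return(list(A = diag(2), b = c(0, 0), mse = NA_real_, mse_identity = NA_real_))
  }
  par_to_affine <- function(p) {
    th <- p[3]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Sh <- matrix(c(1, p[6], 0, 1), 2, 2)
    A <- R %*% Sh %*% diag(exp(p[4:5]))
    list(A = A, b = p[1:2])
  }
  cost_at <- function(ref, mov, p, tscale) {
    tr <- par_to_affine(c(p[1:2] * tscale, p[3:6]))
    w <- warp_affine2d(mov, tr$A, tr$b, fill = NA)
    ok <- !is.na(w)
    if (sum(ok) < 0.25 * length(w)) return(1e12)
    mean((ref[ok] - w[ok])^2)
  }
  ## images are pre-smoothed at every level: with raw noisy frames the MSE
  ## rewards the noise averaging of bilinear resampling, biasing the
  ## optimum toward spurious half-pixel shifts
  presmooth <- 1.5
  ## coarse integer-shift search initializes the translation (gradient-free
  ## refinement alone stalls far from the optimum)
  s0 <- levels[1]
  ref_0 <- smooth2d(resize_img(reference, s0), presmooth)
  mov_0 <- smooth2d(resize_img(moving, s0), presmooth)
  rad <- round(0.3 * min(dim(ref_0)))
  best <- c(0, 0); best_mse <- Inf
  for (dy in -rad:rad) for (dx in -rad:rad) {
    w <- warp_affine2d(mov_0, diag(2), c(dy, dx), fill = NA)
    ok <- !is.na(w)
    mse <- mean((ref_0[ok] - w[ok])^2)
    if (mse < best_mse) { best_mse <- mse; best <- c(dy, dx) }
  }
  p <- c(best / s0, 0, 0, 0, 0)
  ## 1D rotation scan at the coarse level: Nelder-Mead alone creeps too
  ## slowly along the rotation axis to escape the identity basin
  thetas <- seq(-0.3, 0.3, by = 0.02)
  th_cost <- vapply(thetas, function(t2)
    cost_at(ref_0, mov_0, c(p[1:2], t2, 0, 0, 0), s0), numeric(1))
  p[3] <- thetas[which.min(th_cost)]
  for (s in levels) {
    ref_s <- smooth2d(if (s < 1) resize_img(reference, s) else reference, presmooth)
    mov_s <- smooth2d(if (s < 1) resize_img(moving, s) else moving, presmooth)
    ## translations optimized in full-resolution pixels, scaled per level;
    ## a restart re-inflates the simplex after premature collapse
    for (restart in 1:2) {
      op <- stats::optim(p, cost_at, ref = ref_s, mov = mov_s, tscale = s,
                         method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9,
                                        parscale = c(2 / s, 2 / s, 0.05,
                                                     0.02, 0.02, 0.02)))
      p <- op$par
    }
  }
  tr <- par_to_affine(p)
  ref_sm <- smooth2d(reference, presmooth)
  mov_sm <- smooth2d(moving, presmooth)
  mse0 <- mean((ref_sm - mov_sm)^2)
  w <- warp_affine2d(mov_sm, tr$A, tr$b, fill = NA)
  ok <- !is.na(w)
  mse1 <- mean((ref_sm[ok] - w[ok])^2)
  if (!is.finite(mse1) || mse1 > mse0) {
    warning("affine registration did not improve; returning identity")
    return(list(A = diag(2), b = c(0, 0), mse = mse0, mse_identity = mse0))
  }
  list(A = tr$A, b = tr$b, mse = mse1, mse_identity = mse0)
}

resize_img <- function(img, scale) {
  out <- EBImage::resize(img, w = max(2L, round(nrow(img) * scale)),
                         h = max(2L, round(ncol(img) * scale)))
  matrix(as.numeric(out), nrow(out), ncol(out))
}

#' Estimate a smooth non-rigid displacement field
#'
#' Demons-style diffeomorphic-flavored estimator run at reduced resolution:
#' both frames are downscaled by `scale_factor`, the displacement field is
#' iteratively refined (intensity-difference force normalized by local
#' gradient magnitude, Gaussian-smoothed each iteration), and the converged
#' field is upscaled back to full resolution. Estimating at reduced scale
#' and upscaling guarantees the field is band-limited (smooth) at the
#' chosen scale.
#'
#' @param reference affine-corrected target frame (2D matrix).
#' @param moving frame to deform onto the reference.
#' @param scale_factor estimation scale in (0, 0.5] (default 0.25).
#' @param n_iter demons iterations.
#' @param smooth_sigma Gaussian sigma (pixels, at the reduced scale) applied
#'   to the field every iteration.
#' @return list with `uy`, `ux`: full-size displacement matrices in pixels
#'   (`warped(x) = moving(x + u(x))`).
#' @export
estimate_nonrigid <- function(reference, moving, scale_factor = 0.25,
                              n_iter = 150L, smooth_sigma = 4.5) {
  if (scale_factor <= 0 || scale_factor > 1) stop("scale_factor must be in (0, 1]")
  demons_at <- function(ref_s, mov_s, uy, ux, n_iter, smooth_sigma) {
    eps <- 1e-6 * max(diff(range(ref_s))^2, 1)
    for (it in seq_len(n_iter)) {
      w <- warp_field2d(mov_s, uy, ux, fill = NA)
      w[is.na(w)] <- ref_s[is.na(w)]
      diffi <- w - ref_s
      gy <- (shift_arr(w, c(-1, 0)) - shift_arr(w, c(1, 0))) / 2
      gx <- (shift_arr(w, c(0, -1)) - shift_arr(w, c(0, 1))) / 2
      denom <- gy^2 + gx^2 + diffi^2 + eps
      ## fluid-like demons: smooth the update; only a light diffusion of
      ## the accumulated field (heavy field smoothing kills convergence)
      duy <- smooth2d(-diffi * gy / denom, smooth_sigma)
      dux <- smooth2d(-diffi * gx / denom, smooth_sigma)
      uy <- smooth2d(uy + duy, 0.5)
      ux <- smooth2d(ux + dux, 0.5)
    }
    list(uy = uy, ux = ux)
  }
  ## coarse-to-fine: half the estimation scale first, then the target scale
  scales <- unique(c(scale_factor / 2, scale_factor))
  uy <- ux <- NULL
  for (s in scales) {
    ref_s <- resize_img(reference, s)
    mov_s <- resize_img(moving, s)
    if (is.null(uy)) {
      uy <- matrix(0, nrow(ref_s), ncol(ref_s))
      ux <- matrix(0, nrow(ref_s), ncol(ref_s))
    } else {
      uy <- 2 * matrix(as.numeric(EBImage::resize(uy, w = nrow(ref_s), h = ncol(ref_s))),
                       nrow(ref_s), ncol(ref_s))
      ux <- 2 * matrix(as.numeric(EBImage::resize(ux, w = nrow(ref_s), h = ncol(ref_s))),
                       nrow(ref_s), ncol(ref_s))
    }
    fld <- demons_at(ref_s, mov_s, uy, ux, n_iter, smooth_sigma)
    uy <- fld$uy; ux <- fld$ux
  }
  full_nr <- nrow(reference); full_nc <- ncol(reference)
  uy_full <- matrix(as.numeric(EBImage::resize(uy, w = full_nr, h = full_nc)),
                    full_nr, full_nc) / scale_factor
  ux_full <- matrix(as.numeric(EBImage::resize(ux, w = full_nr, h = full_nc)),
                    full_nr, full_nc) / scale_factor
  list(uy = uy_full, ux = ux_full, scale_factor = scale_factor)
}

#' Register a time-lapse stack to its first frame
#'
#' Estimates, for every frame after the first, an affine transform followed
#' by a smooth non-rigid displacement field on the estimation channel's
#' maximum-intensity projection, and applies the composed transform to
#' every z-slice of the requested channels (the field is 2D and constant
#' over z, appropriate for thin stacks where axial resolution is poor).
#' Intensities are interpolated linearly and out-of-view pixels filled with
#' the background median. If a frame's composed transform would increase
#' the dissimilarity to frame 1, that frame falls back to the best simpler
#' transform (registration never increases the dissimilarity).
#'
#' @param stack a `timelapse_stack` or a named list of 4D arrays
#'   \code{[T, Z, Y, X]}.
#' @param estimation_channel channel name used to estimate transforms
#'   (default `"nucleus"`).
#' @param apply_channels channels the transforms are applied to.
#' @param nonrigid run the non-rigid stage after the affine stage?
#' @param scale_factor non-rigid estimation scale.
#' @return list with the registered `stack` and `transforms` (per-frame
#'   list with `A`, `b`, `uy`, `ux`).
#' @export
register_sequence <- function(stack, estimation_channel = "nucleus",
                              apply_channels = c("nucleus", "chromatin"),
                              nonrigid = TRUE, scale_factor = 0.25) {
  is_tls <- inherits(stack, "timelapse_stack")
  get_ch <- function(nm) if (is_tls) stack[[nm]] else stack[[nm]]
  est <- get_ch(estimation_channel)
  if (is.null(est)) stop("estimation channel not found")
  nt <- dim(est)[1]
  if (nt < 2) stop("need at least 2 frames")
  proj <- lapply(seq_len(nt), function(f)
    apply(est[f, , , , drop = FALSE][1, , , ], c(2, 3), max))
  ref <- proj[[1]]
  transforms <- vector("list", nt)
  transforms[[1]] <- list(A = diag(2), b = c(0, 0), uy = NULL, ux = NULL)
  out <- stack
  for (f in 2:nt) {
    bgp <- stats::median(proj[[f]])
    aff <- estimate_affine(ref, proj[[f]])
    warped_aff <- warp_affine2d(proj[[f]], aff$A, aff$b, fill = bgp)
    nr_field <- NULL
    if (nonrigid) {
      nr_field <- estimate_nonrigid(ref, warped_aff, scale_factor = scale_factor)
      warped_full <- warp_field2d(warped_aff, nr_field$uy, nr_field$ux,
                                  fill = bgp)
      ## dissimilarity guard: drop the field if it made things worse
      if (mean((ref - warped_full)^2) > mean((ref - warped_aff)^2))
        nr_field <- NULL
    }
    ## the transform is kept only if it actually reduces the dissimilarity
    ## to frame 1 on the estimation channel; an already-still frame is
    ## passed through untouched rather than resampled
    mse_id <- mean((ref - proj[[f]])^2)
    mse_aff <- if (is.null(nr_field)) mean((ref - warped_aff)^2)
               else mean((ref - warp_field2d(warped_aff, nr_field$uy,
                                             nr_field$ux, fill = bgp))^2)
    if (mse_aff >= mse_id) {
      transforms[[f]] <- list(A = diag(2), b = c(0, 0), uy = NULL, ux = NULL)
      next
    }
    transforms[[f]] <- list(A = aff$A, b = aff$b,
                            uy = if (is.null(nr_field)) NULL else nr_field$uy,
                            ux = if (is.null(nr_field)) NULL else nr_field$ux)
    for (ch in apply_channels) {
      arr <- out[[ch]]
      if (is.null(arr)) next
      bg <- stats::median(arr[f, , , ])
      for (z in seq_len(dim(arr)[2])) {
        sl <- arr[f, z, , ]
        sl <- warp_affine2d(sl, aff$A, aff$b, fill = bg)
        if (!is.null(nr_field))
          sl <- warp_field2d(sl, nr_field$uy, nr_field$ux, fill = bg)
        arr[f, z, , ] <- sl
      }
      if (is_tls) out[[ch]] <- arr else out[[ch]] <- arr
    }
  }
  list(stack = out, transforms = transforms)
}
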