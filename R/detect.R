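#' Spot-enhancing-filter detection of 3D chromatin foci
#'
#' Applies a Laplacian-of-Gaussian filter (Gaussian smoothing followed by a
#' discrete Laplacian, sign-flipped so bright spots give positive peaks,
#' with the axial sigma scaled by the voxel anisotropy), thresholds the
#' response at mean(|response|) + k * sd(|response|), and extracts local
#' maxima under 26-connectivity. Sub-voxel positions are refined by an
#' intensity-weighted centroid over the 3x3x3 response neighborhood and
#' returned in µm.
#'
#' @param volume 3D array \code{[Z, Y, X]} of intensities.
#' @param voxel_um voxel size c(z, y, x) in µm.
#' @param sigma_um lateral LoG sigma in µm (default 0.06, of the order of
#'   the SIM-like spot width); the axial sigma is scaled by the voxel
#'   anisotropy so the kernel is ~isotropic in voxel units.
#' @param k threshold factor (default 7, calibrated on noise-only
#'   control scenes so that pure noise yields no detections; the same k must be used for all
#'   frames of a sequence).
#' @return data frame with `x_um`, `y_um`, `z_um`, `response`,
#'   `volume_um3` (voxels above half-peak response in a local window times
#'   the voxel volume).
#' @export
sef_detect <- function(volume, voxel_um, sigma_um = 0.06, k = 7) {
  stopifnot(length(dim(volume)) == 3, all(is.finite(volume)))
  sig_yx <- sigma_um / voxel_um[2:3]
  sig_z <- max(sigma_um / voxel_um[1], 0.35)  # anisotropy-scaled, floored
  resp <- log_response3d(volume, sig_z, sig_yx[1], sig_yx[2])
  a <- abs(resp)
  s <- stats::sd(a)
  if (s == 0) return(empty_detections())
  thr <- mean(a) + k * s
  mx <- local_maxima3d(resp, thr)
  if (nrow(mx) == 0) return(empty_detections())
  d <- dim(volume)
  ## replicate padding inflates the response variance at the lateral
  ## borders; maxima inside the filter support of the border are dropped
  margin <- max(2L, ceiling(2 * max(sig_yx)))
  ok <- mx[, 2] > margin & mx[, 2] <= d[2] - margin &
        mx[, 3] > margin & mx[, 3] <= d[3] - margin
  mx <- mx[ok, , drop = FALSE]
  if (nrow(mx) == 0) return(empty_detections())
  out <- lapply(seq_len(nrow(mx)), function(i) {
    zi <- mx[i, 1]; yi <- mx[i, 2]; xi <- mx[i, 3]
    zr <- max(1, zi - 1):min(d[1], zi + 1)
    yr <- max(1, yi - 1):min(d[2], yi + 1)
    xr <- max(1, xi - 1):min(d[3], xi + 1)
    w <- resp[zr, yr, xr, drop = FALSE]
    w <- w - min(w)
    if (sum(w) == 0) w[] <- 1
    wz <- apply(w, 1, sum); wy <- apply(w, 2, sum); wx <- apply(w, 3, sum)
    cz <- sum(zr * wz) / sum(wz)
    cy <- sum(yr * wy) / sum(wy)
    cx <- sum(xr * wx) / sum(wx)
    ## crude volume estimate: voxels above half the peak response nearby
    zr2 <- max(1, zi - 3):min(d[1], zi + 3)
    yr2 <- max(1, yi - 4):min(d[2], yi + 4)
    xr2 <- max(1, xi - 4):min(d[3], xi + 4)
    nvox <- sum(resp[zr2, yr2, xr2] >= resp[zi, yi, xi] / 2)
    data.frame(x_um = (cx - 0.5) * voxel_um[3],
               y_um = (cy - 0.5) * voxel_um[2],
               z_um = (cz - 0.5) * voxel_um[1],
               response = resp[zi, yi, xi],
               volume_um3 = nvox * prod(voxel_um))
  })
  do.call(rbind, out)
}

empty_detections <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             response = numeric(0), volume_um3 = numeric(0))
}

#' Detect foci in every frame of a time-lapse stack
#'
#' Runs [sef_detect()] on the chosen channel of each frame with a single
#' threshold factor k for the whole sequence.
#'
#' @param stack a `timelapse_stack` (see [render_timelapse()]) or a 4D array
#'   \code{[T, Z, Y, X]}.
#' @param channel `"chromatin"` or `"nucleus"` for a `timelapse_stack`.
#' @param voxel_um voxel size (taken from the stack when available).
#' @param ... passed to [sef_detect()].
#' @return data frame of detections with a `frame` column.
#' @export
detect_sequence <- function(stack, channel = "chromatin", voxel_um = NULL, ...) {
  if (inherits(stack, "timelapse_stack")) {
    arr <- stack[[channel]]
    if (is.null(voxel_um)) voxel_um <- stack$voxel_um
  } else arr <- stack
  if (is.null(voxel_um)) stop("voxel_um required")
  nt <- dim(arr)[1]
  out <- lapply(seq_len(nt), function(f) {
    vol <- array(arr[f, , , , drop = FALSE], dim(arr)[-1])
    det <- sef_detect(vol, voxel_um, ...)
    if (nrow(det)) cbind(frame = f, det) else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) cbind(frame = integer(0), empty_detections()) else out
}

#' Segment chromosome territories on max-intensity projections
#'
#' Difference-of-Gaussians band-pass on the per-frame maximum-intensity
#' projection, thresholded (Otsu on the DoG response by default), connected
#' components, and intensity-weighted centroids per region.
#'
#' @param stack a `timelapse_stack` or 4D array \code{[T, Z, Y, X]}.
#' @param channel channel name for a `timelapse_stack`.
#' @param dog_sigma_um c(narrow, wide) DoG sigmas in µm (narrow < wide).
#' @param threshold intensity threshold on the DoG response, or `NULL` for
#'   Otsu.
#' @param min_area_px discard regions smaller than this (default 4).
#' @param voxel_um voxel size c(z, y, x) µm.
#' @return data frame with `frame`, `region`, `x_um`, `y_um`, `area_px`.
#' @export
segment_territories <- function(stack, channel = "chromatin",
                                dog_sigma_um = c(0.3, 0.9),
                                threshold = NULL, min_area_px = 4L,
                                voxel_um = NULL) {
  if (dog_sigma_um[1] >= dog_sigma_um[2]) stop("dog narrow sigma must be < wide")
  if (inherits(stack, "timelapse_stack")) {
    arr <- stack[[channel]]
    if (is.null(voxel_um)) voxel_um <- stack$voxel_um
  } else arr <- stack
  if (is.null(voxel_um)) stop("voxel_um required")
  nt <- dim(arr)[1]
  sig_px <- dog_sigma_um / voxel_um[2]   # assume square pixels laterally
  out <- list()
  for (f in seq_len(nt)) {
    vol <- array(arr[f, , , , drop = FALSE], dim(arr)[-1])
    proj <- apply(vol, c(2, 3), max)
    dog <- smooth2d(proj, sig_px[1]) - smooth2d(proj, sig_px[2])
    thr <- if (is.null(threshold)) tryCatch(otsu_threshold(dog),
                                            error = function(e) Inf)
           else threshold
    mask <- dog > thr
    if (!any(mask)) next
    lab <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(mask),
                                                     nrow(mask), ncol(mask)))),
                  nrow(mask), ncol(mask))
    for (r in seq_len(max(lab))) {
      sel <- which(lab == r, arr.ind = TRUE)
      if (nrow(sel) < min_area_px) next
      wt <- proj[sel]
      cy <- sum(sel[, 1] * wt) / sum(wt)
      cx <- sum(sel[, 2] * wt) / sum(wt)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, region = r,
        x_um = (cx - 0.5) * voxel_um[3],
        y_um = (cy - 0.5) * voxel_um[2],
        area_px = nrow(sel))
    }
  }
  if (length(out) == 0) {
    warning("no territory region found in any frame")
    return(data.frame(frame = integer(0), region = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0)))
  }
  do.call(rbind, out)
}
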