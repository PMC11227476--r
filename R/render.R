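#' Configuration of a synthetic two-channel time-lapse scene
#'
#' Defines the rendering geometry, optics and noise of the synthetic
#' microscopy generator. Defaults emulate the acquisition the pipeline is
#' built for: 12 frames at 10 s intervals, 7 z-sections, voxel
#' 41 x 41 x 125 nm, and two resolution regimes — a SIM-like point spread
#' function (~120 nm lateral / ~300 nm axial FWHM) and a WF-like one
#' (~240 nm lateral / ~600 nm axial FWHM). Photon counts are not reported
#' for the emulated movies, so spot amplitude, background and noise are
#' exposed here rather than hard-coded; the defaults give a peak
#' signal-to-noise ratio of about 11, typical of reconstructed live-cell
#' data. Noise is Poisson on signal plus background followed by additive
#' Gaussian read noise (the standard sCMOS approximation).
#'
#' @param n_frames,n_z number of time points and z-sections.
#' @param ny,nx image height and width in pixels.
#' @param voxel_um voxel size, c(z, y, x) in µm.
#' @param dt frame interval (s).
#' @param regime `"sim"` or `"wf"` resolution regime.
#' @param psf_sigma list with per-regime Gaussian sigmas c(z, y, x) in µm.
#' @param spot_amplitude peak spot intensity (counts above background).
#' @param background background level (counts).
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param poisson_noise apply Poisson noise to signal + background?
#' @param nucleus_semiaxes_um nucleus ellipsoid semi-axes c(z, y, x), µm.
#' @param nucleus_intensity nucleus-channel plateau intensity (counts).
#' @param affine optional per-frame global affine series ([affine_series()]).
#' @param deformation optional [sinusoidal_deformation()].
#' @param spot_sigma_um optional explicit spot sigma c(z, y, x) in µm,
#'   overriding the PSF regime (used for extended territory blobs).
#' @param seed integer seed used when rendering noise.
#' @return an object of class `"scene_config"`.
#' @export
scene_config <- function(n_frames = 12L, n_z = 7L, ny = 256L, nx = 256L,
                         voxel_um = c(0.125, 0.041, 0.041), dt = 10,
                         regime = c("sim", "wf"),
                         psf_sigma = list(sim = c(0.127, 0.051, 0.051),
                                          wf  = c(0.255, 0.102, 0.102)),
                         spot_amplitude = 150, background = 20,
                         read_noise_sd = 2, poisson_noise = TRUE,
                         nucleus_semiaxes_um = c(1.5, 4.2, 4.8),
                         nucleus_intensity = 80,
                         affine = NULL, deformation = NULL,
                         spot_sigma_um = NULL, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(all(voxel_um > 0), n_frames >= 1, n_z >= 1)
  if (any(psf_sigma$wf <= psf_sigma$sim))
    stop("WF-like psf_sigma must exceed SIM-like psf_sigma on every axis")
  structure(list(n_frames = as.integer(n_frames), n_z = as.integer(n_z),
                 ny = as.integer(ny), nx = as.integer(nx),
                 voxel_um = voxel_um, dt = dt, regime = regime,
                 psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
                 background = background, read_noise_sd = read_noise_sd,
                 poisson_noise = poisson_noise,
                 nucleus_semiaxes_um = nucleus_semiaxes_um,
                 nucleus_intensity = nucleus_intensity,
                 affine = affine, deformation = deformation,
                 spot_sigma_um = spot_sigma_um, seed = as.integer(seed)),
            class = "scene_config")
}

## field center in µm, c(y, x)
scene_center <- function(config) {
  c(config$ny, config$nx) * config$voxel_um[2:3] / 2
}

## µm -> fractional voxel index (1-based, voxel centers at (i - 0.5) * size)
um_to_index <- function(pos_um, voxel_um) pos_um / voxel_um + 0.5

add_gaussian_spot <- function(vol, center_idx, sigma_idx, amplitude) {
  d <- dim(vol)
  r <- ceiling(4 * sigma_idx)
  lo <- pmax(1L, floor(center_idx - r))
  hi <- pmin(d, ceiling(center_idx + r))
  if (any(lo > hi)) return(vol)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- exp(-(zi - center_idx[1])^2 / (2 * sigma_idx[1]^2))
  gy <- exp(-(yi - center_idx[2])^2 / (2 * sigma_idx[2]^2))
  gx <- exp(-(xi - center_idx[3])^2 / (2 * sigma_idx[3]^2))
  spot <- amplitude * outer(gz, outer(gy, gx))
  sub <- array(vol[zi, yi, xi], dim(spot))
  vol[zi, yi, xi] <- sub + spot
  vol
}

## invert the per-frame global motion at image points (µm): find x0 with
## affine(x0) + deformation(affine(x0)) = x, by fixed-point iteration on the
## deformation followed by the exact affine inverse
invert_global_motion <- function(xy, affine_t, deformation, frame) {
  p <- xy
  if (!is.null(deformation)) {
    for (it in 1:3) p <- xy - eval_deformation(deformation, p, frame)
  }
  if (!is.null(affine_t)) {
    Ai <- solve(affine_t$A)
    p <- t(Ai %*% (t(p) - affine_t$b))
  }
  p
}

#' Render tracks as a two-channel synthetic time-lapse stack
#'
#' Produces a nucleus-marker channel (a textured ellipsoidal nucleus moved by
#' the configured global motion) and a chromatin channel with one
#' anisotropic Gaussian spot per track per frame at the globally moved true
#' position. Noise is applied last. The returned ground truth carries
#' everything needed to score registration, detection and tracking:
#' original and moved trajectories, the global-motion parameters, and flags
#' for spots clipped at the field of view.
#'
#' @param tracks a `chromo_tracks` data frame in nucleus coordinates
#'   (µm, origin at the field corner). 2D tracks are rendered at the axial
#'   mid-plane.
#' @param config a [scene_config()].
#' @return list with `nucleus` and `chromatin` arrays of dimension
#'   \code{[T, Z, Y, X]}, plus `truth` (ground-truth list) and `config`.
#' @export
render_timelapse <- function(tracks, config) {
  stopifnot(inherits(tracks, "chromo_tracks"), inherits(config, "scene_config"))
  set.seed(config$seed)
  nt <- config$n_frames; nz <- config$n_z; ny <- config$ny; nx <- config$nx
  vox <- config$voxel_um
  dims <- attr(tracks, "dims")
  moved <- apply_global_motion(tracks, config$affine, config$deformation)
  sigma_um <- if (!is.null(config$spot_sigma_um)) config$spot_sigma_um
              else config$psf_sigma[[config$regime]]
  sigma_idx <- sigma_um / vox
  zmid_um <- nz * vox[1] / 2

  nucleus <- array(0, c(nt, nz, ny, nx))
  chromatin <- array(0, c(nt, nz, ny, nx))
  ctr <- scene_center(config)
  semi <- config$nucleus_semiaxes_um

  ## nucleus template evaluated on the (inverse-moved) grid: smooth-edged
  ## ellipsoid with a fixed low-frequency internal texture that moves with it
  gy_um <- (seq_len(ny) - 0.5) * vox[2]
  gx_um <- (seq_len(nx) - 0.5) * vox[3]
  gz_um <- (seq_len(nz) - 0.5) * vox[1]
  grid_xy <- cbind(rep(gx_um, each = ny), rep(gy_um, nx))  # (x, y) µm
  nucleus_plane <- function(xy, z_um) {
    ## xy: n x 2 matrix (x, y) in nucleus coordinates
    q <- ((xy[, 1] - ctr[2]) / semi[3])^2 + ((xy[, 2] - ctr[1]) / semi[2])^2 +
         ((z_um - zmid_um) / semi[1])^2
    inside <- 1 / (1 + exp((q - 1) / 0.005))     # soft edge
    tex <- 1 + 0.35 * sin(2 * pi * xy[, 1] / 2.1) * sin(2 * pi * xy[, 2] / 1.7) +
           0.25 * sin(2 * pi * (xy[, 1] + xy[, 2]) / 3.3) +
           0.20 * sin(2 * pi * xy[, 1] / 0.9) * cos(2 * pi * xy[, 2] / 0.8) +
           0.15 * sin(2 * pi * xy[, 1] / 1.3 + 1.1) * sin(2 * pi * xy[, 2] / 1.15) +
           0.12 * cos(2 * pi * (xy[, 1] - 0.6 * xy[, 2]) / 0.75)
    config$nucleus_intensity * inside * tex
  }

  clipped <- logical(nrow(moved))
  for (f in seq_len(nt)) {
    aff_t <- if (!is.null(config$affine)) config$affine[[f]] else NULL
    xy0 <- invert_global_motion(grid_xy, aff_t, config$deformation, f)
    for (z in seq_len(nz)) {
      nucleus[f, z, , ] <- matrix(nucleus_plane(xy0, gz_um[z]), ny, nx)
    }
    idx <- which(moved$frame == f)
    vol <- array(chromatin[f, , , , drop = FALSE], c(nz, ny, nx))
    for (i in idx) {
      z_um <- if (dims == 3L) moved$z_um[i] else zmid_um
      ci <- c(um_to_index(z_um, vox[1]),
              um_to_index(moved$y_um[i], vox[2]),
              um_to_index(moved$x_um[i], vox[3]))
      if (ci[2] < 1 || ci[2] > ny || ci[3] < 1 || ci[3] > nx) clipped[i] <- TRUE
      vol <- add_gaussian_spot(vol, ci, sigma_idx, config$spot_amplitude)
    }
    chromatin[f, , , ] <- vol
  }

  nucleus <- nucleus + config$background
  chromatin <- chromatin + config$background
  if (config$poisson_noise) {
    nucleus[] <- stats::rpois(length(nucleus), pmax(nucleus, 0))
    chromatin[] <- stats::rpois(length(chromatin), pmax(chromatin, 0))
  }
  if (config$read_noise_sd > 0) {
    nucleus <- nucleus + stats::rnorm(length(nucleus), sd = config$read_noise_sd)
    chromatin <- chromatin + stats::rnorm(length(chromatin), sd = config$read_noise_sd)
  }

  truth <- list(tracks = attr(moved, "true_tracks"), moved_tracks = moved,
                affine = config$affine, deformation = config$deformation,
                clipped = clipped, seed = config$seed)
  structure(list(nucleus = nucleus, chromatin = chromatin,
                 voxel_um = vox, dt = config$dt,
                 truth = truth, config = config),
            class = "timelapse_stack")
}

#' Render a fixed-cell DNA-quantification scene
#'
#' Builds a DAPI-like total-DNA channel (ellipsoidal nucleus) plus a focus
#' channel marking labeled chromatin foci, constructed so that the summed
#' DAPI intensity inside focus i divided by the summed nuclear intensity
#' equals `focus_fractions[i]` exactly before noise. Used to validate the
#' DNA-per-focus quantification by construction.
#'
#' @param n_foci number of foci.
#' @param focus_fractions per-focus DNA fractions (all > 0, sum < 1);
#'   recycled to `n_foci`.
#' @param stage cell-cycle stage label (`"G1"`, `"eS"`, `"mS"`, `"lS"`,
#'   `"G2"`), stored in the ground truth.
#' @param voxel_um voxel size c(z, y, x) µm. The default is coarser than the
#'   live-imaging voxel because these are full-nucleus volumetric stacks.
#' @param nucleus_semiaxes_um nucleus semi-axes c(z, y, x) µm; the default
#'   encloses ~530 µm³.
#' @param focus_radius_um focus sphere radius (µm).
#' @param noise_sd additive Gaussian noise sd (0 for a noiseless scene).
#' @param seed integer seed.
#' @return list with `dapi` and `label` arrays \code{[Z, Y, X]}, `voxel_um`
#'   and a `truth` list (focus centers, fractions, stage).
#' @export
make_dna_scene <- function(n_foci, focus_fractions, stage = "mS",
                           voxel_um = c(0.25, 0.1, 0.1),
                           nucleus_semiaxes_um = c(3, 6, 7),
                           focus_radius_um = 0.35,
                           noise_sd = 0, seed = 1L) {
  focus_fractions <- rep_len(focus_fractions, n_foci)
  if (any(focus_fractions <= 0)) stop("focus fractions must be positive")
  if (sum(focus_fractions) >= 1) stop("focus fractions must sum to < 1")
  set.seed(seed)
  semi <- nucleus_semiaxes_um
  pad <- 4
  nz <- ceiling(2 * semi[1] / voxel_um[1]) + pad
  ny <- ceiling(2 * semi[2] / voxel_um[2]) + pad
  nx <- ceiling(2 * semi[3] / voxel_um[3]) + pad
  ctr <- c(nz, ny, nx) * voxel_um / 2

  gz <- (seq_len(nz) - 0.5) * voxel_um[1]
  gy <- (seq_len(ny) - 0.5) * voxel_um[2]
  gx <- (seq_len(nx) - 0.5) * voxel_um[3]
  qz <- ((gz - ctr[1]) / semi[1])^2
  qy <- ((gy - ctr[2]) / semi[2])^2
  qx <- ((gx - ctr[3]) / semi[3])^2
  inside <- outer(qz, outer(qy, qx, "+"), "+") <= 1

  ## place non-overlapping focus centers well inside the nucleus
  centers <- matrix(NA_real_, n_foci, 3)
  got <- 0L; tries <- 0L
  while (got < n_foci) {
    tries <- tries + 1L
    if (tries > 20000L) stop("could not place foci without overlap")
    p <- sample_ellipsoid(1, ctr, 0.7 * semi)
    if (got > 0 &&
        min(sqrt(colSums((t(centers[seq_len(got), , drop = FALSE]) - as.vector(p))^2))) <
        3.2 * focus_radius_um) next
    got <- got + 1L
    centers[got, ] <- p
  }

  focus_label <- array(0L, c(nz, ny, nx))
  for (i in seq_len(n_foci)) {
    q <- outer(((gz - centers[i, 1]) / focus_radius_um)^2,
               outer(((gy - centers[i, 2]) / focus_radius_um)^2,
                     ((gx - centers[i, 3]) / focus_radius_um)^2, "+"), "+")
    focus_label[q <= 1 & inside] <- i
  }

  ## solve per-focus intensities so sum-intensity ratios match exactly
  base <- 100
  v <- tabulate(focus_label[focus_label > 0L], n_foci)
  if (any(v == 0)) stop("a focus rendered with zero voxels; enlarge radius")
  V <- sum(inside)
  p <- focus_fractions
  total <- base * (V - sum(v)) / (1 - sum(p))
  amp <- p * total / v

  dapi <- array(0, c(nz, ny, nx))
  dapi[inside] <- base
  for (i in seq_len(n_foci)) dapi[focus_label == i] <- amp[i]
  label_ch <- array(0, c(nz, ny, nx))
  label_ch[focus_label > 0L] <- 200

  if (noise_sd > 0) {
    dapi <- dapi + stats::rnorm(length(dapi), sd = noise_sd)
    label_ch <- label_ch + stats::rnorm(length(label_ch), sd = noise_sd)
  }

  list(dapi = dapi, label = label_ch, voxel_um = voxel_um,
       truth = list(centers_um = centers, fractions = focus_fractions,
                    stage = stage, focus_label = focus_label,
                    nucleus_mask = inside))
}
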