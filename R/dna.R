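#' Cell-cycle correction factors and genome size
#'
#' Relative genome content per cell-cycle stage (G1 = 1 up to G2 = 1.98,
#' from flow-cytometry DNA profiles of the HeLa K line the pipeline was
#' built for) and the corresponding genome size in kbp. Used to convert
#' DAPI sum-intensity fractions into absolute DNA amounts.
#'
#' @return list with `C` (named vector of stage factors) and `GS_kbp`.
#' @export
cell_cycle_factors <- function() {
  list(C = c(G1 = 1, eS = 1.06, mS = 1.27, lS = 1.71, G2 = 1.98),
       GS_kbp = 9.682e6)
}

#' Segment the nucleus from a fixed-cell total-DNA stack
#'
#' Intensity threshold (Otsu by default) on the DAPI-like channel, holes
#' filled slice-wise, 3D connected components, objects smaller than
#' `min_volume_um3` discarded; the largest surviving object is the nucleus.
#'
#' @param dapi_stack 3D array \code{[Z, Y, X]}.
#' @param voxel_um voxel size c(z, y, x) µm.
#' @param threshold intensity threshold; `NULL` for Otsu.
#' @param min_volume_um3 minimum object volume (default 500 µm³).
#' @return list with `mask` (logical array), `volume_um3`, `sum_intensity`.
#' @export
segment_nucleus_3d <- function(dapi_stack, voxel_um, threshold = NULL,
                               min_volume_um3 = 500) {
  thr <- if (is.null(threshold)) otsu_threshold(dapi_stack) else threshold
  mask <- dapi_stack > thr
  d <- dim(mask)
  for (z in seq_len(d[1])) {
    filled <- EBImage::fillHull(matrix(as.numeric(mask[z, , ]), d[2], d[3]))
    mask[z, , ] <- filled > 0
  }
  lab <- label3d(mask)
  if (max(lab) == 0) stop("no object found above threshold")
  vol_vox <- tabulate(lab[lab > 0L])
  vol_um3 <- vol_vox * prod(voxel_um)
  keep <- which(vol_um3 >= min_volume_um3)
  if (length(keep) == 0)
    stop(sprintf("no object of at least %g um^3 (largest: %.1f um^3)",
                 min_volume_um3, max(vol_um3)))
  nuc <- keep[which.max(vol_um3[keep])]
  m <- lab == nuc
  list(mask = m, volume_um3 = vol_um3[nuc],
       sum_intensity = sum(dapi_stack[m]))
}

## split a labeled component at the local maxima of its (anisotropic)
## distance transform: each foreground voxel goes to the nearest seed.
## Seeds must reach at least `rel_height` of the component's inradius and
## be separated by at least that inradius, which suppresses the ridge and
## digitization maxima a raw distance transform produces.
split_touching <- function(mask, voxel_um, rel_height = 0.6) {
  lab <- label3d(mask)
  n0 <- max(lab)
  if (n0 == 0) return(lab)
  dtm <- distance_transform3d(mask, voxel_um)
  out <- array(0L, dim(mask))
  next_lab <- 0L
  for (cc in seq_len(n0)) {
    sel <- lab == cc
    dloc <- array(0, dim(mask)); dloc[sel] <- dtm[sel]
    inradius <- max(dloc)
    mx <- local_maxima3d(dloc, threshold = rel_height * inradius)
    if (nrow(mx) > 1) {
      ## plateau maxima form connected clumps: collapse each clump to its
      ## centroid before treating it as a candidate seed
      mmask <- array(FALSE, dim(mask)); mmask[mx] <- TRUE
      mlab <- label3d(mmask)
      mx <- do.call(rbind, lapply(seq_len(max(mlab)), function(g) {
        vv <- which(mlab == g, arr.ind = TRUE)
        round(colMeans(vv))
      }))
    }
    if (nrow(mx) > 1) {
      ## strongest seed first; drop seeds within one inradius of a survivor
      vals <- dloc[mx]
      mx <- mx[order(-vals), , drop = FALSE]
      pos <- sweep(mx[, c(1, 2, 3), drop = FALSE], 2L, voxel_um, "*")
      keep <- rep(TRUE, nrow(pos))
      for (i in seq_len(nrow(pos) - 1)) {
        if (!keep[i]) next
        for (j in (i + 1):nrow(pos)) {
          if (keep[j] && sqrt(sum((pos[i, ] - pos[j, ])^2)) < inradius)
            keep[j] <- FALSE
        }
      }
      mx <- mx[keep, , drop = FALSE]
    }
    vox <- which(sel, arr.ind = TRUE)
    if (nrow(mx) <= 1) {
      next_lab <- next_lab + 1L
      out[sel] <- next_lab
    } else {
      seeds_um <- sweep(mx, 2L, voxel_um, "*")
      vox_um <- sweep(vox, 2L, voxel_um, "*")
      d2 <- outer(rowSums(vox_um^2), rowSums(seeds_um^2), "+") -
            2 * vox_um %*% t(seeds_um)
      nearest <- max.col(-d2, ties.method = "first")
      out[vox] <- next_lab + nearest
      next_lab <- next_lab + nrow(mx)
    }
  }
  out
}

#' Segment labeled chromatin foci inside the nucleus
#'
#' Triangle auto-threshold on the full-stack histogram of the focus
#' channel; the binary mask is combined with the original image by
#' voxel-wise minimum (so original intensities survive only inside the
#' mask), connected components are extracted, touching objects are split at
#' the local maxima of the distance transform, and foci not touching the
#' nucleus are discarded.
#'
#' @param label_stack 3D focus-channel array \code{[Z, Y, X]}.
#' @param nucleus result of [segment_nucleus_3d()].
#' @param voxel_um voxel size c(z, y, x) µm.
#' @param threshold threshold override; `NULL` for triangle.
#' @param min_voxels discard components smaller than this (default 20: at
#'   the intended sampling a diffraction-limited focus spans hundreds of
#'   voxels, while suprathreshold noise clusters stay below ~15 voxels;
#'   lower it when working at coarser voxel sizes).
#' @return list with `labels` (integer array, 0 = background) and `n_foci`;
#'   warns and returns zero foci when nothing is above threshold.
#' @export
segment_foci <- function(label_stack, nucleus, voxel_um, threshold = NULL,
                         min_voxels = 20L) {
  thr <- if (is.null(threshold)) triangle_threshold(label_stack, tail = "upper")
         else threshold
  masked <- ifelse(label_stack > thr, label_stack, 0)
  mask <- masked > 0
  if (!any(mask)) {
    warning("no focus above triangle threshold")
    return(list(labels = array(0L, dim(label_stack)), n_foci = 0L))
  }
  labs <- split_touching(mask, voxel_um)
  ## drop sub-minimum components and foci with no voxel touching the nucleus
  sizes <- tabulate(labs[labs > 0L])
  keep <- sort(unique(labs[labs > 0L & nucleus$mask]))
  keep <- keep[sizes[keep] >= min_voxels]
  relab <- integer(max(labs))
  relab[keep] <- seq_along(keep)
  pos <- labs > 0L
  labs[pos] <- relab[labs[pos]]
  list(labels = labs, n_foci = length(keep))
}

#' Quantify DNA content (kbp) per labeled chromatin focus
#'
#' For each focus, the total-DNA (DAPI) sum intensity inside the focus
#' divided by the nuclear total gives the DNA fraction; multiplying by the
#' cell-cycle correction factor C of the annotated stage and the genome
#' size GS converts it to kbp. A histogram summary reports the mode bin
#' ± 5 bins and the median.
#'
#' @param foci result of [segment_foci()].
#' @param nucleus result of [segment_nucleus_3d()].
#' @param dapi_stack the total-DNA channel \code{[Z, Y, X]}.
#' @param stage one of `"G1"`, `"eS"`, `"mS"`, `"lS"`, `"G2"`.
#' @param voxel_um voxel size c(z, y, x) µm.
#' @param factors [cell_cycle_factors()] (override for other cell lines).
#' @param bin_width_kbp histogram bin width (default 10 kbp).
#' @return list with `records` (per-focus data frame: voxel count, volume,
#'   sum intensities, ratio, `dna_kbp`, validity flag) and `histogram`
#'   (`mode_kbp`, `mode_range_kbp` = mode ± 5 bins, `median_kbp`,
#'   `bin_width_kbp`).
#' @export
quantify_focus_dna <- function(foci, nucleus, dapi_stack, stage,
                               voxel_um, factors = cell_cycle_factors(),
                               bin_width_kbp = 10) {
  if (!stage %in% names(factors$C)) stop("unknown cell-cycle stage: ", stage)
  C <- factors$C[[stage]]
  GS <- factors$GS_kbp
  total <- nucleus$sum_intensity
  recs <- lapply(seq_len(foci$n_foci), function(i) {
    sel <- foci$labels == i
    nvox <- sum(sel)
    si <- sum(dapi_stack[sel])
    ratio <- si / total
    data.frame(focus = i, n_voxels = nvox,
               volume_um3 = nvox * prod(voxel_um),
               sum_intensity = si, ratio = ratio,
               dna_kbp = ratio * C * GS,
               valid = ratio > 0 & ratio < 1)
  })
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(focus = integer(0), n_voxels = integer(0),
               volume_um3 = numeric(0), sum_intensity = numeric(0),
               ratio = numeric(0), dna_kbp = numeric(0), valid = logical(0))
  hist_summary <- NULL
  v <- records$dna_kbp[records$valid]
  if (length(v) > 0) {
    bins <- floor(v / bin_width_kbp)
    tab <- table(bins)
    mode_bin <- as.numeric(names(tab)[which.max(tab)])
    mode_kbp <- (mode_bin + 0.5) * bin_width_kbp
    hist_summary <- list(mode_kbp = mode_kbp,
                         mode_range_kbp = mode_kbp + c(-5, 5) * bin_width_kbp,
                         median_kbp = stats::median(v),
                         bin_width_kbp = bin_width_kbp)
  }
  list(records = records, histogram = hist_summary,
       stage = stage, C = C, GS_kbp = GS)
}

#' Fraction of objects in A overlapping objects in B
#'
#' An object of set A counts as overlapping when at least one of its voxels
#' intersects any object of B. Used for double-pulse colocalization.
#'
#' @param labels_a,labels_b integer label arrays of the same dimension
#'   (0 = background).
#' @return percentage (0–100) of A objects overlapping B, or `NA` with a
#'   flag attribute when A is empty.
#' @export
colocalization_fraction <- function(labels_a, labels_b) {
  stopifnot(all(dim(labels_a) == dim(labels_b)))
  ids <- sort(unique(labels_a[labels_a > 0L]))
  if (length(ids) == 0) {
    out <- NA_real_
    attr(out, "flag") <- "no_objects_in_A"
    return(out)
  }
  overl <- vapply(ids, function(i) any(labels_b[labels_a == i] > 0L), logical(1))
  100 * sum(overl) / length(ids)
}

#' Convert combed DNA fiber lengths to kbp
#'
#' @param lengths_um fiber lengths in µm (all > 0).
#' @param stretching_kbp_per_um stretching factor (default 2 kbp/µm, the
#'   lambda-DNA calibration of molecular combing).
#' @return lengths in kbp.
#' @export
combing_convert <- function(lengths_um, stretching_kbp_per_um = 2.0) {
  if (any(lengths_um <= 0)) stop("fiber lengths must be positive")
  lengths_um * stretching_kbp_per_um
}

#' Calibrate the combing stretching factor from lambda-DNA fibers
#'
#' Bacteriophage lambda DNA is 48.5 kbp; the stretching factor is
#' 48.5 / mean(measured fiber length in µm).
#'
#' @param measured_lambda_lengths_um measured lambda fiber lengths (µm).
#' @return stretching factor in kbp/µm.
#' @export
combing_calibrate <- function(measured_lambda_lengths_um) {
  if (any(measured_lambda_lengths_um <= 0)) stop("fiber lengths must be positive")
  48.5 / mean(measured_lambda_lengths_um)
}
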