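#' Segment the nucleus from a 2D nucleus-channel image
#'
#' Otsu threshold on the (max-projected) nucleus channel, keeping the
#' largest connected component with holes filled.
#'
#' @param frame 2D matrix (e.g. max-intensity projection of the nucleus
#'   channel).
#' @return logical mask matrix.
#' @export
segment_nucleus <- function(frame) {
  thr <- otsu_threshold(frame)
  mask <- frame > thr
  if (!any(mask)) stop("empty nucleus mask after thresholding")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(frame), ncol(frame)))
  lab <- matrix(as.integer(lab), nrow(frame), ncol(frame))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  filled <- EBImage::fillHull(matrix(as.numeric(mask), nrow(frame), ncol(frame)))
  matrix(filled > 0, nrow(frame), ncol(frame))
}

#' Convex hull by gift wrapping (Jarvis–March)
#'
#' @param pts n x 2 matrix of (x, y) points.
#' @return m x 2 matrix of hull vertices in counter-clockwise order.
#' @export
jarvis_march <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) stop("degenerate hull: need at least 3 distinct points")
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])  # leftmost, lowest tie-break
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1L) (seq_len(n))[-cur] else seq_len(n)[-cur]
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) > sum((pts[nxt, ] - pts[cur, ])^2)))
        nxt <- j
    }
    if (nxt == start) break
    cur <- nxt
    if (length(hull) > n) stop("gift wrapping failed to terminate")
  }
  pts[hull, , drop = FALSE]
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * A)
}

point_in_polygon <- function(px, py, poly) {
  ## even-odd ray casting, vectorized over points
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Partition a nucleus mask into N nested equal-area shells
#'
#' Computes the convex hull of the mask contour by gift wrapping
#' (Jarvis–March), then scales the hull polygon about its area centroid by
#' factors sqrt(i/N) to obtain N nested polygons; the ring between
#' consecutive polygons encloses exactly 1/N of the hull area (the area
#' scaling law is the unique choice that makes the rings equal). Shell 1 is
#' the outermost ring, shell N the innermost polygon.
#'
#' @param mask logical matrix (nucleus mask) or an n x 2 matrix of contour
#'   points in µm.
#' @param N number of shells (default 7).
#' @param voxel_um pixel size c(y, x) in µm when `mask` is a matrix image.
#' @return object of class `"shell_partition"`: list with `polygons`
#'   (inner to outer, each m x 2 in µm), `N`, `centroid`, `hull_area`.
#' @export
make_shells <- function(mask, N = 7L, voxel_um = c(1, 1)) {
  if (is.logical(mask) || (is.matrix(mask) && ncol(mask) != 2)) {
    if (!any(mask)) stop("empty mask")
    idx <- which(mask, arr.ind = TRUE)           # (row=y, col=x)
    pts <- cbind((idx[, 2] - 0.5) * voxel_um[2], # x µm
                 (idx[, 1] - 0.5) * voxel_um[1]) # y µm
    ## contour points only: boundary of the mask (cheap erosion test)
    er <- mask
    er[] <- mask &
      shift_arr(mask, c(1, 0)) & shift_arr(mask, c(-1, 0)) &
      shift_arr(mask, c(0, 1)) & shift_arr(mask, c(0, -1))
    border <- mask & !er
    if (sum(border) >= 3) {
      idx <- which(border, arr.ind = TRUE)
      pts <- cbind((idx[, 2] - 0.5) * voxel_um[2], (idx[, 1] - 0.5) * voxel_um[1])
    }
  } else pts <- mask
  hull <- jarvis_march(pts)
  ctr <- polygon_centroid(hull)
  polys <- lapply(seq_len(N), function(i) {
    s <- sqrt(i / N)
    sweep(sweep(hull, 2L, ctr) * s, 2L, ctr, "+")
  })
  structure(list(polygons = polys, N = as.integer(N), centroid = ctr,
                 hull_area = polygon_area(hull)),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat("Equal-area shell partition: N =", x$N,
      "| hull area =", format(x$hull_area, digits = 4),
      "| centroid =", paste(round(x$centroid, 2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.shell_partition <- function(x, ...) {
  all_pts <- do.call(rbind, x$polygons)
  graphics::plot(NA, xlim = range(all_pts[, 1]), ylim = range(all_pts[, 2]),
                 xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  for (p in rev(x$polygons)) graphics::polygon(p[, 1], p[, 2], border = "gray30")
  graphics::points(x$centroid[1], x$centroid[2], pch = 3)
  invisible(x)
}

## ring index (1 = outermost) of points; outside the hull counts as ring 1
shell_ring_of_points <- function(partition, px, py) {
  N <- partition$N
  ring <- rep(1L, length(px))               # default: outside hull -> shell 1
  ## innermost polygon containing the point determines the ring
  containment <- matrix(FALSE, length(px), N)
  for (i in seq_len(N)) {
    containment[, i] <- point_in_polygon(px, py, partition$polygons[[i]])
  }
  inner_most <- apply(containment, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
  inside <- !is.na(inner_most)
  ring[inside] <- N - inner_most[inside] + 1L
  ring
}

#' Assign trajectories to nuclear shells
#'
#' Each trajectory is assigned to the shell containing the majority of its
#' points (x–y positions; z is ignored, matching the 2D shell
#' construction). Points outside the hull count toward shell 1, and
#' majority ties are broken toward the outer shell.
#'
#' @param tracks a `chromo_tracks` data frame.
#' @param partition a [make_shells()] partition in the same µm frame.
#' @return named integer vector: shell index (1 = outermost) per track.
#' @export
assign_tracks <- function(tracks, partition) {
  stopifnot(inherits(partition, "shell_partition"))
  ring <- shell_ring_of_points(partition, tracks$x_um, tracks$y_um)
  vapply(split(ring, tracks$track_id), function(r) {
    tab <- table(r)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)                               # tie -> outer (smaller index)
  }, integer(1))
}

#' Per-shell motion statistics and outer-vs-inner significance tests
#'
#' Summarizes per-track motion properties (and per-track alpha, when
#' supplied) within each shell, and tests shell 1 (outermost) against every
#' other shell with a two-sided Wilcoxon rank-sum test per property.
#'
#' @param properties data frame from [motion_properties()], optionally with
#'   an `alpha` column merged in.
#' @param shell_of_track named shell assignment from [assign_tracks()].
#' @param N number of shells.
#' @return list with `summary` (per-shell mean/median per property and
#'   track counts) and `tests` (shell-1-vs-shell p-values; NA where a group
#'   has fewer than 2 tracks).
#' @export
per_shell_stats <- function(properties, shell_of_track, N = max(shell_of_track)) {
  shells <- shell_of_track[match(as.character(properties$track_id),
                                 names(shell_of_track))]
  if (anyNA(shells)) stop("every track in properties needs a shell assignment")
  vars <- intersect(c("rg_um", "mean_velocity_um_s", "dist_start_end_um",
                      "straightness", "alpha"), names(properties))
  summ <- do.call(rbind, lapply(seq_len(N), function(s) {
    sub <- properties[shells == s, , drop = FALSE]
    row <- data.frame(shell = s, n_tracks = nrow(sub))
    for (v in vars) {
      row[[paste0("mean_", v)]] <- if (nrow(sub)) mean(sub[[v]]) else NA_real_
      row[[paste0("median_", v)]] <- if (nrow(sub)) stats::median(sub[[v]]) else NA_real_
    }
    row
  }))
  tests <- NULL
  if (N >= 2 && sum(shells == 1) >= 2) {
    tests <- do.call(rbind, lapply(2:N, function(s) {
      row <- data.frame(shell = s)
      for (v in vars) {
        a <- properties[[v]][shells == 1]
        b <- properties[[v]][shells == s]
        row[[paste0("p_", v)]] <- if (length(b) >= 2) compare_groups(a, b) else NA_real_
      }
      row
    }))
  }
  list(summary = summ, tests = tests)
}
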