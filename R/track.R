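## O(n^3) Hungarian assignment (shortest augmenting path with potentials,
## Jonker-Volgenant style). Returns, for each row, the assigned column.
## Written here because no linear-assignment solver ships with the
## pre-declared dependencies; validated against a brute-force permutation
## oracle in the test suite.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n == m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)         # p[j]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                  # columns are 1-based with a virtual col 1 slot
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(m + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  assign
}

## square-pad a rectangular cost matrix with `pad` and solve; returns
## row -> col assignment with 0 for rows matched to padding
assign_gated <- function(cost, pad) {
  n <- nrow(cost); m <- ncol(cost)
  k <- max(n, m)
  full <- matrix(pad, k, k)
  full[seq_len(n), seq_len(m)] <- cost
  a <- hungarian(full)
  a <- a[seq_len(n)]
  a[a > m] <- 0L
  a
}

new_kalman <- function(pos, dt = 1) {
  ## per-axis constant-velocity Kalman filter; units: position in µm,
  ## velocity in µm/frame (dt folded into F)
  d <- length(pos)
  list(p = pos, v = rep(0, d),
       Pp = rep(0.01, d), Pv = rep(0.05, d), Ppv = rep(0, d),
       q = 1e-4, r = 1e-4)
}

kalman_predict <- function(kf) {
  kf$p <- kf$p + kf$v
  kf$Pp <- kf$Pp + 2 * kf$Ppv + kf$Pv + kf$q
  kf$Ppv <- kf$Ppv + kf$Pv
  kf$Pv <- kf$Pv + kf$q
  kf
}

kalman_update <- function(kf, z) {
  S <- kf$Pp + kf$r
  Kp <- kf$Pp / S; Kv <- kf$Ppv / S
  innov <- z - kf$p
  kf$p <- kf$p + Kp * innov
  kf$v <- kf$v + Kv * innov
  Pp <- (1 - Kp) * kf$Pp
  Ppv <- (1 - Kp) * kf$Ppv
  Pv <- kf$Pv - Kv * kf$Ppv
  kf$Pp <- Pp; kf$Ppv <- Ppv; kf$Pv <- Pv
  kf
}

#' Link per-frame detections into 3D trajectories
#'
#' Motion-predictive global linking: each live track carries a per-axis
#' constant-velocity Kalman state (position + velocity); the frame-to-frame
#' correspondence is solved as an optimal one-to-one assignment on the
#' distance between each track's prediction and the candidate detections,
#' with assignments beyond `gate_um` forbidden. Unmatched detections seed
#' new tracks; a track coasts (prediction only) through up to `max_gap`
#' missed frames before it is terminated. Ties are deterministic (smaller
#' detection index wins).
#'
#' @param detections data frame with `frame`, `x_um`, `y_um` and optionally
#'   `z_um` (from [detect_sequence()]).
#' @param gate_um gating radius in µm (> 0).
#' @param max_gap maximum number of consecutive missed frames (default 1).
#' @param dt frame interval in seconds (stored on the output).
#' @return a `chromo_tracks` data frame.
#' @export
track_foci <- function(detections, gate_um = 0.5, max_gap = 1L, dt = 10) {
  if (gate_um <= 0) stop("gate_um must be positive")
  dims <- if ("z_um" %in% names(detections) && !all(is.na(detections$z_um))) 3L else 2L
  cols <- track_coord_cols(dims)
  if (nrow(detections) == 0)
    return(as_chromo_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                       x_um = numeric(0), y_um = numeric(0),
                                       z_um = numeric(0))[c("track_id", "frame", cols)],
                            dt = dt, dims = dims))
  frames <- sort(unique(detections$frame))
  tracks <- list()   # each: list(id, kf, last_frame, rows=list of (frame, pos))
  done <- list()
  next_id <- 1L
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    det <- det[order(det$x_um, det$y_um), , drop = FALSE]   # deterministic order
    P <- as.matrix(det[, cols, drop = FALSE])
    nd <- nrow(P)
    ## predict all live tracks to this frame
    live <- which(vapply(tracks, function(tr) f - tr$last_frame <= max_gap + 1L,
                         logical(1)))
    if (length(live) > 0) {
      for (ti in live) tracks[[ti]]$kf <- kalman_predict(tracks[[ti]]$kf)
      pred <- t(vapply(tracks[live], function(tr) tr$kf$p, numeric(dims)))
      cost <- sqrt(outer(rowSums(pred^2), rowSums(P^2), "+") -
                   2 * pred %*% t(P))
      cost[!is.finite(cost)] <- 0
      cost[cost > gate_um] <- 10 * gate_um
      a <- assign_gated(cost, pad = gate_um)
      matched_det <- logical(nd)
      for (ii in seq_along(live)) {
        j <- a[ii]
        ti <- live[ii]
        if (j > 0 && cost[ii, j] <= gate_um) {
          tracks[[ti]]$kf <- kalman_update(tracks[[ti]]$kf, P[j, ])
          tracks[[ti]]$last_frame <- f
          tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1L]] <-
            c(f, P[j, ])
          matched_det[j] <- TRUE
        }
      }
    } else matched_det <- logical(nd)
    ## retire tracks that exceeded the gap
    if (length(tracks) > 0) {
      dead <- which(vapply(tracks, function(tr) f - tr$last_frame > max_gap,
                           logical(1)))
      if (length(dead) > 0) {
        done <- c(done, tracks[dead])
        tracks <- tracks[-dead]
      }
    }
    ## seed new tracks from unmatched detections
    for (j in which(!matched_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, kf = new_kalman(P[j, ]), last_frame = f,
        rows = list(c(f, P[j, ])))
      next_id <- next_id + 1L
    }
  }
  done <- c(done, tracks)
  rows <- do.call(rbind, lapply(done, function(tr) {
    m <- do.call(rbind, tr$rows)
    cbind(tr$id, m)
  }))
  out <- as.data.frame(rows)
  names(out) <- c("track_id", "frame", cols)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  as_chromo_tracks(out, dt = dt, dims = dims)
}

#' Link territory centroids by mutual nearest neighbor
#'
#' Greedy mutual nearest-neighbor association with a gate: a link is made
#' when a territory in frame t and one in frame t+1 are each other's
#' nearest neighbors within `gate_um`. Territories that fail matching end
#' their track; unmatched centroids start new tracks.
#'
#' @param centroids data frame with `frame`, `x_um`, `y_um` (from
#'   [segment_territories()]).
#' @param gate_um gating radius (µm).
#' @param dt frame interval (s).
#' @return a 2D `chromo_tracks` data frame.
#' @export
track_territories <- function(centroids, gate_um = 1, dt = 10) {
  if (nrow(centroids) == 0)
    return(as_chromo_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                       x_um = numeric(0), y_um = numeric(0)),
                            dt = dt, dims = 2L))
  frames <- sort(unique(centroids$frame))
  cent_by_frame <- lapply(frames, function(f)
    as.matrix(centroids[centroids$frame == f, c("x_um", "y_um"), drop = FALSE]))
  ids_by_frame <- vector("list", length(frames))
  next_id <- 1L
  ids_by_frame[[1]] <- seq_len(nrow(cent_by_frame[[1]]))
  next_id <- nrow(cent_by_frame[[1]]) + 1L
  if (length(frames) >= 2) for (fi in 2:length(frames)) {
    A <- cent_by_frame[[fi - 1]]; B <- cent_by_frame[[fi]]
    idB <- integer(nrow(B))
    if (nrow(A) > 0 && nrow(B) > 0 && frames[fi] - frames[fi - 1] == 1) {
      D <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
      nnA <- apply(D, 1, which.min)   # nearest B for each A
      nnB <- apply(D, 2, which.min)   # nearest A for each B
      for (j in seq_len(nrow(B))) {
        i <- nnB[j]
        if (nnA[i] == j && D[i, j] <= gate_um) idB[j] <- ids_by_frame[[fi - 1]][i]
      }
    }
    for (j in which(idB == 0L)) { idB[j] <- next_id; next_id <- next_id + 1L }
    ids_by_frame[[fi]] <- idB
  }
  out <- do.call(rbind, lapply(seq_along(frames), function(fi) {
    B <- cent_by_frame[[fi]]
    if (nrow(B) == 0) return(NULL)
    data.frame(track_id = ids_by_frame[[fi]], frame = frames[fi],
               x_um = B[, 1], y_um = B[, 2])
  }))
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  as_chromo_tracks(out, dt = dt, dims = 2L)
}

#' Minimum-duration track filter
#'
#' Keeps only trajectories spanning at least `min_steps` inter-frame steps
#' (i.e. `min_steps + 1` points for gap-free tracks); with the default 4
#' steps at a 10 s frame interval this is the 40 s minimum duration used
#' throughout the motion analysis.
#'
#' @param tracks a `chromo_tracks` data frame.
#' @param min_steps minimum number of steps (default 4).
#' @return filtered `chromo_tracks`.
#' @export
filter_tracks <- function(tracks, min_steps = 4L) {
  if (nrow(tracks) == 0) return(tracks)
  span <- tapply(tracks$frame, tracks$track_id,
                 function(f) max(f) - min(f))
  keep_ids <- names(span)[span >= min_steps]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  as_chromo_tracks(out, dt = attr(tracks, "dt"), dims = attr(tracks, "dims"))
}
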