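## Shared fixture builders: everything is generated in code at test time.

## small 3D scene with n immobile or moving spots well inside the field
spot_scene <- function(n_spots = 10, model = "immobile", D = 8.32e-5,
                       n_frames = 3, ny = 128, nx = 128, seed = 1,
                       noiseless = FALSE, amplitude = 150, affine = NULL,
                       deformation = NULL) {
  sc <- scene_config(n_frames = n_frames, ny = ny, nx = nx,
                     spot_amplitude = amplitude,
                     poisson_noise = !noiseless,
                     read_noise_sd = if (noiseless) 0 else 2,
                     background = if (noiseless) 0 else 20,
                     affine = affine, deformation = deformation,
                     seed = seed)
  sp <- motion_spec(model, D = D, dims = 3, dt = 10,
                    n_frames = max(n_frames, 2L))
  region <- list(center = c(nx * 0.041 / 2, ny * 0.041 / 2, 7 * 0.125 / 2),
                 semiaxes = c(0.36 * nx * 0.041, 0.33 * ny * 0.041, 0.25))
  tracks <- simulate_tracks(sp, n_spots, start_region = region,
                            seed = seed + 1)
  list(tracks = tracks, stack = render_timelapse(tracks, sc), config = sc)
}

## nucleus-channel projection of a small rendered scene; the nucleus is
## shrunk so it fits the reduced field with margin
nucleus_projection <- function(ny = 160, nx = 160, seed = 5,
                               semiaxes = c(1.5, 2.6, 3.0)) {
  sc <- scene_config(n_frames = 1, ny = ny, nx = nx,
                     nucleus_semiaxes_um = semiaxes, seed = seed)
  off <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1, x_um = -5, y_um = -5, z_um = 0.4),
    dt = 10, dims = 3)
  r <- render_timelapse(off, sc)
  apply(array(r$nucleus[1, , , , drop = FALSE], dim(r$nucleus)[-1]),
        c(2, 3), max)
}

## random convex mask: filled convex hull of random points, as polygon pts
random_convex_polygon <- function(n_pts = 12, seed = 1) {
  set.seed(seed)
  th <- sort(runif(n_pts, 0, 2 * pi))
  r <- runif(n_pts, 3, 8)
  cbind(10 + r * cos(th), 10 + r * sin(th))
}

## brute-force two-sided rank-sum p-value by full enumeration (distinct
## values assumed): reference oracle for compare_groups
enumerate_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(n1 + n2, n1), 2L,
                 function(idx) sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
}

## greedy nearest-neighbor linker (contrast oracle for the Kalman tracker)
greedy_nn_link <- function(detections, gate) {
  frames <- sort(unique(detections$frame))
  prev <- detections[detections$frame == frames[1], ]
  prev$id <- seq_len(nrow(prev))
  out <- list(prev)
  nid <- nrow(prev) + 1L
  for (f in frames[-1]) {
    cur <- detections[detections$frame == f, ]
    cur$id <- NA_integer_
    taken <- logical(nrow(cur))
    for (i in seq_len(nrow(prev))) {
      d <- sqrt((cur$x_um - prev$x_um[i])^2 + (cur$y_um - prev$y_um[i])^2)
      d[taken] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= gate) { cur$id[j] <- prev$id[i]; taken[j] <- TRUE }
    }
    for (j in which(is.na(cur$id))) { cur$id[j] <- nid; nid <- nid + 1L }
    out[[length(out) + 1L]] <- cur
    prev <- cur
  }
  do.call(rbind, out)
}

## fraction of frame-to-frame links agreeing with ground-truth identity
link_purity <- function(tracks, truth_of_detection) {
  ok <- 0L; tot <- 0L
  for (id in unique(tracks$track_id)) {
    sub <- tracks[tracks$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    if (nrow(sub) < 2) next
    tru <- truth_of_detection[match(
      paste(sub$frame, round(sub$x_um, 6), round(sub$y_um, 6)),
      names(truth_of_detection))]
    tot <- tot + (nrow(sub) - 1L)
    ok <- ok + sum(tru[-1] == tru[-length(tru)], na.rm = TRUE)
  }
  ok / tot
}
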