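test_that("the assignment solver matches brute-force enumeration", {
  hung <- chromomotion:::hungarian
  brute <- function(cost) {
    n <- nrow(cost)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (p in perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    best <- Inf; bp <- NULL
    for (p in perms(seq_len(n))) {
      s <- sum(cost[cbind(seq_len(n), p)])
      if (s < best) { best <- s; bp <- p }
    }
    list(cost = best, p = bp)
  }
  set.seed(50)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- hung(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), brute(cost)$cost,
                 tolerance = 1e-12)
  }
})

test_that("well-separated constant-velocity spots link into full tracks", {
  det <- do.call(rbind, lapply(1:12, function(f) {
    data.frame(frame = f,
               x_um = c(1 + 0.05 * (f - 1), 6 - 0.04 * (f - 1)),
               y_um = c(1, 6), z_um = 0.4)
  }))
  tk <- track_foci(det, gate_um = 0.5, dt = 10)
  expect_equal(length(unique(tk$track_id)), 2L)
  expect_true(all(table(tk$track_id) == 12))
  ## no identity switch: y stays constant within each track
  expect_true(all(tapply(tk$y_um, tk$track_id, function(v) diff(range(v))) == 0))
})

test_that("velocity-predictive linking resolves crossings that defeat nearest neighbor", {
  ## two tracks crossing at frame 6-7 with distinct constant velocities
  det <- do.call(rbind, lapply(1:12, function(f) {
    data.frame(frame = f,
               x_um = c(0 + 1.0 * (f - 1), 11 - 1.0 * (f - 1)),
               y_um = c(0, 0.3), z_um = 0)
  }))
  tk <- track_foci(det, gate_um = 2, dt = 10)
  expect_equal(length(unique(tk$track_id)), 2L)
  switches_kalman <- sum(vapply(split(tk, tk$track_id), function(s)
    diff(range(s$y_um)) > 0, logical(1)))
  expect_equal(switches_kalman, 0L)
  nn <- greedy_nn_link(det, gate = 2)
  switches_nn <- sum(vapply(split(nn, nn$id), function(s)
    diff(range(s$y_um)) > 0, logical(1)))
  expect_gte(switches_nn, 1L)
})

test_that("linking purity exceeds 0.95 on 1000 noisy Brownian tracks", {
  sp <- motion_spec("brownian", D = 8.32e-5, dims = 3, dt = 10, n_frames = 12)
  ## spots spread over a wide field so density matches a nucleus population
  set.seed(52)
  tr <- simulate_tracks(sp, 1000, seed = 52)
  tr$x_um <- tr$x_um + rep(runif(1000, 0, 60), each = 12)
  tr$y_um <- tr$y_um + rep(runif(1000, 0, 60), each = 12)
  tr$z_um <- tr$z_um + rep(runif(1000, 0.2, 0.7), each = 12)
  ## detection = truth + localization noise at the default-SNR level
  noise <- 0.015
  det <- data.frame(frame = tr$frame,
                    x_um = tr$x_um + rnorm(nrow(tr), sd = noise),
                    y_um = tr$y_um + rnorm(nrow(tr), sd = noise),
                    z_um = tr$z_um + rnorm(nrow(tr), sd = noise * 2))
  truth <- setNames(tr$track_id,
                    paste(det$frame, round(det$x_um, 6), round(det$y_um, 6)))
  tk <- track_foci(det, gate_um = 0.5, dt = 10)
  expect_gte(link_purity(tk, truth), 0.95)
  ## invariants: one detection per track per frame; total points bounded
  expect_false(any(duplicated(tk[, c("track_id", "frame")])))
  expect_lte(nrow(tk), nrow(det))
})

test_that("immobile scenes never produce large within-track displacements", {
  sp <- motion_spec("immobile", dims = 3, dt = 10, n_frames = 8)
  tr <- simulate_tracks(sp, 50, seed = 53)
  tr$x_um <- tr$x_um + rep(runif(50, 0, 20), each = 8)
  tr$y_um <- tr$y_um + rep(runif(50, 0, 20), each = 8)
  loc <- 0.015
  set.seed(54)
  det <- data.frame(frame = tr$frame,
                    x_um = tr$x_um + rnorm(nrow(tr), sd = loc),
                    y_um = tr$y_um + rnorm(nrow(tr), sd = loc),
                    z_um = tr$z_um + rnorm(nrow(tr), sd = loc))
  tk <- track_foci(det, gate_um = 0.3, dt = 10)
  maxdisp <- max(vapply(split(tk, tk$track_id), function(s) {
    if (nrow(s) < 2) return(0)
    max(sqrt(diff(s$x_um)^2 + diff(s$y_um)^2 + diff(s$z_um)^2))
  }, numeric(1)))
  expect_lte(maxdisp, 4 * loc * sqrt(2) * 3)  # 4 x pairwise noise scale
})

test_that("tracker input validation and empty input", {
  expect_error(track_foci(data.frame(frame = 1, x_um = 1, y_um = 1),
                          gate_um = 0), "positive")
  empty <- track_foci(data.frame(frame = integer(0), x_um = numeric(0),
                                 y_um = numeric(0)), gate_um = 0.5)
  expect_equal(nrow(empty), 0L)
})

test_that("territory nearest-neighbor linking follows slow blobs", {
  cent <- do.call(rbind, lapply(1:10, function(f) {
    data.frame(frame = f,
               x_um = c(2, 6, 10) + 0.02 * (f - 1),
               y_um = c(2, 5, 3) - 0.015 * (f - 1))
  }))
  tk <- track_territories(cent, gate_um = 1, dt = 10)
  expect_equal(length(unique(tk$track_id)), 3L)
  expect_true(all(table(tk$track_id) == 10))

  vanish <- cent[!(cent$frame > 4 & abs(cent$x_um - (6 + 0.02 * (cent$frame - 1))) < 0.1), ]
  tk2 <- track_territories(vanish, gate_um = 1, dt = 10)
  lens <- table(tk2$track_id)
  expect_true(4 %in% lens)                   # the vanishing blob ends at frame 4
})

test_that("territory linking purity at the reported territory mobility", {
  sp <- motion_spec("brownian", D = 3.18e-5, dims = 2, dt = 10, n_frames = 12)
  tr <- simulate_tracks(sp, 200, seed = 55)
  tr$x_um <- tr$x_um + rep(runif(200, 0, 100), each = 12)
  tr$y_um <- tr$y_um + rep(runif(200, 0, 100), each = 12)
  cent <- data.frame(frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um)
  truth <- setNames(tr$track_id,
                    paste(cent$frame, round(cent$x_um, 6), round(cent$y_um, 6)))
  tk <- track_territories(cent, gate_um = 0.5, dt = 10)
  expect_gte(link_purity(tk, truth), 0.99)
})

test_that("duration filter boundary: four steps kept, three dropped", {
  tr <- as_chromo_tracks(
    data.frame(track_id = rep(c(1, 2), c(5, 4)),
               frame = c(1:5, 1:4),
               x_um = 0, y_um = 0), dt = 10, dims = 2)
  kept <- filter_tracks(tr, min_steps = 4)
  expect_equal(unique(kept$track_id), 1)
  none <- filter_tracks(tr[0, ], min_steps = 4)
  expect_equal(nrow(none), 0L)
})
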