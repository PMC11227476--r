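test_that("gift-wrapping hull matches the reference hull", {
  set.seed(70)
  for (rep in 1:10) {
    pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
    h <- jarvis_march(pts)
    ref <- pts[grDevices::chull(pts), , drop = FALSE]
    expect_equal(nrow(h), nrow(ref))
    expect_equal(sort(h[, 1] + 1i * h[, 2]), sort(ref[, 1] + 1i * ref[, 2]))
  }
  expect_error(jarvis_march(cbind(c(0, 1), c(0, 1))), "degenerate")
})

test_that("circle partition: equal ring areas and closed-form outer width", {
  th <- seq(0, 2 * pi, length.out = 720)[-1]
  R <- 5
  circle <- cbind(10 + R * cos(th), 10 + R * sin(th))
  part <- make_shells(circle, N = 7)
  areas <- vapply(seq_len(7), function(i)
    chromomotion:::polygon_area(part$polygons[[i]]), numeric(1))
  rings <- diff(c(0, areas))
  expect_lt(max(abs(rings - mean(rings))) / mean(rings), 0.005)
  ## outer ring width R (1 - sqrt(6/7)) ~ 0.0742 R, measured along +x
  r_outer <- max(part$polygons[[7]][, 1]) - part$centroid[1]
  r_inner <- max(part$polygons[[6]][, 1]) - part$centroid[1]
  expect_equal(r_outer - r_inner, R * (1 - sqrt(6 / 7)), tolerance = 0.01)
})

test_that("two-shell partition halves the hull area; square hull is exact", {
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  part <- make_shells(sq, N = 2)
  inner <- chromomotion:::polygon_area(part$polygons[[1]])
  expect_lt(abs(inner - part$hull_area / 2) / part$hull_area, 0.01)
  hull <- part$polygons[[2]]
  expect_equal(nrow(hull), 4L)
  expect_equal(part$centroid, c(2, 2), tolerance = 1e-9)
})

test_that("ring areas are equal within 1% for any convex mask and N in 2..10", {
  for (s in 1:20) {
    poly <- random_convex_polygon(n_pts = 10 + s %% 6, seed = 700 + s)
    for (N in c(2, 5, 7, 10)) {
      part <- make_shells(jarvis_march(poly), N = N)
      areas <- vapply(seq_len(N), function(i)
        chromomotion:::polygon_area(part$polygons[[i]]), numeric(1))
      rings <- diff(c(0, areas))
      expect_lt(max(abs(rings - mean(rings))) / mean(rings), 0.01)
    }
  }
})

test_that("nucleus segmentation recovers the rendered ellipse", {
  proj <- nucleus_projection(ny = 160, nx = 160, seed = 71)
  mask <- segment_nucleus(proj)
  semi <- c(2.6, 3.0) / 0.041                  # (y, x) semiaxes in px
  ctr <- c(80.5, 80.5)
  yy <- matrix(seq_len(160), 160, 160); xx <- t(yy)
  truth <- ((yy - ctr[1]) / semi[1])^2 + ((xx - ctr[2]) / semi[2])^2 <= 1
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.98)
  expect_error(segment_nucleus(matrix(1, 32, 32)), "constant")
  ## two nuclei: only the largest is kept
  two <- proj * 0
  two[20:60, 20:60] <- 100
  two[100:110, 100:110] <- 100
  m2 <- segment_nucleus(two + matrix(rnorm(160 * 160), 160, 160))
  expect_true(m2[40, 40] && !m2[105, 105])
})

test_that("track-to-shell assignment: centroid, majority and tie rules", {
  th <- seq(0, 2 * pi, length.out = 256)[-1]
  circle <- cbind(5 + 4 * cos(th), 5 + 4 * sin(th))
  part <- make_shells(circle, N = 7)
  center_track <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1:5, x_um = 5, y_um = 5),
    dt = 10, dims = 2)
  expect_equal(unname(assign_tracks(center_track, part)), 7L)

  ## radii of the ring boundaries: sqrt(i/7) * 4
  r_mid <- function(shell) {
    i_out <- 7 - shell + 1L
    4 * mean(sqrt(c(i_out - 1, i_out) / 7))
  }
  majority <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1:5,
               x_um = 5 + c(rep(r_mid(2), 3), rep(r_mid(3), 2)), y_um = 5),
    dt = 10, dims = 2)
  expect_equal(unname(assign_tracks(majority, part)), 2L)

  tie <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1:4,
               x_um = 5 + c(rep(r_mid(2), 2), rep(r_mid(3), 2)), y_um = 5),
    dt = 10, dims = 2)
  expect_equal(unname(assign_tracks(tie, part)), 2L)  # outer of the tied pair

  outside <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1:3, x_um = 5 + 4.5, y_um = 5),
    dt = 10, dims = 2)
  expect_equal(unname(assign_tracks(outside, part)), 1L)
})

test_that("per-shell statistics: counts, null calibration and injected effect", {
  th <- seq(0, 2 * pi, length.out = 256)[-1]
  circle <- cbind(6 + 5 * cos(th), 6 + 5 * sin(th))
  part <- make_shells(circle, N = 7)
  sp <- motion_spec("brownian", D = 8e-5, dims = 2, dt = 10, n_frames = 12)
  region <- list(center = c(6, 6), semiaxes = c(4.9, 4.9))
  tr <- simulate_tracks(sp, 350, start_region = region, seed = 72)
  shells <- assign_tracks(tr, part)
  expect_equal(sum(table(shells)), 350L)        # every track in one shell
  props <- motion_properties(tr)
  st <- per_shell_stats(props, shells, N = 7)
  expect_equal(sum(st$summary$n_tracks), 350L)
  ## same-distribution null: outer-vs-inner tests stay non-significant
  expect_true(all(st$tests$p_mean_velocity_um_s > 0.01, na.rm = TRUE))

  ## halve D in shell 1 and the innermost shells: velocity drops there
  slow <- names(shells)[shells %in% c(1, 6, 7)]
  sp_slow <- motion_spec("brownian", D = 4e-5, dims = 2, dt = 10, n_frames = 12)
  tr2 <- tr
  repl <- simulate_tracks(sp_slow, length(slow), seed = 73)
  for (i in seq_along(slow)) {
    sel <- tr2$track_id == as.integer(slow[i])
    src <- repl[repl$track_id == i, ]
    tr2$x_um[sel] <- src$x_um + tr$x_um[sel][1]
    tr2$y_um[sel] <- src$y_um + tr$y_um[sel][1]
  }
  props2 <- motion_properties(tr2)
  st2 <- per_shell_stats(props2, shells, N = 7)
  mid <- st2$summary$mean_mean_velocity_um_s[st2$summary$shell %in% 2:4]
  s1 <- st2$summary$mean_mean_velocity_um_s[st2$summary$shell == 1]
  expect_lt(s1, min(mid))
  p_mid <- st2$tests$p_mean_velocity_um_s[st2$tests$shell %in% 2:4]
  expect_true(all(p_mid < 0.05))
})

test_that("single populated shell yields stats but no tests", {
  th <- seq(0, 2 * pi, length.out = 128)[-1]
  circle <- cbind(3 + 2 * cos(th), 3 + 2 * sin(th))
  part <- make_shells(circle, N = 3)
  tr <- as_chromo_tracks(
    data.frame(track_id = rep(1:3, each = 5), frame = rep(1:5, 3),
               x_um = 3 + rep(c(0, 0.05, -0.05), each = 5),
               y_um = 3), dt = 10, dims = 2)
  shells <- assign_tracks(tr, part)
  st <- per_shell_stats(motion_properties(tr), shells, N = 3)
  expect_equal(st$summary$n_tracks[3], 3L)
  expect_true(is.null(st$tests) || all(is.na(st$tests$p_straightness)))
})
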