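mk_curve <- function(lag_s, msd_um2, n_pairs = rep(1L, length(lag_s)),
                     dims = 3, dt = 10) {
  cv <- data.frame(lag_s = lag_s, msd_um2 = msd_um2, n_pairs = n_pairs)
  attr(cv, "dims") <- dims; attr(cv, "dt") <- dt; attr(cv, "n_tracks") <- 1L
  class(cv) <- c("msd_curve", "data.frame")
  cv
}

test_that("MSD closed forms: stationary and ballistic tracks", {
  still <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1:6, x_um = 2, y_um = 3, z_um = 1),
    dt = 10, dims = 3)
  expect_true(all(msd(still)$msd_um2 == 0))

  v <- 0.01
  ball <- as_chromo_tracks(
    data.frame(track_id = 1, frame = 1:12, x_um = v * 10 * (0:11),
               y_um = 0, z_um = 0), dt = 10, dims = 3)
  cv <- msd(ball)
  expect_equal(cv$msd_um2, (v * cv$lag_s)^2, tolerance = 1e-12)
})

test_that("ensemble MSD of Brownian tracks matches 6 D dt at early lags", {
  D <- 8.32e-5
  sp <- motion_spec("brownian", D = D, dims = 3, dt = 10, n_frames = 12)
  cv <- msd(simulate_tracks(sp, 1000, seed = 30))
  for (k in 1:5) {
    expect_lt(abs(cv$msd_um2[k] / (6 * cv$lag_s[k]) - D) / D, 0.10)
  }
})

test_that("diffusion fit is the weighted through-origin slope", {
  lags <- seq(10, 110, by = 10)
  exact <- mk_curve(lags, 6 * 8.32e-5 * lags)
  expect_equal(fit_diffusion(exact)$D, 8.32e-5, tolerance = 1e-12)

  ## ballistic curve: closed-form weighted regression oracle
  v <- 0.01
  w <- 12 - (1:11)                       # pair counts of a 12-frame track
  ball <- mk_curve(lags, (v * lags)^2, n_pairs = w)
  expected <- v^2 * sum(w * lags^3) / (6 * sum(w * lags^2))
  expect_equal(fit_diffusion(ball)$D, expected, tolerance = 1e-12)

  zero <- mk_curve(lags, rep(0, 11))
  z <- fit_diffusion(zero)
  expect_equal(z$D, 0)
  down <- mk_curve(lags, -lags)          # negative slope flagged
  expect_equal(fit_diffusion(down)$flag, "negative_slope")
  expect_equal(fit_diffusion(down)$D, 0)
})

test_that("anomalous fit recovers exact power laws", {
  lags <- seq(10, 110, by = 10)
  ball <- mk_curve(lags, (0.01 * lags)^2)
  expect_equal(fit_anomalous(ball)$alpha, 2, tolerance = 1e-3)
  brown <- mk_curve(lags, 6 * 8.32e-5 * lags)
  fb <- fit_anomalous(brown)
  expect_equal(fb$alpha, 1, tolerance = 1e-3)
  expect_equal(fb$Gamma, 6 * 8.32e-5, tolerance = 1e-6)

  with_zero <- mk_curve(lags, c(0, 6 * 8.32e-5 * lags[-1]))
  expect_equal(fit_anomalous(with_zero)$alpha, 1, tolerance = 1e-3)
  expect_error(fit_anomalous(mk_curve(lags, c(1e-3, 1e-3, rep(0, 9)))),
               "3 lags")
})

test_that("simulated fBm ensemble recovers the generating exponent 0.76", {
  sp <- motion_spec("anomalous", D = 5.44e-5, alpha = 0.76, dims = 3,
                    dt = 10, n_frames = 12)
  fit <- msd_fit(simulate_tracks(sp, 1000, seed = 31))
  expect_lt(abs(fit$alpha - 0.76), 0.05)
})

test_that("msd_fit model object supports the standard methods", {
  sp <- motion_spec("brownian", D = 8.32e-5, dims = 3, dt = 10, n_frames = 12)
  fit <- msd_fit(simulate_tracks(sp, 300, seed = 33))
  co <- coef(fit)
  expect_named(co, c("D", "alpha", "Gamma"))
  expect_equal(predict(fit, 10, model = "diffusion"),
               fit$diffusion$slope * 10)
  expect_equal(predict(fit, 20, model = "anomalous"),
               fit$Gamma * 20^fit$alpha)
  expect_length(residuals(fit), nrow(fit$curve))
  expect_output(print(fit), "diffusion")
  expect_output(print(summary(fit)), "lag range")
  ## simulate() round trip: tracks drawn from the fitted law refit close by
  tr2 <- simulate(fit, nsim = 500, seed = 34, n_frames = 12)
  fit2 <- msd_fit(tr2)
  expect_lt(abs(fit2$alpha - fit$alpha), 0.1)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("motion properties match hand geometry", {
  two <- as_chromo_tracks(data.frame(track_id = 1, frame = 1:2,
                                     x_um = c(0, 3), y_um = 0), dt = 10, dims = 2)
  p <- motion_properties(two)
  expect_equal(p$rg_um, 1.5)
  expect_equal(p$straightness, 1)

  sq <- as_chromo_tracks(data.frame(track_id = 1, frame = 1:4,
                                    x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 1)),
                         dt = 10, dims = 2)
  p <- motion_properties(sq)
  expect_equal(p$rg_um, sqrt(0.5), tolerance = 1e-12)
  expect_equal(p$dist_start_end_um, 1)
  expect_equal(p$straightness, 1 / 3, tolerance = 1e-12)

  ell <- as_chromo_tracks(data.frame(track_id = 1, frame = 1:3,
                                     x_um = c(0, 1, 1), y_um = c(0, 0, 1)),
                          dt = 10, dims = 2)
  p <- motion_properties(ell)
  expect_equal(p$dist_start_end_um, sqrt(2), tolerance = 1e-12)
  expect_equal(p$straightness, sqrt(2) / 2, tolerance = 1e-12)

  zero <- as_chromo_tracks(data.frame(track_id = 1, frame = 1:3,
                                      x_um = 1, y_um = 1), dt = 10, dims = 2)
  p <- motion_properties(zero)
  expect_equal(p$straightness, 0)
  expect_equal(p$flag, "zero_path")
})

test_that("rank-sum comparison: exact small-sample enumeration", {
  expect_equal(compare_groups(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(compare_groups(rep(1, 3), rep(1, 4)), 1)
  set.seed(40)
  for (n1 in 2:6) for (n2 in n1:6) {
    a <- sample(seq(1, 100), n1); b <- sample(seq(101, 200) + 0.5, n2)
    ab <- sample(c(a, b))                  # interleave values randomly
    a2 <- ab[seq_len(n1)]; b2 <- ab[-seq_len(n1)]
    expect_equal(compare_groups(a2, b2), enumerate_ranksum_p(a2, b2),
                 tolerance = 1e-10)
  }
  big_a <- rnorm(200); big_b <- rnorm(200, mean = 1)
  expect_lt(compare_groups(big_a, big_b), 1e-10)
})

test_that("time-averaged and ensemble MSD agree for stationary increments", {
  sp <- motion_spec("brownian", D = 8e-5, dims = 2, dt = 10, n_frames = 12)
  tr <- simulate_tracks(sp, 2000, seed = 41)
  ta <- msd(tr)                            # time-averaged then ensemble
  ## pure ensemble average at lag 1: first-step displacement only
  firsts <- tr[tr$frame <= 2, ]
  m <- matrix(firsts$x_um, nrow = 2); my <- matrix(firsts$y_um, nrow = 2)
  ens1 <- mean(diff(m)^2 + diff(my)^2)
  expect_lt(abs(ta$msd_um2[1] - ens1) / ens1, 0.10)
})

test_that("ensemble-level anomalous fits are unbiased across exponents", {
  for (alpha in c(0.48, 0.95, 1.66)) {
    sp <- motion_spec("anomalous", D = 8.32e-5, alpha = alpha, dims = 3,
                      dt = 10, n_frames = 12)
    tr <- simulate_tracks(sp, 1000, seed = round(1000 * alpha))
    expect_lt(abs(fit_anomalous(msd(tr))$alpha - alpha), 0.05)
  }
})
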