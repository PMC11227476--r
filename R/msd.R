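#' Mean squared displacement of trajectories
#'
#' Computes the time-averaged MSD per trajectory over all ordered position
#' pairs at each lag (a multiple of the frame interval), and optionally the
#' ensemble curve: the unweighted mean of the per-track MSDs at each lag,
#' with tracks too short for a lag skipped at that lag. Gapped tracks
#' contribute pairs according to their true frame separation.
#'
#' @param tracks a `chromo_tracks` data frame (see [simulate_tracks()],
#'   [track_foci()]).
#' @param mode `"ensemble"` (default) for a single averaged curve or
#'   `"per_track"` for a list of per-track curves.
#' @param max_lag maximum lag in frames (default: longest available).
#' @return an `msd_curve` data frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs` (total pair count at that lag), and attributes `dims`, `dt`,
#'   `n_tracks`; or a named list of such curves for `mode = "per_track"`.
#' @export
msd <- function(tracks, mode = c("ensemble", "per_track"), max_lag = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tracks, "chromo_tracks"))
  dt <- attr(tracks, "dt"); dims <- attr(tracks, "dims")
  cols <- track_coord_cols(dims)
  split_idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  per <- lapply(split_idx, function(idx) {
    fr <- tracks$frame[idx]
    o <- order(fr); fr <- fr[o]
    P <- as.matrix(tracks[idx[o], cols, drop = FALSE])
    n <- length(fr)
    if (n < 2) return(NULL)
    dfr <- outer(fr, fr, "-")
    sel <- which(dfr > 0)
    lags <- dfr[sel]
    i <- ((sel - 1L) %% n) + 1L     # row (earlier point)
    j <- ((sel - 1L) %/% n) + 1L    # col (later point)
    sq <- rowSums((P[j, , drop = FALSE] - P[i, , drop = FALSE])^2)
    agg_m <- tapply(sq, lags, mean)
    agg_n <- tapply(sq, lags, length)
    data.frame(lag = as.integer(names(agg_m)),
               msd = as.numeric(agg_m), n_pairs = as.integer(agg_n))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0) stop("no track has at least two points")
  if (!is.null(max_lag)) per <- lapply(per, function(p) p[p$lag <= max_lag, ])

  mk_curve <- function(df, n_tracks) {
    out <- data.frame(lag_s = df$lag * dt, msd_um2 = df$msd,
                      n_pairs = df$n_pairs)
    attr(out, "dims") <- dims; attr(out, "dt") <- dt
    attr(out, "n_tracks") <- n_tracks
    class(out) <- c("msd_curve", "data.frame")
    out
  }
  if (mode == "per_track") return(lapply(per, mk_curve, n_tracks = 1L))

  all_lags <- sort(unique(unlist(lapply(per, `[[`, "lag"))))
  ens <- vapply(all_lags, function(l) {
    vals <- unlist(lapply(per, function(p) p$msd[p$lag == l]))
    np <- sum(unlist(lapply(per, function(p) p$n_pairs[p$lag == l])))
    c(mean(vals), np)
  }, numeric(2))
  mk_curve(data.frame(lag = all_lags, msd = ens[1, ], n_pairs = ens[2, ]),
           n_tracks = length(per))
}

#' Fit the normal-diffusion model to an MSD curve
#'
#' Weighted least-squares slope of MSD versus lag through the origin
#' (weights: pair counts), under the convention MSD = 2 d D Δt for
#' dimensionality d — 6 D Δt for 3D foci, 4 D Δt for 2D territories.
#'
#' @param curve an `msd_curve`.
#' @param dims dimensionality (default: the curve's `dims` attribute).
#' @return list with `D` (µm²/s), `slope`, `flag` (`"ok"` or
#'   `"negative_slope"`), and fitted values.
#' @export
fit_diffusion <- function(curve, dims = attr(curve, "dims")) {
  stopifnot(nrow(curve) >= 2)
  w <- curve$n_pairs; x <- curve$lag_s; y <- curve$msd_um2
  slope <- sum(w * x * y) / sum(w * x^2)
  flag <- "ok"
  if (slope < 0) { slope <- 0; flag <- "negative_slope" }
  list(D = slope / (2 * dims), slope = slope, flag = flag,
       fitted = slope * x, residuals = y - slope * x)
}

#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Weighted linear regression of log(MSD) on log(lag) (weights: pair
#' counts): the slope is the anomalous exponent alpha and exp(intercept) the
#' generalized coefficient Gamma, i.e. MSD = Gamma * Δt^alpha. Lags with
#' non-positive MSD are dropped; at least 3 usable lags are required.
#'
#' @param curve an `msd_curve`.
#' @return list with `alpha`, `Gamma` (µm²/s^alpha), and log-scale fitted
#'   values / residuals.
#' @export
fit_anomalous <- function(curve) {
  use <- curve$msd_um2 > 0
  if (sum(use) < 3) stop("need at least 3 lags with positive MSD")
  x <- log(curve$lag_s[use]); y <- log(curve$msd_um2[use])
  w <- curve$n_pairs[use]
  xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  intercept <- ym - slope * xm
  list(alpha = slope, Gamma = exp(intercept),
       used_lags = curve$lag_s[use],
       fitted = intercept + slope * x, residuals = y - (intercept + slope * x))
}

#' Per-track motion properties
#'
#' Radius of gyration (RMS distance of the positions from the track
#' centroid), mean velocity over consecutive steps, start-to-end distance,
#' and track straightness (start-to-end distance divided by path length,
#' in [0, 1]; defined as 0 with a flag for zero-length paths).
#'
#' @param tracks a `chromo_tracks` data frame.
#' @return data frame keyed by `track_id` with columns `rg_um`,
#'   `mean_velocity_um_s`, `dist_start_end_um`, `straightness`,
#'   `n_points`, `flag`.
#' @export
motion_properties <- function(tracks) {
  stopifnot(inherits(tracks, "chromo_tracks"))
  dt <- attr(tracks, "dt"); dims <- attr(tracks, "dims")
  cols <- track_coord_cols(dims)
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    sub <- tracks[tracks$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    P <- as.matrix(sub[, cols, drop = FALSE])
    n <- nrow(P)
    if (n < 2) return(NULL)
    ctr <- colMeans(P)
    rg <- sqrt(mean(rowSums(sweep(P, 2L, ctr)^2)))
    steps <- diff(P)
    step_len <- sqrt(rowSums(steps^2))
    step_dt <- diff(sub$frame) * dt
    mv <- mean(step_len / step_dt)
    dse <- sqrt(sum((P[n, ] - P[1, ])^2))
    path <- sum(step_len)
    flag <- "ok"
    if (path == 0) { straight <- 0; flag <- "zero_path" }
    else straight <- dse / path
    data.frame(track_id = id, rg_um = rg, mean_velocity_um_s = mv,
               dist_start_end_um = dse, straightness = straight,
               n_points = n, flag = flag)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Thin wrapper with the conventions used throughout the pipeline: exact
#' enumeration when the smaller group has at most 8 values and there are no
#' ties, normal approximation with tie correction otherwise; two identical
#' constant groups give p = 1.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @return two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (length(unique(c(values_a, values_b))) == 1L) return(1)
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- min(length(values_a), length(values_b)) <= 8 && !has_ties
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = FALSE)$p.value)
}

#' Per-track anomalous-exponent fits
#'
#' Fits the anomalous-diffusion model to each track's time-averaged MSD,
#' using lags up to half the track duration and at most the first 10 lags
#' (long-lag points of a single-track MSD are few-pair averages whose
#' log-scale noise biases the exponent downward; capping the lag range is
#' standard single-track MSD practice and roughly halves the estimator sd).
#' Used to feed the motion-subpopulation classification.
#'
#' @param tracks a `chromo_tracks` data frame (already duration-filtered).
#' @return data frame with `track_id`, `alpha`, `Gamma`, `D` (from the
#'   diffusion model on the same lags).
#' @export
track_alphas <- function(tracks) {
  per <- msd(tracks, mode = "per_track")
  dims <- attr(tracks, "dims")
  out <- lapply(names(per), function(id) {
    cv <- per[[id]]
    dt <- attr(tracks, "dt")
    keep <- cv$lag_s <= min(max(cv$lag_s) / 2, 10 * dt)
    if (sum(keep & cv$msd_um2 > 0) < 3) keep <- rep(TRUE, nrow(cv))
    cv2 <- cv[keep, , drop = FALSE]
    attr(cv2, "dims") <- dims
    a <- tryCatch(fit_anomalous(cv2), error = function(e) NULL)
    if (is.null(a)) return(NULL)
    d <- fit_diffusion(cv2, dims = dims)
    data.frame(track_id = id, alpha = a$alpha, Gamma = a$Gamma, D = d$D)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}
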