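#' Classify trajectories into motion subpopulations by k-means on alpha
#'
#' One-dimensional k-means clustering of per-track anomalous exponents with
#' k-means++ initialization: initial centroids are sampled from the data
#' points with probability proportional to squared distance from the nearest
#' already-chosen centroid, then refined by Lloyd iterations (assign to
#' closest centroid, recompute centroid means) to a fixed point. The best of
#' `n_init` restarts by within-cluster sum of squares is kept, and labels
#' are relabeled so centroids ascend — population 0 (lower alpha,
#' constrained motion) before population 1 (higher alpha, directed motion).
#'
#' @param alphas numeric vector of per-track anomalous exponents.
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means++ initialization.
#' @param n_init number of restarts (default 10).
#' @return object of class `"subpop_result"`: list with `labels`
#'   (0-based, same length/order as `alphas`), `centroids` (ascending),
#'   `withinss`, `sizes`.
#' @export
cluster_alpha <- function(alphas, k = 2L, seed = 1L, n_init = 10L) {
  alphas <- as.numeric(alphas)
  if (length(unique(alphas)) < k)
    stop("need at least k distinct alpha values")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    ctr <- kmeanspp_init(alphas, k)
    fit <- lloyd_1d(alphas, ctr)
    if (is.null(best) || fit$withinss < best$withinss) best <- fit
  }
  o <- order(best$centroids)
  relab <- integer(k); relab[o] <- seq_len(k)
  labels0 <- relab[best$assign] - 1L
  structure(list(labels = labels0, centroids = best$centroids[o],
                 withinss = best$withinss,
                 sizes = tabulate(labels0 + 1L, k), k = k),
            class = "subpop_result")
}

## D^2-weighted seeding from the data points
kmeanspp_init <- function(x, k) {
  ctr <- numeric(k)
  ctr[1] <- x[sample.int(length(x), 1L)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(v) min((v - ctr[seq_len(j - 1L)])^2), numeric(1))
    if (sum(d2) == 0) ctr[j] <- x[sample.int(length(x), 1L)]
    else ctr[j] <- x[sample.int(length(x), 1L, prob = d2)]
  }
  ctr
}

lloyd_1d <- function(x, ctr, max_iter = 100L) {
  k <- length(ctr)
  assign_old <- rep(0L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, ctr, "-"))
    asg <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {
      if (any(asg == j)) ctr[j] <- mean(x[asg == j])
    }
    if (identical(asg, assign_old)) break
    assign_old <- asg
  }
  wss <- sum((x - ctr[asg])^2)
  list(centroids = ctr, assign = asg, withinss = wss)
}

#' @export
print.subpop_result <- function(x, ...) {
  cat("Motion subpopulations (k =", x$k, ")\n")
  for (j in seq_len(x$k)) {
    cat(sprintf("  population %d: centroid alpha = %.3f, n = %d\n",
                j - 1L, x$centroids[j], x$sizes[j]))
  }
  invisible(x)
}

#' Spatial distribution of motion subpopulations across nuclear shells
#'
#' Cross-tabulates subpopulation labels against shell assignments and
#' reports per-shell counts and fractions (fractions sum to 1 within each
#' populated shell; empty shells are flagged with NA fractions).
#'
#' @param result a [cluster_alpha()] result.
#' @param shell_of_track integer vector of shell indices (1 = outermost),
#'   same order as the alphas that produced `result`.
#' @param n_shells total number of shells (default: max observed).
#' @return data frame with `shell`, per-population `count_*` and
#'   `fraction_*` columns, and the population-0 : population-1 ratio.
#' @export
subpop_shell_distribution <- function(result, shell_of_track,
                                      n_shells = max(shell_of_track)) {
  stopifnot(length(shell_of_track) == length(result$labels))
  out <- lapply(seq_len(n_shells), function(s) {
    sel <- shell_of_track == s
    counts <- tabulate(result$labels[sel] + 1L, result$k)
    tot <- sum(counts)
    fr <- if (tot > 0) counts / tot else rep(NA_real_, result$k)
    ratio <- if (result$k == 2 && counts[2] > 0) counts[1] / counts[2] else NA_real_
    df <- data.frame(shell = s, n = tot, ratio_0_1 = ratio)
    for (j in seq_len(result$k)) {
      df[[paste0("count_", j - 1L)]] <- counts[j]
      df[[paste0("fraction_", j - 1L)]] <- fr[j]
    }
    df
  })
  do.call(rbind, out)
}
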