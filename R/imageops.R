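## Internal low-level image operations shared by the detection, registration,
## shell and DNA-quantification stages. 2D images are matrices indexed
## [y, x]; 3D volumes are arrays [z, y, x]. Physical units enter only through
## voxel sizes passed by the callers.

gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

## 1D convolution along the first dimension of a matrix, replicate padding
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  out
}

smooth2d <- function(img, sigma_y, sigma_x = sigma_y) {
  img <- conv_cols(img, gauss_kernel(sigma_y))
  t(conv_cols(t(img), gauss_kernel(sigma_x)))
}

smooth3d <- function(vol, sigma_z, sigma_y, sigma_x) {
  d <- dim(vol)
  ## z: unfold to [z, y*x]
  m <- conv_cols(matrix(vol, d[1], d[2] * d[3]), gauss_kernel(sigma_z))
  vol <- array(m, d)
  ## y: permute to [y, z, x]
  v <- aperm(vol, c(2, 1, 3))
  m <- conv_cols(matrix(v, d[2], d[1] * d[3]), gauss_kernel(sigma_y))
  v <- array(m, c(d[2], d[1], d[3]))
  vol <- aperm(v, c(2, 1, 3))
  ## x: permute to [x, z, y]
  v <- aperm(vol, c(3, 1, 2))
  m <- conv_cols(matrix(v, d[3], d[1] * d[2]), gauss_kernel(sigma_x))
  v <- array(m, c(d[3], d[1], d[2]))
  aperm(v, c(2, 3, 1))
}

shift_arr <- function(a, by) {
  ## integer shift with replicate padding; by = c(dz, dy, dx) or c(dy, dx)
  d <- dim(a)
  idx <- lapply(seq_along(d), function(i) {
    j <- seq_len(d[i]) - by[i]
    pmin(pmax(j, 1L), d[i])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## second derivative along one dimension (unit spacing), replicate padding
second_diff <- function(a, dim_i) {
  nd <- length(dim(a))
  up <- dn <- integer(nd)
  up[dim_i] <- 1L; dn[dim_i] <- -1L
  shift_arr(a, up) + shift_arr(a, dn) - 2 * a
}

## Laplacian of Gaussian with anisotropic sigmas (voxel units); response is
## sign-flipped so bright blobs give positive peaks, and scale-normalized by
## the lateral sigma^2.
log_response3d <- function(vol, sigma_z, sigma_y, sigma_x) {
  s <- smooth3d(vol, sigma_z, sigma_y, sigma_x)
  lap <- second_diff(s, 1L) / 1 + second_diff(s, 2L) + second_diff(s, 3L)
  -lap * sigma_y * sigma_x
}

## 26-connectivity local maxima of a 3D array; returns index matrix [z,y,x]
local_maxima3d <- function(resp, threshold) {
  d <- dim(resp)
  is_max <- resp > threshold
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (!any(is_max)) break
    is_max <- is_max & (resp >= shift_arr(resp, c(dz, dy, dx)))
  }
  ## strictness against the flat replicate-padded border
  if (d[1] > 2) { } # z borders kept: 7-section stacks often peak at z edges
  which(is_max, arr.ind = TRUE)
}

## bilinear sampling of a matrix at fractional (row, col) positions;
## out-of-range samples return `fill`
interp_bilinear <- function(img, rows, cols, fill = 0) {
  rows <- as.vector(rows); cols <- as.vector(cols)
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  ## clamp for safe indexing, mask later
  r0c <- pmin(pmax(r0, 1L), nr - 1L)
  c0c <- pmin(pmax(c0, 1L), nc - 1L)
  i00 <- img[cbind(r0c, c0c)]
  i10 <- img[cbind(r0c + 1L, c0c)]
  i01 <- img[cbind(r0c, c0c + 1L)]
  i11 <- img[cbind(r0c + 1L, c0c + 1L)]
  v <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
       i01 * (1 - fr) * fc + i11 * fr * fc
  v[!ok] <- fill
  v
}

## warp a 2D image by an affine transform about the image center:
## out(x) = img(A x + b), pixel coordinates
warp_affine2d <- function(img, A, b, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  g <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  gc <- sweep(g, 2L, ctr)
  src <- t(A %*% t(gc)) + matrix(b, nrow(g), 2, byrow = TRUE)
  src <- sweep(src, 2L, ctr, "+")
  matrix(interp_bilinear(img, src[, 1], src[, 2], fill), nr, nc)
}

## warp a 2D image by a dense displacement field: out(x) = img(x + u(x));
## uy, ux are matrices the same size as img (pixel units)
warp_field2d <- function(img, uy, ux, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc) + uy
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + ux
  matrix(interp_bilinear(img, rows, cols, fill), nr, nc)
}

## 3D connected components (26-connectivity) via per-slice 2D labelling
## (EBImage::bwlabel) merged across z with union-find. EBImage's labeller is
## 2D-only, hence the merge step.
label3d <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[1])) {
    sl <- EBImage::bwlabel(matrix(as.numeric(mask[z, , ]), d[2], d[3]))
    sl <- matrix(as.integer(sl), d[2], d[3])
    sl[sl > 0L] <- sl[sl > 0L] + offset
    offset <- max(offset, if (any(sl > 0L)) max(sl) else offset)
    labs[z, , ] <- sl
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  if (d[1] > 1) for (z in seq_len(d[1] - 1L)) {
    a <- labs[z, , ]; bm <- labs[z + 1L, , ]
    ## 26-connectivity between adjacent slices: compare b against a shifted
    for (dy in -1:1) for (dx in -1:1) {
      bs <- shift_arr(bm, c(dy, dx))
      sel <- a > 0L & bs > 0L
      if (any(sel)) {
        pairs <- unique(cbind(a[sel], bs[sel]))
        for (r in seq_len(nrow(pairs))) union_(pairs[r, 1], pairs[r, 2])
      }
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- integer(offset)
  relab[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- labs > 0L
  labs[pos] <- relab[roots[labs[pos]]]
  labs
}

## exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher
## lower-envelope recursion), one 1D pass per axis, anisotropic spacing
dt1d <- function(f, spacing = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- seq_len(n) * spacing
  v <- integer(n); zz <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; zz[1L] <- -Inf; zz[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + x[q]^2) - (f[vk] + x[vk]^2)) / (2 * (x[q] - x[vk]))
      if (is.nan(s)) s <- Inf              # both parabolas at +Inf
      if (k > 1L && s <= zz[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; zz[k] <- s; zz[k + 1L] <- Inf
  }
  k <- 1L
  out <- numeric(n)
  for (q in seq_len(n)) {
    while (zz[k + 1L] < x[q]) k <- k + 1L
    out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  out
}

## 3D distance transform: distance (µm) from each foreground voxel of `mask`
## to the nearest background voxel, voxel spacing `voxel` = c(z, y, x) µm
distance_transform3d <- function(mask, voxel = c(1, 1, 1)) {
  d <- dim(mask)
  INF <- sum((d * voxel)^2)
  f <- array(ifelse(mask, INF, 0), d)
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    v <- aperm(f, perm)
    dv <- dim(v)
    m <- matrix(v, dv[1], dv[2] * dv[3])
    m <- apply(m, 2L, dt1d, spacing = voxel[ax])
    v <- array(m, dv)
    inv <- order(perm)
    f <- aperm(v, inv)
  }
  sqrt(f)
}

#' Triangle auto-threshold
#'
#' Classic geometric triangle threshold on a 256-bin histogram: a line is
#' drawn from the histogram peak to the far tail end and the threshold is the
#' bin with maximum perpendicular distance below that line. Operates on the
#' full-stack histogram, matching the behavior of the common ImageJ
#' implementation on 16-bit-converted stacks.
#'
#' @param x numeric array of intensities.
#' @param n_bins histogram bins (default 256).
#' @param tail `"auto"` picks the longer tail; `"upper"`/`"lower"` force the
#'   side (bright-object segmentation uses `"upper"`).
#' @return threshold on the intensity scale of `x`.
#' @export
triangle_threshold <- function(x, n_bins = 256L,
                               tail = c("auto", "upper", "lower")) {
  tail <- match.arg(tail)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  peak <- which.max(h)
  nz <- which(h > 0)
  end <- switch(tail,
    upper = nz[length(nz)],
    lower = nz[1],
    auto = if ((peak - nz[1]) > (nz[length(nz)] - peak)) nz[1]
           else nz[length(nz)])
  if (end == peak) return(br[peak])
  ## distance from points (i, h[i]) to line peak->end
  i <- peak:end
  vx <- end - peak; vy <- h[end] - h[peak]
  dist <- abs(vy * (i - peak) - vx * (h[i] - h[peak])) / sqrt(vx^2 + vy^2)
  thr_bin <- i[which.max(dist)]
  (br[thr_bin] + br[thr_bin + 1L]) / 2
}

## Otsu threshold on an arbitrary-range image via EBImage (expects [0,1])
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  xn <- (x - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}
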