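# Low-level image primitives shared by the feature extractors.
#
# All images are plain numeric matrices (2D) or arrays (3D); masks are logical
# arrays of the same shape. Coordinates are array indices (1-based, row-major
# in R's column-major storage sense); no geometry beyond voxel spacing is kept.

# Symmetric (mirror) index into 1..n for any integer i, edge repeated:
# ..., x[2], x[1] | x[1], x[2], ..., x[n] | x[n], x[n-1], ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

# Reflect-pad a matrix by `r` pixels on every side (supports r >= n by
# repeated mirroring).
pad_reflect <- function(x, r) {
  n <- nrow(x)
  m <- ncol(x)
  x[reflect_index((1L - r):(n + r), n), reflect_index((1L - r):(m + r), m),
    drop = FALSE]
}

# Separable convolution of a matrix with an odd-length 1-D kernel applied to
# rows then columns, reflect padding. Exact (direct) convolution.
conv_separable <- function(x, kernel) {
  stopifnot(length(kernel) %% 2 == 1)
  r <- (length(kernel) - 1L) / 2L
  xp <- pad_reflect(x, r)
  n <- nrow(x)
  m <- ncol(x)
  # rows
  out <- matrix(0, n, ncol(xp))
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * xp[(k - 1L) + seq_len(n), , drop = FALSE]
  }
  res <- matrix(0, n, m)
  for (k in seq_along(kernel)) {
    res <- res + kernel[k] * out[, (k - 1L) + seq_len(m), drop = FALSE]
  }
  res
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(x, sigma) conv_separable(x, gaussian_kernel(sigma))

# Box sums over a (window x window) neighbourhood, reflect padding.
box_sum <- function(x, window) {
  conv_separable(x, rep(1, window))
}

# Otsu threshold of the values in `v` (maximises between-class variance over
# a 256-bin histogram). Returns a threshold; pixels > threshold are "dense".
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop_invalid("no finite values to threshold")
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) return(lo)
  h <- tabulate(pmin(n_bins, 1L + floor((v - lo) / (hi - lo) * n_bins)), n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Connected-component labelling of a logical 2D/3D mask.
# Connectivity: 8 in 2D, 26 in 3D. Iterative label propagation (min over
# neighbours) with an index-compression pass; exact for any mask.
label_components <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) %in% c(2L, 3L))
  lab <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  lab[idx] <- seq_along(idx)

  if (length(dims) == 2L) {
    shifts <- expand.grid(dr = -1:1, dc = -1:1, dz = 0L)
  } else {
    shifts <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  }
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0 & shifts$dz == 0), ]

  coords <- arrayInd(idx, dims)
  n <- dims[1]
  m <- dims[2]
  z_max <- if (length(dims) == 3L) dims[3] else 1L

  # Precompute, for each foreground voxel, the foreground linear indices of
  # its neighbours.
  pos <- array(0L, dims)
  pos[idx] <- seq_along(idx)
  neigh <- vector("list", nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    rr <- coords[, 1] + shifts$dr[s]
    cc <- coords[, 2] + shifts$dc[s]
    zz <- (if (ncol(coords) == 3L) coords[, 3] else rep(1L, nrow(coords))) +
      shifts$dz[s]
    ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= m & zz >= 1L & zz <= z_max
    lin <- rep(NA_integer_, length(idx))
    lin[ok] <- rr[ok] + (cc[ok] - 1L) * n + (zz[ok] - 1L) * n * m
    p <- rep(0L, length(idx))
    p[ok] <- pos[lin[ok]]
    neigh[[s]] <- p
  }

  cur <- seq_along(idx)
  repeat {
    nxt <- cur
    for (s in seq_along(neigh)) {
      p <- neigh[[s]]
      has <- p > 0L
      nxt[has] <- pmin(nxt[has], cur[p[has]])
    }
    # pointer-jumping to speed convergence
    nxt <- nxt[nxt]
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  lab[idx] <- match(cur, sort(unique(cur)))
  lab
}

# Distance (in mm) of every TRUE voxel of `mask` to the nearest voxel outside
# the mask, computed against the mask's boundary layer. Exact Euclidean
# point-to-point distance; intended for the modest phantom sizes used here.
boundary_distance <- function(mask, spacing = rep(1, length(dim(mask)))) {
  dims <- dim(mask)
  idx_in <- which(mask)
  d_out <- array(Inf, dims)
  if (length(idx_in) == 0L) return(d_out)
  # boundary voxels: in-mask voxels 6/4-adjacent to outside (or image edge)
  coords <- arrayInd(idx_in, dims)
  is_b <- rep(FALSE, length(idx_in))
  for (ax in seq_along(dims)) {
    for (dlt in c(-1L, 1L)) {
      nb <- coords
      nb[, ax] <- nb[, ax] + dlt
      off_edge <- nb[, ax] < 1L | nb[, ax] > dims[ax]
      lin <- rep(1L, length(idx_in))
      inb <- !off_edge
      if (any(inb)) {
        lin[inb] <- nb[inb, 1] +
          (nb[inb, 2] - 1L) * dims[1] +
          (if (length(dims) == 3L) (nb[inb, 3] - 1L) * dims[1] * dims[2] else 0L)
      }
      is_b <- is_b | off_edge | (inb & !mask[ifelse(inb, lin, 1L)])
    }
  }
  bc <- coords[is_b, , drop = FALSE]
  if (nrow(bc) == 0L) {
    d_out[idx_in] <- Inf
    return(d_out)
  }
  sp <- spacing
  # chunked distance to nearest boundary voxel
  d <- rep(Inf, length(idx_in))
  bs <- sweep(bc, 2, sp, `*`)
  step <- max(1L, floor(2e6 / nrow(bc)))
  for (start in seq(1L, length(idx_in), by = step)) {
    sel <- start:min(start + step - 1L, length(idx_in))
    cs <- sweep(coords[sel, , drop = FALSE], 2, sp, `*`)
    dd <- outer(rowSums(cs^2), rep(1, nrow(bs))) +
      outer(rep(1, length(sel)), rowSums(bs^2)) -
      2 * tcrossprod(cs, bs)
    d[sel] <- sqrt(pmax(0, apply(dd, 1, min)))
  }
  d_out[idx_in] <- d
  d_out
}

# Skewness / kurtosis with population (biased) moment estimators; skewness is
# defined as 0 for zero-variance input.
moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2
}
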