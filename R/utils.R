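# Internal array / numeric helpers shared across modules.

# Bounding box of nonzero voxels, as index ranges per axis (with margin,
# clamped to the array).
bbox_ranges <- function(mask, margin = 1L) {
  stopifnot(length(dim(mask)) == 3L)
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("mask has no foreground voxels")
  co <- arrayInd(idx, dim(mask))
  lapply(1:3, function(ax) {
    lo <- max(1L, min(co[, ax]) - margin)
    hi <- min(dim(mask)[ax], max(co[, ax]) + margin)
    lo:hi
  })
}

crop_to <- function(a, rng) a[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]

# Value of the neighbor at offset `d` for every voxel: out[x] = a[x + d],
# NA where x + d falls outside the array.
array_shift <- function(a, d) {
  dm <- dim(a)
  out <- array(a[1][NA], dm)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(dm[ax]) + d[ax]
    i[i >= 1L & i <= dm[ax]]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] - d[ax])
  if (any(vapply(src, length, 1L) == 0L)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 26- or 6-neighborhood coordinate offsets (rows).
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  unname(g)
}

# The 13 unique 3D direction vectors (one per symmetric pair), distance 1.
direction_offsets_13 <- function() {
  g <- neighbor_offsets(26L)
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Stationary Gaussian-correlated unit-variance noise via circular FFT
# convolution of white noise with a Gaussian kernel (no edge artifacts for
# stationary fields; much faster than spatial-domain smoothing).
correlated_noise_fft <- function(dm, scale_vox) {
  w <- array(rnorm(prod(dm)), dm)
  if (scale_vox <= 0) return(w)
  kern1 <- function(n, sigma) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(dm[1], scale_vox), kern1(dm[2], scale_vox)),
             kern1(dm[3], scale_vox))
  out <- Re(stats::fft(stats::fft(w) * stats::fft(K), inverse = TRUE)) /
    prod(dm)
  s <- stats::sd(as.vector(out))
  if (s > 0) out / s else out
}

# Separable Gaussian smoothing with edge replication.
smooth_gaussian <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  dm <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gaussian_kernel1d(sigma[ax])
    pad <- (length(k) - 1L) / 2L
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    mp <- rbind(m[rep(1L, pad), , drop = FALSE], m,
                m[rep(nrow(m), pad), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    m <- as.matrix(f)[(pad + 1L):(pad + dp[1]), , drop = FALSE]
    a <- aperm(array(m, dp), order(perm))
  }
  a
}

# Connected components of an integer label array: voxels are connected when
# adjacent (26- or 6-connectivity) and share the same nonzero value.
# Implemented as vectorized min-label propagation with pointer jumping.
# Returns an integer array of component ids 1..C (0 = background).
label_components <- function(lab, connectivity = 26L) {
  dm <- dim(lab)
  pd <- dm + 2L
  p <- array(0L, pd)
  p[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- as.integer(lab)
  idx <- which(p != 0L)
  if (length(idx) == 0L) return(array(0L, dm))
  comp <- integer(prod(pd))
  comp[idx] <- idx
  offs <- neighbor_offsets(connectivity)
  loff <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  vals <- p[idx]
  # same-value neighbor pairs are fixed; precompute them once per offset
  pairs <- vector("list", length(loff))
  for (i in seq_along(loff)) {
    ni <- idx + loff[i]
    ok <- which(p[ni] == vals & p[ni] > 0L)
    pairs[[i]] <- cbind(ok, ni[ok])
  }
  repeat {
    cur <- comp[idx]
    prev <- cur
    for (pr in pairs) {
      nc <- comp[pr[, 2]]
      upd <- which(nc < cur[pr[, 1]])
      if (length(upd)) cur[pr[upd, 1]] <- nc[upd]
    }
    comp[idx] <- cur
    # pointer jumping accelerates long chains
    for (j in 1:3) {
      nxt <- comp[comp[idx]]
      if (all(nxt == comp[idx])) break
      comp[idx] <- nxt
    }
    if (all(comp[idx] == prev)) break
  }
  u <- comp[idx]
  ids <- match(u, sort(unique(u)))
  outp <- array(0L, pd)
  outp[idx] <- ids
  outp[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L), drop = FALSE]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same voxel or
#' sample set, used to score recovery of planted habitat structure.
#'
#' @param a,b integer vectors (or arrays) of equal length; compared elementwise.
#' @return Numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  exp_idx <- si * sj / comb2(n)
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}

# Stratified train/test split: indices of the training rows.
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  set.seed(seed)
  idx <- integer(0)
  for (lv in unique(y)) {
    w <- which(y == lv)
    n_tr <- round(length(w) * train_frac)
    idx <- c(idx, sample(w, n_tr))
  }
  sort(idx)
}

# Stratified fold assignment 1..k.
stratified_folds <- function(y, k = 5L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in unique(y)) {
    w <- sample(which(y == lv))
    fold[w] <- rep_len(seq_len(k), length(w))
  }
  fold
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}
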