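# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (loops instead of BLAS, direct formula
# transcriptions) so that agreement is informative.

# circular arc between two angles in degrees, [0, 180]
oracle_arc <- function(a, b) {
  d <- abs((a - b) %% 360)
  ifelse(d > 180, 360 - d, d)
}

# loop-based torus KDE on a small grid
naive_kde <- function(samples, bandwidth, grid_size) {
  grid <- -180 + (0:(grid_size - 1)) * (360 / grid_size)
  vals <- matrix(0, grid_size, grid_size)
  for (i in seq_len(grid_size)) for (j in seq_len(grid_size)) {
    d2 <- oracle_arc(grid[i], samples[, 1])^2 + oracle_arc(grid[j], samples[, 2])^2
    vals[i, j] <- sum(exp(-d2 / (2 * bandwidth^2)))
  }
  vals / sum(vals)
}

# brute-force BH: scan all i explicitly, strict rejection rule
brute_bh <- function(p, q) {
  M <- length(p)
  ps <- sort(p)
  i0 <- 0
  for (i in seq_len(M)) if (ps[i] <= q * i / M) i0 <- i
  if (i0 == 0) return(list(alpha = NA_real_, reject = rep(FALSE, M)))
  list(alpha = ps[i0], reject = p < ps[i0])
}

# independent greedy farthest-first traversal
greedy_fps <- function(st, tau, start = 1) {
  sel <- start
  uns <- setdiff(seq_len(nrow(st)), start)
  while (length(uns) > 0) {
    best <- Inf; pick <- NA
    for (j in uns) {
      m <- max(st[sel, j])
      if (m < best) { best <- m; pick <- j }
    }
    if (best > tau) break
    sel <- c(sel, pick)
    uns <- setdiff(uns, pick)
  }
  sel
}

# longest common subsequence length by dynamic programming
lcs_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  m <- matrix(0L, length(x) + 1, length(y) + 1)
  for (i in seq_along(x)) for (j in seq_along(y))
    m[i + 1, j + 1] <- if (x[i] == y[j]) m[i, j] + 1L
                       else max(m[i + 1, j], m[i, j + 1])
  m[length(x) + 1, length(y) + 1]
}

# exhaustive global affine-gap alignment score for tiny strings; a length-L
# gap costs open + L * extend (the implementation's convention)
brute_align_score <- function(a, b, sub, open = 10, extend = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y))
      best <- max(best, sub[x[i], y[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(x))
      best <- max(best,
                  -(if (prev == "d") extend else open + extend) +
                    rec(i + 1, j, "d"))
    if (j <= length(y))
      best <- max(best,
                  -(if (prev == "i") extend else open + extend) +
                    rec(i, j + 1, "i"))
    best
  }
  rec(1, 1, "m")
}

# distance matrix implied by the Gaussian embedding model:
# d(c,c')^2 = ||mu - mu'||^2 + 2 (sigma^2 + sigma'^2), hence d(c,c) = 2 sigma
gaussian_model_distances <- function(mu, sigma) {
  n <- nrow(mu)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- sqrt(sum((mu[i, ] - mu[j, ])^2) +
                      2 * (sigma[i]^2 + sigma[j]^2))
  d
}

# circular standard deviation (degrees) of a sample of angles (degrees)
circ_sd <- function(theta) {
  r <- sqrt(mean(sin(theta * pi / 180))^2 + mean(cos(theta * pi / 180))^2)
  sqrt(-2 * log(r)) * 180 / pi
}
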