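#' Grid of angle bins used for density estimation
#'
#' Bin left-edges at -180 + k * (360 / grid_size), k = 0 .. grid_size - 1,
#' covering [-180, 180) per axis. For the default 128 bins the bin width is
#' 360/128 = 2.8125 degrees.
#'
#' @param grid_size integer number of bins per axis.
#' @return numeric vector of grid-point angles in degrees.
#' @export
density_grid <- function(grid_size = 128L) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("'grid_size' must be >= 2")
  -180 + (seq_len(grid_size) - 1L) * (360 / grid_size)
}

# Gaussian kernel of the circular arc distance between each sample angle and
# each grid angle: exp(-arc^2 / (2 bw^2)). Returns an n x grid_size matrix.
# The 2-D kernel exp(-tord^2 / 2 bw^2) factorizes over the phi and psi arcs,
# so a torus KDE is the normalized cross-product of the two kernel matrices.
.kernel_matrix <- function(angles, grid, bandwidth) {
  d <- .arc_dist(outer(angles, grid, "-"))
  exp(-d^2 / (2 * bandwidth^2))
}

#' Kernel density estimate of a dihedral-angle sample on the torus
#'
#' Estimates the joint (phi, psi) density on a wrap-around grid by placing a
#' Gaussian kernel K(x) = exp(-x^2 / (2 sigma^2)) on the torus distance
#' between every sample and every grid point, then normalizing the grid to
#' unit total mass. Applying the kernel to the wrap-around distance lets
#' density mass flow across the +/-180 degree seam.
#'
#' @param samples dihedral pairs (matrix or data.frame with columns phi, psi).
#' @param bandwidth kernel standard deviation sigma, degrees (default 2).
#' @param grid_size bins per axis (default 128).
#' @return object of class `torus_density`: list with `values` (grid_size x
#'   grid_size matrix, rows indexed by phi, columns by psi, summing to 1),
#'   `grid`, `grid_size` and `bandwidth`.
#' @export
estimate_density <- function(samples, bandwidth = 2, grid_size = 128L) {
  samples <- .as_dihedral_matrix(samples)
  if (nrow(samples) == 0L) stop("'samples' must be non-empty")
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("'bandwidth' must be > 0")
  grid <- density_grid(grid_size)
  kphi <- .kernel_matrix(samples[, 1], grid, bandwidth)
  kpsi <- .kernel_matrix(samples[, 2], grid, bandwidth)
  vals <- crossprod(kphi, kpsi)
  vals <- vals / sum(vals)
  structure(list(values = vals, grid = grid,
                 grid_size = as.integer(grid_size), bandwidth = bandwidth),
            class = "torus_density")
}

#' @export
print.torus_density <- function(x, ...) {
  cat(sprintf("torus density: %d x %d grid (bin %.4f deg), bandwidth %g deg\n",
              x$grid_size, x$grid_size, 360 / x$grid_size, x$bandwidth))
  invisible(x)
}

.check_compatible <- function(f, g) {
  stopifnot(inherits(f, "torus_density"), inherits(g, "torus_density"))
  if (f$grid_size != g$grid_size || f$bandwidth != g$bandwidth)
    stop("densities must share grid_size and bandwidth")
}

#' L1 distance between two torus densities
#'
#' The sum over all grid cells of the absolute difference between two
#' unit-mass discrete densities. Ranges from 0 (identical) to 2 (disjoint
#' support); equals twice the total-variation distance.
#'
#' @param f,g `torus_density` objects on the same grid and bandwidth.
#' @return non-negative scalar in [0, 2].
#' @export
l1_distance <- function(f, g) {
  .check_compatible(f, g)
  sum(abs(f$values - g$values))
}

#' Super-level-set threshold containing a given probability mass
#'
#' Finds the largest threshold tau such that the cells with density >= tau
#' hold at least `lambda_mass` of the total probability (the smallest
#' super-level set covering that mass; cells tied at tau are all included).
#'
#' @param f a `torus_density`.
#' @param lambda_mass target mass fraction in (0, 1).
#' @return scalar threshold tau.
#' @export
level_threshold <- function(f, lambda_mass) {
  stopifnot(inherits(f, "torus_density"))
  if (!is.numeric(lambda_mass) || lambda_mass <= 0 || lambda_mass >= 1)
    stop("'lambda_mass' must be in (0, 1)")
  v <- sort(as.vector(f$values), decreasing = TRUE)
  cs <- cumsum(v)
  v[which(cs >= lambda_mass)[1]]
}

#' Binary mask of the lambda-super-level set of a density
#'
#' @param f a `torus_density`.
#' @param lambda_mass mass fraction in (0, 1).
#' @return logical grid_size x grid_size matrix, TRUE where f >= tau.
#' @export
super_level_mask <- function(f, lambda_mass) {
  f$values >= level_threshold(f, lambda_mass)
}

#' Write a torus density as a plain-text matrix
#'
#' A small header (grid size, bandwidth) followed by one row per phi bin.
#'
#' @param f a `torus_density`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density <- function(f, path) {
  stopifnot(inherits(f, "torus_density"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# grid_size: %d", f$grid_size),
               sprintf("# bandwidth: %.17g", f$bandwidth)), con)
  utils::write.table(f$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a torus density written by [write_density()]
#'
#' @param path input file path.
#' @return a `torus_density`.
#' @export
read_density <- function(path) {
  hdr <- readLines(path, n = 2L)
  gs <- as.integer(sub("# grid_size: ", "", hdr[1], fixed = TRUE))
  bw <- as.numeric(sub("# bandwidth: ", "", hdr[2], fixed = TRUE))
  vals <- as.matrix(utils::read.table(path, skip = 2L))
  dimnames(vals) <- NULL
  structure(list(values = vals, grid = density_grid(gs),
                 grid_size = gs, bandwidth = bw),
            class = "torus_density")
}
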