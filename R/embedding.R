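#' Uncertainty-aware multidimensional scaling of a codon distance matrix
#'
#' Embeds each codon as an isotropic 2-D normal N(mu_c, sigma_c^2 I): the
#' location carries the inter-codon distances and the scale the estimation
#' noise. The scales come from the self-distance diagonal, sigma_c = 0.5 *
#' d(c, c); the squared target distances for the locations are d^2(c, c') -
#' 0.5 * (d^2(c, c) + d^2(c', c')), clamped at zero before the square root,
#' and the locations are solved by classical (Torgerson) MDS. On input built
#' exactly from that Gaussian model the recovery is exact up to rotation and
#' reflection.
#'
#' @param raw_distances square matrix of bootstrap-mean distances including
#'   the self-distance diagonal (e.g. from [distance_matrix()]).
#' @param literal_delta use the alternative target-distance expression with
#'   d^2(c, c') inside the subtracted average (symmetrized); default FALSE.
#' @return object of class `embedding_layout`: list with `locations` (n x 2,
#'   centered), `scales` (sigma_c) and the target distance matrix `delta`.
#' @export
uncertainty_mds <- function(raw_distances, literal_delta = FALSE) {
  d <- as.matrix(raw_distances)
  if (nrow(d) != ncol(d)) stop("'raw_distances' must be square")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  sigma <- 0.5 * diag(d)
  d2 <- d^2
  self2 <- diag(d2)
  delta2 <- if (literal_delta) {
    m <- d2 - 0.5 * (outer(self2, rep(1, nrow(d))) + d2)
    (m + t(m)) / 2
  } else {
    d2 - 0.5 * outer(self2, self2, "+")
  }
  delta <- sqrt(pmax(delta2, 0))
  diag(delta) <- 0
  k <- min(2L, nrow(d) - 1L)
  loc <- stats::cmdscale(delta, k = k)
  if (ncol(loc) < 2L) loc <- cbind(loc, matrix(0, nrow(d), 2L - ncol(loc)))
  loc <- sweep(loc, 2L, colMeans(loc))
  dimnames(loc) <- list(ids, c("x", "y"))
  structure(list(locations = loc, scales = stats::setNames(sigma, ids),
                 delta = delta),
            class = "embedding_layout")
}

#' Confidence-banded super-level contours of a dihedral sample
#'
#' Bootstraps B resamples of size min(N, n_max), estimates a torus KDE from
#' each, and averages them into a mean density whose lambda-super-level sets
#' give the plotted contours. For the confidence bands, each bootstrap
#' density's own lambda-super-level set is turned into a binary image; the
#' images are averaged, and the band is the region where the average lies
#' strictly between alpha and 1 - alpha.
#'
#' @param samples dihedral-pair matrix.
#' @param levels mass fractions lambda (default c(0.1, 0.5, 0.9)).
#' @param alpha band confidence parameter (default 0.1).
#' @param B bootstrap count (default 1000).
#' @param n_max resample-size cap (default 200).
#' @param bandwidth,grid_size KDE parameters.
#' @param seed optional master seed.
#' @return object of class `contour_set`: list with `levels`, `alpha`, `B`,
#'   `N`, `density` (the averaged `torus_density`), `mean_masks` (per-level
#'   super-level masks of the averaged density), `mean_binary` (per-level
#'   averaged binary images) and `bands` (per-level logical band masks).
#' @export
confidence_contours <- function(samples, levels = c(0.1, 0.5, 0.9),
                                alpha = 0.1, B = 1000L, n_max = 200L,
                                bandwidth = 2, grid_size = 128L,
                                seed = NULL) {
  samples <- .as_dihedral_matrix(samples)
  if (nrow(samples) == 0L) stop("'samples' must be non-empty")
  levels <- sort(levels)
  N <- min(nrow(samples), n_max)
  g <- as.integer(grid_size)
  acc_density <- matrix(0, g, g)
  acc_binary <- lapply(levels, function(l) matrix(0, g, g))
  for (b in seq_len(B)) {
    idx <- with_seed(child_seed(seed, b),
                     sample.int(nrow(samples), N, replace = TRUE))
    fb <- estimate_density(samples[idx, , drop = FALSE], bandwidth, g)
    acc_density <- acc_density + fb$values
    for (li in seq_along(levels))
      acc_binary[[li]] <- acc_binary[[li]] + super_level_mask(fb, levels[li])
  }
  avg <- structure(list(values = acc_density / B, grid = density_grid(g),
                        grid_size = g, bandwidth = bandwidth),
                   class = "torus_density")
  avg$values <- avg$values / sum(avg$values)
  mean_binary <- lapply(acc_binary, function(m) m / B)
  names(mean_binary) <- as.character(levels)
  mean_masks <- lapply(levels, function(l) super_level_mask(avg, l))
  names(mean_masks) <- as.character(levels)
  bands <- lapply(mean_binary, function(m) m > alpha & m < 1 - alpha)
  structure(list(levels = levels, alpha = alpha, B = as.integer(B), N = N,
                 density = avg, mean_masks = mean_masks,
                 mean_binary = mean_binary, bands = bands),
            class = "contour_set")
}

#' Write a binary or real-valued grid mask as a plain-text matrix
#'
#' @param mask matrix (logical or numeric).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask * 1, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.open_device <- function(path, width, height) {
  if (grepl("\\.svg$", path, ignore.case = TRUE))
    grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 96, height = height * 96)
}

#' Plot confidence-banded Ramachandran contours
#'
#' One panel per codon: the shaded confidence bands and, on top, the contour
#' lines of the averaged density containing each requested probability mass.
#'
#' @param contour_sets named list of `contour_set` objects (name = codon).
#' @param path output image path (`.png` or `.svg`).
#' @return `path`, invisibly.
#' @export
plot_ramachandran <- function(contour_sets, path) {
  if (length(contour_sets) == 0L) stop("no contour sets to plot")
  stopifnot(all(vapply(contour_sets, inherits, logical(1), "contour_set")))
  n <- length(contour_sets)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  .open_device(path, 4 * nc, 4 * nr)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  for (nm in names(contour_sets)) {
    cs <- contour_sets[[nm]]
    grid <- cs$density$grid
    graphics::plot(NA, xlim = c(-180, 180), ylim = c(-180, 180),
                   xlab = expression(phi), ylab = expression(psi), main = nm,
                   asp = 1)
    shade <- grDevices::grey(0.75)
    for (li in seq_along(cs$levels)) {
      band <- cs$bands[[li]]
      graphics::image(grid, grid, band * 1,
                      col = c(grDevices::rgb(1, 1, 1, 0),
                              grDevices::rgb(0.3, 0.5, 0.9, 0.25)),
                      add = TRUE, useRaster = TRUE)
      tau <- level_threshold(cs$density, cs$levels[li])
      graphics::contour(grid, grid, cs$density$values, levels = tau,
                        drawlabels = FALSE, add = TRUE, col = shade,
                        lwd = 1.5)
    }
  }
  invisible(path)
}

#' Plot sorted p-values against the Benjamini-Hochberg threshold line
#'
#' Sorted p-values by rank, the q * i / M rejection curve, and the rejected
#' tests highlighted.
#'
#' @param p_values numeric p-values (or a `codon_test_results` object, in
#'   which case one curve per structure class is drawn).
#' @param q FDR level.
#' @param path output image path.
#' @param textbook use the textbook step-up rejection rule.
#' @return `path`, invisibly.
#' @export
plot_pvalue_bh_curve <- function(p_values, q, path, textbook = FALSE) {
  sets <- if (inherits(p_values, "codon_test_results"))
    split(p_values$results$p_value, p_values$results$ss)
  else list(all = p_values)
  .open_device(path, 5 * length(sets), 5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(sets)), mar = c(4, 4, 2, 1))
  for (nm in names(sets)) {
    p <- sets[[nm]]
    dec <- bh_procedure(p, q = q, textbook = textbook)
    M <- length(p)
    ord <- order(p)
    graphics::plot(seq_len(M), p[ord], log = "y", pch = 19, cex = 0.6,
                   col = ifelse(dec$reject[ord], "forestgreen", "grey30"),
                   xlab = "rank", ylab = "p-value", main = nm)
    graphics::lines(seq_len(M), q * seq_len(M) / M, col = "red", lwd = 2)
    if (dec$i0 > 0L)
      graphics::abline(h = dec$alpha_M, lty = 2, col = "grey60")
  }
  invisible(path)
}

#' Scatter plot of an uncertainty-aware MDS layout
#'
#' Codon locations with a circle of radius sigma_c (the self-distance-derived
#' uncertainty) around each.
#'
#' @param layout an `embedding_layout`.
#' @param path output image path.
#' @return `path`, invisibly.
#' @export
plot_embedding <- function(layout, path) {
  stopifnot(inherits(layout, "embedding_layout"))
  loc <- layout$locations
  r <- layout$scales
  lim <- range(c(loc[, 1] - r, loc[, 1] + r, loc[, 2] - r, loc[, 2] + r))
  .open_device(path, 5, 5)
  on.exit(grDevices::dev.off())
  graphics::plot(loc, xlim = lim, ylim = lim, asp = 1, pch = 19,
                 xlab = "MDS 1", ylab = "MDS 2")
  graphics::symbols(loc[, 1], loc[, 2], circles = r, inches = FALSE,
                    add = TRUE, fg = "grey50")
  graphics::text(loc, labels = rownames(loc), pos = 3, cex = 0.8)
  invisible(path)
}
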