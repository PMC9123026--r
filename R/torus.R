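#' Wrap an angle into the canonical interval (-180, 180]
#'
#' Backbone dihedral angles live on a circle: values that differ by a full
#' turn are the same angle. All angles in this package are kept in degrees in
#' the half-open interval (-180, 180], so that the wrap point is at +/-180 and
#' -180 canonicalizes to 180.
#'
#' @param theta numeric vector of angles in degrees (any finite value).
#' @return numeric vector congruent to `theta` modulo 360, in (-180, 180].
#' @examples
#' wrap_angle(190)   # -170
#' wrap_angle(-180)  # 180
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric")
  w <- theta %% 360
  w[w > 180] <- w[w > 180] - 360
  # 180 %% 360 == 180 stays; exact -180 maps to 180 via the modulo above
  w
}

#' Assemble a matrix of dihedral-angle pairs
#'
#' A convenience constructor for the (phi, psi) sample representation used
#' throughout the package: a numeric matrix with columns `phi` and `psi`,
#' both wrapped to (-180, 180].
#'
#' @param phi,psi numeric vectors of equal length, degrees.
#' @return numeric matrix with columns `phi`, `psi`.
#' @export
dihedral_pairs <- function(phi, psi) {
  if (length(phi) != length(psi))
    stop("'phi' and 'psi' must have equal length")
  cbind(phi = wrap_angle(phi), psi = wrap_angle(psi))
}

.as_dihedral_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("phi", "psi")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L,
                                   dimnames = list(NULL, c("phi", "psi")))
  if (ncol(x) != 2L) stop("dihedral samples must have two columns (phi, psi)")
  storage.mode(x) <- "double"
  colnames(x) <- c("phi", "psi")
  x
}

#' Circular mean of dihedral-angle pairs on the torus
#'
#' Computes the per-component circular mean atan2(sum sin, sum cos) of a set
#' of (phi, psi) pairs, respecting the wrap-around at +/-180 degrees. This is
#' the centroid used when aggregating the same residue over multiple crystal
#' structures.
#'
#' The circular mean is undefined when a component's resultant vector has
#' length (numerically) zero, e.g. for two exactly antipodal angles; this
#' raises an error so that callers can skip such degenerate positions.
#'
#' @param points matrix (or data.frame) of dihedral pairs, columns phi, psi.
#' @return named numeric vector `c(phi =, psi =)` in (-180, 180].
#' @examples
#' torus_mean(dihedral_pairs(c(170, -170), c(170, -130)))  # c(180, -160)
#' @export
torus_mean <- function(points) {
  points <- .as_dihedral_matrix(points)
  if (nrow(points) == 0L) stop("'points' must contain at least one pair")
  rad <- points * pi / 180
  s <- colSums(sin(rad))
  co <- colSums(cos(rad))
  if (any(sqrt(s^2 + co^2) < 1e-12 * nrow(points)))
    stop("circular mean undefined: zero resultant length (antipodal degeneracy)")
  wrap_angle(atan2(s, co) * 180 / pi)
}

# Arc distance on the circle for an angle difference in degrees, in [0, 180].
# acos(cos(.)) folds any difference onto the shorter arc.
.arc_dist <- function(delta_deg) {
  co <- cos(delta_deg * pi / 180)   # clamp in place to keep dim attributes
  co[co > 1] <- 1
  co[co < -1] <- -1
  acos(co) * 180 / pi
}

#' Distance between two points on the torus of dihedral angles
#'
#' The torus distance sqrt(arccos^2 cos(phi1 - phi2) + arccos^2 cos(psi1 -
#' psi2)): the Euclidean combination of the per-component shortest arcs, in
#' degrees. Each arc is in [0, 180], so the distance is in [0, 180 * sqrt(2)].
#'
#' @param p1,p2 dihedral pairs (length-2 vectors or single-row matrices).
#' @return non-negative distance in degrees.
#' @examples
#' torus_distance(c(175, 0), c(-175, 0))  # 10
#' @export
torus_distance <- function(p1, p2) {
  p1 <- .as_dihedral_matrix(p1); p2 <- .as_dihedral_matrix(p2)
  unname(sqrt(.arc_dist(p1[, 1] - p2[, 1])^2 +
                .arc_dist(p1[, 2] - p2[, 2])^2))
}
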