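## Minimum-image arithmetic and Kabsch superposition.  Orthorhombic boxes only:
## every routine here assumes box = c(Lx, Ly, Lz) edge lengths in nm.

#' Minimum-image displacement components
#'
#' @param d numeric vector/matrix of coordinate differences (nm).
#' @param box box edge lengths, recycled against columns of `d`.
#' @return displacements folded into `[-L/2, L/2)` per component.
#' @keywords internal
minImage <- function(d, box) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

# all pairwise minimum-image distances between rows of a (n x 3) and b (m x 3);
# returns n x m matrix.  Used by both the brute-force contact oracle and the
# cell list, so the two paths share one distance formula bit-for-bit.
miDistMatrix <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(a[, 3], b[, 3], "-"); dz <- dz - box[3] * round(dz / box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# make a particle group whole across periodic boundaries by wrapping every
# particle to its minimum image about the group's first particle
makeWhole <- function(coords, box) {
  ref <- coords[1, , drop = TRUE]
  d <- sweep(coords, 2, ref)
  sweep(minImage(d, box), 2, ref, "+")
}

# mass-weighted centre of mass of (possibly pre-wrapped) coordinates
massCOM <- function(coords, mass) {
  colSums(coords * mass) / sum(mass)
}

#' Kabsch rotation between two point sets
#'
#' Least-squares proper rotation `R` mapping the centred reference onto the
#' centred current coordinates (`current_i ~ R %*% reference_i` after
#' centring).  The smallest singular axis is negated when the raw solution is
#' a reflection, so `det(R) = +1` always.
#'
#' @param reference,current n x 3 matrices of paired coordinates (nm).
#' @return 3 x 3 proper rotation matrix.
#' @examples
#' th <- pi / 3
#' rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
#' ref <- matrix(rnorm(12), 4, 3)
#' R <- kabschRotation(ref, ref %*% t(rot))
#' max(abs(R - rot)) < 1e-9
#' @export
kabschRotation <- function(reference, current) {
  stopifnot(is.matrix(reference), is.matrix(current),
            ncol(reference) == 3, all(dim(reference) == dim(current)))
  if (nrow(reference) < 3)
    stop("Kabsch superposition needs at least 3 points")
  P <- sweep(reference, 2, colMeans(reference))
  Q <- sweep(current, 2, colMeans(current))
  if (qr(P)$rank < 2)
    stop("degenerate (collinear) reference geometry: rotation is not defined")
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (abs(det(s$v %*% t(s$u))) < .Machine$double.eps)
    stop("degenerate superposition: singular cross-covariance")
  if (d < 0 && s$d[2] - s$d[3] < 1e-12 * max(s$d))
    stop("degenerate superposition: reflected solution with tied singular values")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R
}

# rotation matrix for angle (rad) about a unit axis (Rodrigues)
axisAngleRotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
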