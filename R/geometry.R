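## Cartesian geometry primitives shared by every module. All coordinates are
## in Angstrom, all angles in degrees.

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

## wrap an angle difference into (-180, 180]
.wrapAngle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x == -180] <- 180
  x
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four points using the IUPAC sign
#' convention (positive when, looking from `p2` towards `p3`, the far bond
#' rotates clockwise relative to the near bond).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Cartesian, Angstrom).
#' @return Angle in degrees in the range (-180, 180].
#' @examples
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 1))
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("degenerate geometry: collinear points in dihedral")
  m1 <- .vcross(n1, .vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -.deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points
#'
#' @param p1,p2,p3 Numeric 3-vectors; the angle is at `p2`.
#' @return Angle in degrees in \[0, 180\].
#' @export
bondAngle <- function(p1, p2, p3) {
  u <- .vunit(p1 - p2)
  v <- .vunit(p3 - p2)
  .deg(acos(max(-1, min(1, sum(u * v)))))
}

## NeRF atom placement: position a new atom bonded to c, with bond length
## |X-c|, angle X-c-b, and dihedral X-c-b-a.
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  theta <- .rad(angle)
  phi <- .rad(dihedral)
  d <- c(-bond * cos(theta),
         bond * sin(theta) * cos(phi),
         bond * sin(theta) * sin(phi))
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- cbind(bc, .vcross(n, bc), n)
  as.numeric(c + m %*% d)
}

#' Coordinate RMSD between two atom sets paired by atom name
#'
#' Root-mean-square deviation over atoms paired by name, with no
#' superposition: the molecular environment is held fixed across the states
#' being compared, so raw coordinates are directly comparable.
#'
#' @param a,b Data frames with columns `name`, `x`, `y`, `z` (as in the
#'   `atoms` slot of a [PDBStructure-class]), or numeric matrices with three
#'   columns and atom names as row names.
#' @param names Optional character vector restricting the comparison to the
#'   given atom names.
#' @return RMSD in Angstrom.
#' @examples
#' a <- data.frame(name = c("N", "O"), x = c(0, 0), y = 0, z = 0)
#' b <- data.frame(name = c("N", "O"), x = c(3, 4), y = 0, z = 0)
#' coordinateRMSD(a, b)  # sqrt((9 + 16) / 2)
#' @export
coordinateRMSD <- function(a, b, names = NULL) {
  a <- .asNamedCoords(a)
  b <- .asNamedCoords(b)
  if (!is.null(names)) {
    a <- a[rownames(a) %in% names, , drop = FALSE]
    b <- b[rownames(b) %in% names, , drop = FALSE]
  }
  if (anyDuplicated(rownames(a)) || anyDuplicated(rownames(b)))
    stop("atom names must be unique within each side for name-based pairing")
  only_a <- setdiff(rownames(a), rownames(b))
  only_b <- setdiff(rownames(b), rownames(a))
  if (length(only_a) || length(only_b))
    stop("unpairable atoms: ",
         paste(c(only_a, only_b), collapse = ", "))
  d <- a - b[rownames(a), , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

.asNamedCoords <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3, !is.null(rownames(x)))
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("name", "x", "y", "z") %in% names(x)))
  m <- as.matrix(x[, c("x", "y", "z")])
  rownames(m) <- x$name
  m
}

## coordinate matrix (n x 3) from an atoms data.frame
.coordsOf <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

## all-pairs euclidean distances between two coordinate matrices
.crossDist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
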