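#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Å).
#' @return Distance in Å.
#' @examples
#' atom_distance(c(0, 0, 0), c(0, 0, 3.5))
#' @export
atom_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Angle at a vertex, in degrees
#'
#' The angle a–vertex–c, computed as the arccosine of the normalized dot
#' product of the two arm vectors; arguments to `acos` are clamped to
#' `[-1, 1]` so collinear arms are exact at 0/180 despite rounding.
#'
#' @param a,vertex,c Numeric 3-vectors (Å).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
#' @export
bond_angle <- function(a, vertex, c) {
  u <- a - vertex
  v <- c - vertex
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("bond_angle(): zero-length arm (point coincides with vertex)")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Van der Waals radii
#'
#' Radii of the elements the method touches, from the Bondi compilation
#' (Å). Packaged as data so users can substitute a different compilation:
#' pass a modified copy to [vdw_overlap()] or [detect_halogen_bonds()].
#'
#' @return A tibble with columns `element`, `radius`.
#' @export
vdw_radii <- function() {
  tribble(
    ~element, ~radius,
    "F",  1.47,
    "CL", 1.75,
    "BR", 1.85,
    "I",  1.98,
    "O",  1.52,
    "N",  1.55,
    "S",  1.80,
    "P",  1.80,
    "SE", 1.90,
    "C",  1.70
  )
}

#' Van der Waals overlap of a halogen-acceptor pair
#'
#' `(r_x + r_y) - d`: positive values mean the interatomic distance is
#' shorter than the sum of the Van der Waals radii (interpenetration).
#'
#' @param d Interatomic distance (Å). Vectorised.
#' @param element_x,element_y Element symbols (case-insensitive).
#' @param radii Radius table as from [vdw_radii()].
#' @return Overlap in Å.
#' @examples
#' vdw_overlap(3.30, "I", "O")
#' @export
vdw_overlap <- function(d, element_x, element_y, radii = vdw_radii()) {
  lookup <- setNames(radii$radius, toupper(radii$element))
  rx <- lookup[toupper(element_x)]
  ry <- lookup[toupper(element_y)]
  miss <- unique(c(element_x[is.na(rx)], element_y[is.na(ry)]))
  if (length(miss)) {
    abort(sprintf("vdw_overlap(): no Van der Waals radius for element(s): %s",
                  paste(miss, collapse = ", ")))
  }
  unname(rx + ry - d)
}

#' Centroid of an aromatic ring
#'
#' Unweighted arithmetic mean of the ring-atom positions; the centroid is
#' the acceptor point of a halogen-π interaction.
#'
#' @param ring_atoms A data frame with columns `x`, `y`, `z` (≥ 3 rows), or
#'   an n×3 numeric matrix.
#' @return A numeric 3-vector (Å).
#' @export
ring_centroid <- function(ring_atoms) {
  m <- if (is.matrix(ring_atoms)) ring_atoms
       else cbind(ring_atoms$x, ring_atoms$y, ring_atoms$z)
  if (nrow(m) < 3L) abort("ring_centroid(): a ring needs at least 3 atoms")
  colMeans(m)
}

#' Geometry of one halogen-bond candidate
#'
#' Computes the descriptors of a C–X··Y or C–X···Π candidate: the
#' halogen–acceptor distance `d`, the angle `theta1` at the halogen
#' (parent carbon – halogen – acceptor point), and, for atomic acceptors
#' only, the angle `theta2` at the acceptor (halogen – acceptor – covalent
#' neighbour) and the Van der Waals overlap. For π acceptors the acceptor
#' point is the ring centroid and `theta2` / `vdw_overlap` are undefined
#' (`NA`).
#'
#' @param x Halogen position (3-vector, Å).
#' @param x_parent Position of the carbon bonded to the halogen.
#' @param acceptor Acceptor-atom position, or the ring centroid for a π
#'   acceptor.
#' @param neighbor Position of the acceptor's covalent neighbour (atomic
#'   acceptors; `NULL` for π).
#' @param element_x,element_y Element symbols for the overlap (atomic
#'   acceptors; ignored for π).
#' @param pi_acceptor Is the acceptor a π system?
#' @param radii Van der Waals radius table.
#' @return A one-row tibble: `d`, `vdw_overlap`, `theta1`, `theta2`.
#' @export
compute_bond_geometry <- function(x, x_parent, acceptor, neighbor = NULL,
                                  element_x = NULL, element_y = NULL,
                                  pi_acceptor = FALSE, radii = vdw_radii()) {
  d <- atom_distance(x, acceptor)
  theta1 <- bond_angle(x_parent, x, acceptor)
  if (pi_acceptor) {
    return(tibble(d = d, vdw_overlap = NA_real_, theta1 = theta1,
                  theta2 = NA_real_))
  }
  if (is.null(neighbor)) {
    abort("compute_bond_geometry(): atomic acceptor requires its covalent neighbour (theta2 undefined otherwise)")
  }
  tibble(
    d = d,
    vdw_overlap = vdw_overlap(d, element_x, element_y, radii),
    theta1 = theta1,
    theta2 = bond_angle(x, acceptor, neighbor)
  )
}
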