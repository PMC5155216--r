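# Periodic-cell geometry: lattice matrices, wrapping, minimum-image
# displacements, mass density.

#' Build a simulation cell matrix
#'
#' The cell is the 3x3 matrix **h** whose columns are the lattice vectors
#' (A). Orthorhombic cells may be given as three edge lengths.
#'
#' @param x Either a length-3 numeric vector of orthorhombic edge lengths or
#'   a 3x3 matrix of column lattice vectors.
#' @return A 3x3 lattice matrix with positive volume.
#' @examples
#' h <- simulation_cell(c(29.72, 8.580, 8.580))
#' cell_volume(h)
#' @export
simulation_cell <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(3, 3)))
    h <- x
  } else {
    stopifnot(is.numeric(x), length(x) == 3)
    h <- diag(x, 3, 3)
  }
  if (det(h) <= 0) stop("cell must have positive volume (det h > 0)")
  unname(h)
}

#' @rdname simulation_cell
#' @param h A 3x3 lattice matrix.
#' @export
cell_volume <- function(h) {
  det(h)
}

#' @rdname simulation_cell
#' @export
is_orthorhombic <- function(h) {
  all(abs(h[row(h) != col(h)]) < 1e-10)
}

# Minimum-image displacement vectors for an n x 3 matrix of raw
# displacements. Orthorhombic cells use the closed form; triclinic cells
# fall back to a search over the 27 neighbour images (sufficient for cells
# that are not extremely skewed, which is all this package produces).
min_image_displacement <- function(dx, h) {
  dx <- matrix(dx, ncol = 3)
  if (is_orthorhombic(h)) {
    L <- diag(h)
    for (k in 1:3) dx[, k] <- dx[, k] - L[k] * round(dx[, k] / L[k])
    return(dx)
  }
  # triclinic: reduce via fractional rounding, then check neighbour images
  s <- dx %*% t(solve(h))
  s <- s - round(s)
  dx <- s %*% t(h)
  best <- dx
  bestd <- rowSums(dx^2)
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    if (a == 0 && b == 0 && cc == 0) next
    shift <- h %*% c(a, b, cc)
    cand <- sweep(dx, 2, -as.numeric(shift))
    d <- rowSums(cand^2)
    sel <- d < bestd
    if (any(sel)) {
      best[sel, ] <- cand[sel, , drop = FALSE]
      bestd[sel] <- d[sel]
    }
  }
  best
}

#' Minimum-image distance between two atoms of a frame
#'
#' Shortest distance between atoms `i` and `j` over all periodic images of
#' the cell.
#'
#' @param frame An [md_frame()] (or any list with `positions` and `cell`).
#' @param i,j Atom indices (1-based, distinct).
#' @return Distance in A.
#' @examples
#' f <- md_frame(c("H", "H"), rbind(c(0.5, 0, 0), c(9.9, 0, 0)),
#'               simulation_cell(c(10, 10, 10)))
#' minimum_image_distance(f, 1, 2) # 0.6
#' @export
minimum_image_distance <- function(frame, i, j) {
  n <- nrow(frame$positions)
  if (!(i %in% seq_len(n)) || !(j %in% seq_len(n))) {
    stop("atom index out of range")
  }
  if (i == j) stop("minimum_image_distance requires two distinct atoms")
  d <- min_image_displacement(frame$positions[i, ] - frame$positions[j, ],
                              frame$cell)
  sqrt(sum(d^2))
}

# Wrap Cartesian positions into the primary cell.
wrap_positions <- function(pos, h) {
  s <- pos %*% t(solve(h))
  s <- s - floor(s)
  s %*% t(h)
}

#' Initial mass density of a composition in a cell
#'
#' rho0 = sum(m_i) / V with IUPAC standard atomic weights.
#'
#' @param composition Named integer vector of element counts, e.g.
#'   `c(Fe = 36, N = 32, O = 38, H = 76)`.
#' @param cell A 3x3 lattice matrix (or length-3 edge vector).
#' @return Mass density in g/cm^3.
#' @examples
#' initial_density(c(Fe = 36, N = 32, O = 38, H = 76),
#'                 c(29.72, 8.580, 8.580)) # about 2.386
#' @export
initial_density <- function(composition, cell) {
  if (length(composition) == 0 || sum(composition) == 0) {
    stop("empty composition")
  }
  h <- simulation_cell(if (is.matrix(cell)) cell else as.numeric(cell))
  m <- sum(atomic_masses(names(composition)) * as.numeric(composition))
  m / cell_volume(h) * .amua3_gcm3
}
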