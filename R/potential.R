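# Pairwise potential models (Lennard-Jones / Morse, energy-shifted at the
# cutoff) with optional harmonic intramolecular bonds. These stand in for
# the interatomic forces of the simulated material; all chemistry in the
# analysis fixtures is scripted geometrically, not emergent.

#' Define a pairwise potential model
#'
#' @param pair_style "lj" (4 eps ((s/r)^12-(s/r)^6)) or "morse"
#'   (D (1-exp(-a(r-r0)))^2 - D). Energies are shifted so the pair energy is
#'   zero at the cutoff, keeping dynamics conservative.
#' @param pair_params Named list keyed by unordered element pair (e.g.
#'   `"Fe-Fe"`). Each entry is a named numeric vector: for LJ
#'   `c(eps=, sigma=, cutoff=)` (eV, A, A); for Morse
#'   `c(D=, a=, r0=, cutoff=)`.
#' @param bonds Optional data.frame with columns `i`, `j`, `k` (eV/A^2) and
#'   `r0` (A) defining harmonic bonds `0.5 k (r - r0)^2`.
#' @return A `potential_model` object.
#' @examples
#' pot <- potential_model("lj",
#'   list("Fe-Fe" = c(eps = 0.1, sigma = 2.2, cutoff = 5.0)))
#' @export
potential_model <- function(pair_style = c("lj", "morse"),
                            pair_params = list(), bonds = NULL) {
  pair_style <- match.arg(pair_style)
  if (length(pair_params)) {
    names(pair_params) <- vapply(names(pair_params), canonical_pair, "")
    need <- if (pair_style == "lj") c("eps", "sigma", "cutoff")
            else c("D", "a", "r0", "cutoff")
    for (nm in names(pair_params)) {
      miss <- setdiff(need, names(pair_params[[nm]]))
      if (length(miss)) {
        stop("pair '", nm, "' missing parameter(s): ",
             paste(miss, collapse = ", "))
      }
    }
  }
  if (!is.null(bonds)) {
    stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)))
  }
  structure(list(pair_style = pair_style, pair_params = pair_params,
                 bonds = bonds),
            class = "potential_model")
}

# canonical unordered pair key "A-B" with A <= B alphabetically
canonical_pair <- function(key) {
  parts <- strsplit(key, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("pair key must look like 'A-B': ", key)
  paste(sort(parts), collapse = "-")
}

# Precompute the pair table for a fixed element list: indices, per-pair
# parameters. Returns NULL-free list used by evaluate_potential.
build_pair_table <- function(potential, elements) {
  n <- length(elements)
  if (n < 2 || length(potential$pair_params) == 0) {
    return(list(i = integer(), j = integer(),
                par = matrix(0, 0, 4), style = potential$pair_style))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  key <- paste(pmin(elements[i], elements[j]),
               pmax(elements[i], elements[j]), sep = "-")
  keep <- key %in% names(potential$pair_params)
  i <- i[keep]; j <- j[keep]; key <- key[keep]
  if (potential$pair_style == "lj") {
    par <- t(vapply(potential$pair_params[key], function(p)
      c(p[["eps"]], p[["sigma"]], p[["cutoff"]], 0), numeric(4)))
    # energy shift at cutoff
    sr6 <- (par[, 2] / par[, 3])^6
    par[, 4] <- 4 * par[, 1] * (sr6^2 - sr6)
  } else {
    par <- t(vapply(potential$pair_params[key], function(p)
      c(p[["D"]], p[["a"]], p[["r0"]], p[["cutoff"]]), numeric(4)))
  }
  list(i = i, j = j, par = unname(par), style = potential$pair_style)
}

# Energy, forces and virial for positions in cell h (orthorhombic assumed
# for dynamics). Returns energy (eV), forces (n x 3, eV/A), and the pair
# virial tensor diagonal W_kk = sum f_k dx_k (eV) plus full trace.
evaluate_potential <- function(positions, h, potential, pair_table = NULL,
                               elements = NULL) {
  n <- nrow(positions)
  if (is.null(pair_table)) {
    pair_table <- build_pair_table(potential, elements)
  }
  f <- matrix(0, n, 3)
  energy <- 0
  wdiag <- c(0, 0, 0)
  pt <- pair_table
  if (length(pt$i)) {
    dx <- min_image_displacement(positions[pt$i, , drop = FALSE] -
                                 positions[pt$j, , drop = FALSE], h)
    r2 <- rowSums(dx^2)
    r <- sqrt(r2)
    within <- if (pt$style == "lj") r < pt$par[, 3] else r < pt$par[, 4]
    if (any(within)) {
      dxw <- dx[within, , drop = FALSE]
      rw <- r[within]
      pw <- pt$par[within, , drop = FALSE]
      if (pt$style == "lj") {
        sr6 <- (pw[, 2] / rw)^6
        e <- 4 * pw[, 1] * (sr6^2 - sr6) - pw[, 4]
        # dE/dr = -24 eps (2 sr12 - sr6)/r ; force on i along +dx
        fmag <- 24 * pw[, 1] * (2 * sr6^2 - sr6) / rw
      } else {
        ex <- exp(-pw[, 2] * (rw - pw[, 3]))
        ecut <- pw[, 1] * ((1 - exp(-pw[, 2] * (pw[, 4] - pw[, 3])))^2 - 1)
        e <- pw[, 1] * ((1 - ex)^2 - 1) - ecut
        fmag <- -2 * pw[, 1] * pw[, 2] * (1 - ex) * ex
      }
      energy <- energy + sum(e)
      fij <- dxw * (fmag / rw)
      for (k in 1:3) {
        fk <- fij[, k]
        f[, k] <- f[, k] +
          unname(tapply2(fk, pt$i[within], n) - tapply2(fk, pt$j[within], n))
        wdiag[k] <- wdiag[k] + sum(fk * dxw[, k])
      }
    }
  }
  if (!is.null(potential$bonds) && nrow(potential$bonds)) {
    b <- potential$bonds
    dx <- min_image_displacement(positions[b$i, , drop = FALSE] -
                                 positions[b$j, , drop = FALSE], h)
    r <- sqrt(rowSums(dx^2))
    energy <- energy + sum(0.5 * b$k * (r - b$r0)^2)
    fmag <- -b$k * (r - b$r0) / r
    fij <- dx * fmag
    for (k in 1:3) {
      fk <- fij[, k]
      f[, k] <- f[, k] + tapply2(fk, b$i, n) - tapply2(fk, b$j, n)
      wdiag[k] <- wdiag[k] + sum(fk * dx[, k])
    }
  }
  list(energy = energy, forces = f, wdiag = wdiag, wtrace = sum(wdiag))
}

# fast grouped sum into a length-n vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
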