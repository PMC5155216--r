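# Molecular speciation: connected components of the lifetime-filtered bond
# graph, formula flags for the nitrogen/oxygen species of interest, first
# formation events, and Mulliken-charge bookkeeping from gross populations.

# parse "N2H5" / "NH3" into a named count vector
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula) {
    stop("cannot parse formula '", formula, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  out <- tapply(ct, el, sum)
  structure(as.integer(out), names = names(out))
}

format_formula <- function(counts) {
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts))]
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

# formulas of the named species the census flags
.species_flags <- list(
  NH3 = c(H = 3L, N = 1L), NH4 = c(H = 4L, N = 1L),
  N2H4 = c(H = 4L, N = 2L), N2H5 = c(H = 5L, N = 2L),
  H3O = c(H = 3L, O = 1L), OH = c(H = 1L, O = 1L),
  H2O = c(H = 2L, O = 1L), N2 = c(N = 2L)
)

# connected components of the bond graph at one frame; returns a membership
# integer vector over atoms
bond_components <- function(n, edges) {
  if (!nrow(edges)) return(seq_len(n))
  g <- igraph::make_graph(t(as.matrix(edges)), n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Molecular species census at one frame
#'
#' Connected components of the bonded graph are read as molecules and
#' labelled by formula. Flags count the named species: NH3 is a component
#' of exactly one N and three H (so in particular not bonded to Fe), NH4
#' its protonated topology, etc. Charge states cannot be assigned from
#' geometry alone; the census reports neutral formulas and protonation
#' topology only.
#'
#' @param bond_series A [detect_bonds()] result (use [full_bond_criteria()]
#'   so all covalent pairs are present).
#' @param frame_index Frame at which to take the census.
#' @return A `species_census`: list with `formulas` (per component),
#'   `members` (list of atom-id vectors), `formula_counts` (table),
#'   `flags` (named integer vector over NH3, NH4, N2H4, N2H5, H3O, OH,
#'   H2O, N2), `frame_index`, `time`.
#' @export
species_census <- function(bond_series, frame_index) {
  stopifnot(inherits(bond_series, "bond_series"))
  nf <- length(bond_series$bonded)
  stopifnot(frame_index >= 1, frame_index <= nf)
  el <- bond_series$elements
  n <- length(el)
  rows <- bond_series$bonded[[frame_index]]
  edges <- bond_series$pairs[rows, c("i", "j"), drop = FALSE]
  memb <- bond_components(n, edges)
  census_from_membership(memb, el, frame_index,
                         bond_series$times[frame_index])
}

census_from_membership <- function(memb, el, frame_index = NA, time = NA) {
  comp_ids <- sort(unique(memb))
  members <- split(seq_along(el), memb)
  formulas <- vapply(members, function(ix) {
    format_formula(table(el[ix]))
  }, "")
  flags <- vapply(.species_flags, function(f) {
    sum(formulas == format_formula(f))
  }, 0L)
  structure(list(formulas = unname(formulas), members = unname(members),
                 formula_counts = table(formulas), flags = flags,
                 frame_index = frame_index, time = time),
            class = "species_census")
}

#' @export
print.species_census <- function(x, ...) {
  cat("species_census at frame", x$frame_index,
      sprintf("(t = %.4g fs):", x$time), length(x$members), "components\n")
  fc <- sort(x$formula_counts, decreasing = TRUE)
  cat("  ", paste(sprintf("%s x%d", names(fc), as.integer(fc)),
                  collapse = ", "), "\n")
  fl <- x$flags[x$flags > 0]
  if (length(fl)) {
    cat("  flags:", paste(sprintf("%s=%d", names(fl), fl),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' Cumulative formation events of a target species
#'
#' Tracks every nitrogen atom (or, for N-free formulas, every atom of the
#' heaviest element in the formula) and fires one event the first time the
#' atom's molecular component attains the target formula. Later protonation
#' (e.g. NH3 to NH4) or further reaction never decrements the cumulative
#' count — the series is a cumulative quantity.
#'
#' @param bond_series A [detect_bonds()] result.
#' @param formula Target formula string, default "NH3".
#' @return List with `events` (data.frame time, frame, atom; one row per
#'   tracked atom, strictly increasing times) and `cumulative` (integer
#'   vector per frame).
#' @export
cumulative_formation_events <- function(bond_series, formula = "NH3") {
  stopifnot(inherits(bond_series, "bond_series"))
  target <- parse_formula(formula)
  target_str <- format_formula(target)
  el <- bond_series$elements
  n <- length(el)
  track_el <- if ("N" %in% names(target)) "N" else
    names(target)[which.max(atomic_masses(names(target)))]
  tracked <- which(el == track_el)
  if (!length(tracked)) {
    return(list(events = data.frame(time = numeric(), frame = integer(),
                                    atom = integer()),
                cumulative = integer(length(bond_series$bonded))))
  }
  nf <- length(bond_series$bonded)
  fired <- logical(n)
  ev_t <- numeric(); ev_f <- integer(); ev_a <- integer()
  cumulative <- integer(nf)
  prev_rows <- NULL
  memb <- NULL
  for (k in seq_len(nf)) {
    rows <- bond_series$bonded[[k]]
    if (is.null(memb) || !identical(rows, prev_rows)) {
      edges <- bond_series$pairs[rows, c("i", "j"), drop = FALSE]
      memb <- bond_components(n, edges)
      prev_rows <- rows
      # formula per component containing a tracked atom
      for (a in tracked[!fired[tracked]]) {
        ix <- which(memb == memb[a])
        if (format_formula(table(el[ix])) == target_str) {
          fired[a] <- TRUE
          ev_t <- c(ev_t, bond_series$times[k])
          ev_f <- c(ev_f, k)
          ev_a <- c(ev_a, a)
        }
      }
    }
    cumulative[k] <- sum(fired[tracked])
  }
  list(events = data.frame(time = ev_t, frame = ev_f, atom = ev_a),
       cumulative = cumulative)
}

#' Mulliken charges from gross populations
#'
#' Q_i(t) = Z0(element_i) - Z_i(t): the difference between the valence
#' electron count of the isolated neutral atom and the atom's gross
#' population. Negative Q marks reduced (electron-rich) atoms.
#'
#' @param Z Matrix of gross populations, atoms x times (or a vector).
#' @param elements Element symbol per atom (row).
#' @param Z0 Named vector of isolated-atom valence counts for the projector
#'   set in use; defaults N 5, O 6, H 1, Fe 8.
#' @return Charges with the same shape as `Z`.
#' @examples
#' mulliken_charge(c(5.4), "N") # -0.4: reduced nitrogen
#' @export
mulliken_charge <- function(Z, elements,
                            Z0 = c(N = 5, O = 6, H = 1, Fe = 8)) {
  Z <- as.matrix(Z)
  stopifnot(length(elements) == nrow(Z))
  bad <- setdiff(unique(elements), names(Z0))
  if (length(bad)) {
    stop("element(s) missing from the Z0 table: ",
         paste(bad, collapse = ", "))
  }
  out <- Z0[elements] - Z
  dimnames(out) <- dimnames(Z)
  out
}
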