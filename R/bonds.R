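# Lifetime-filtered bond detection and radial distribution functions.
#
# A pair counts as bonded once it has stayed within its cutoff distance
# continuously for the prescribed lifetime (default 2.42 fs = 10 frames at
# the 0.242 fs step), and the bond drops the moment the distance exceeds
# the cutoff. Cutoffs default to the values read off the first minima of
# the partial radial distribution functions of the 5 km/s shocked system.

.warned_pairs <- new.env(parent = emptyenv())

#' Bond criteria: cutoff table and lifetime
#'
#' @param cutoffs Named numeric vector of cutoff lengths (A), keyed by
#'   unordered element pair. Defaults: H-O 1.25, O-Fe 1.50, H-N 2.00,
#'   H-Fe 2.50.
#' @param lifetime Continuous-residence lifetime (fs), default 2.42.
#' @return A `bond_criteria` object.
#' @seealso [full_bond_criteria()] for the speciation table.
#' @export
bond_criteria <- function(cutoffs = c("H-O" = 1.25, "O-Fe" = 1.50,
                                      "H-N" = 2.00, "H-Fe" = 2.50),
                          lifetime = 2.42) {
  stopifnot(all(cutoffs > 0), lifetime > 0)
  names(cutoffs) <- vapply(names(cutoffs), canonical_pair, "")
  if (anyDuplicated(names(cutoffs))) stop("duplicate pair in cutoff table")
  structure(list(cutoffs = cutoffs, lifetime = lifetime),
            class = "bond_criteria")
}

#' Full covalent cutoff table for speciation
#'
#' The four shocked-system cutoffs plus the extra covalent pairs molecular
#' speciation needs (N-N 1.8 A, H-H 1.0 A, N-Fe 2.3 A; O-H is the same
#' unordered pair as H-O). All values are overridable.
#'
#' @inheritParams bond_criteria
#' @param extra Named numeric vector merged over the defaults.
#' @export
full_bond_criteria <- function(extra = NULL, lifetime = 2.42) {
  cut <- c("H-O" = 1.25, "O-Fe" = 1.50, "H-N" = 2.00, "H-Fe" = 2.50,
           "N-N" = 1.8, "H-H" = 1.0, "N-Fe" = 2.3)
  if (!is.null(extra)) {
    names(extra) <- vapply(names(extra), canonical_pair, "")
    cut[names(extra)] <- extra
  }
  bond_criteria(cut, lifetime)
}

#' Detect lifetime-filtered bonds along a trajectory
#'
#' A bond between atoms i and j (whose element pair appears in the cutoff
#' table) is reported from the first frame at which it completes L
#' consecutive within-cutoff frames, with L = round(lifetime / dt), and is
#' dropped immediately at the first frame beyond the cutoff. `lifetime`
#' must be an integer multiple of the frame spacing (to 1e-6 relative).
#'
#' @param trajectory An [md_trajectory()].
#' @param criteria A [bond_criteria()].
#' @return A `bond_series`: list with `pairs` (data.frame i, j, type),
#'   `bonded` (per-frame list of row indices into `pairs`), `counts`
#'   (n_frames x n_types matrix), `times`, `lifetime_frames`, `criteria`,
#'   `elements`.
#' @export
detect_bonds <- function(trajectory, criteria) {
  stopifnot(inherits(criteria, "bond_criteria"))
  nf <- n_frames(trajectory)
  dt <- if (nf > 1) trajectory_dt(trajectory) else criteria$lifetime
  Lf <- round(criteria$lifetime / dt)
  if (Lf < 1 || abs(Lf - criteria$lifetime / dt) > 1e-6 * Lf) {
    stop("lifetime (", criteria$lifetime,
         " fs) is not an integer number of frames at dt = ", dt, " fs")
  }
  el <- trajectory$elements
  present <- unique(el)
  # candidate pairs per type present in the table
  ii <- integer(); jj <- integer(); tt <- character()
  for (key in names(criteria$cutoffs)) {
    ab <- strsplit(key, "-", fixed = TRUE)[[1]]
    if (!all(ab %in% present)) next
    ia <- which(el == ab[1])
    ib <- which(el == ab[2])
    if (ab[1] == ab[2]) {
      if (length(ia) < 2) next
      cmb <- utils::combn(ia, 2)
      pa <- cmb[1, ]; pb <- cmb[2, ]
    } else {
      gr <- expand.grid(ia, ib)
      pa <- gr[, 1]; pb <- gr[, 2]
    }
    ii <- c(ii, pa); jj <- c(jj, pb); tt <- c(tt, rep(key, length(pa)))
  }
  types <- names(criteria$cutoffs)
  # element pairs present in the trajectory but absent from the table are
  # skipped; warn once per pair key per session
  combos <- outer(present, present, function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "-"))
  missing_keys <- setdiff(unique(as.character(combos)), types)
  new_keys <- setdiff(missing_keys, ls(.warned_pairs))
  if (length(new_keys)) {
    for (k in new_keys) assign(k, TRUE, envir = .warned_pairs)
    warning("no cutoff for element pair(s) ",
            paste(new_keys, collapse = ", "), "; skipped", call. = FALSE)
  }
  pairs <- data.frame(i = ii, j = jj, type = tt,
                      stringsAsFactors = FALSE)
  cut2 <- unname(criteria$cutoffs[tt])^2
  np <- length(ii)
  counts <- matrix(0L, nf, length(types), dimnames = list(NULL, types))
  bonded <- vector("list", nf)
  type_f <- factor(tt, levels = types)
  cnt <- integer(np)
  for (k in seq_len(nf)) {
    pos <- trajectory$positions[, , k]
    h <- trajectory$cells[, , k]
    d <- min_image_displacement(pos[ii, , drop = FALSE] -
                                pos[jj, , drop = FALSE], h)
    within <- rowSums(d * d) <= cut2
    cnt <- ifelse(within, cnt + 1L, 0L)
    on <- cnt >= Lf
    bonded[[k]] <- which(on)
    counts[k, ] <- as.integer(table(type_f[on]))
  }
  structure(list(pairs = pairs, bonded = bonded, counts = counts,
                 times = trajectory$times, lifetime_frames = Lf,
                 criteria = criteria, elements = el),
            class = "bond_series")
}

#' @export
print.bond_series <- function(x, ...) {
  nf <- length(x$bonded)
  cat("bond_series:", nf, "frames,", nrow(x$pairs), "candidate pairs,",
      "lifetime", x$lifetime_frames, "frames\n")
  cat("  final counts:",
      paste(sprintf("%s=%d", colnames(x$counts), x$counts[nf, ]),
            collapse = " "), "\n")
  invisible(x)
}

#' Bond-count time series for one pair type
#'
#' @param bond_series A [detect_bonds()] result.
#' @param pair_type Pair key, e.g. "H-O" (order-insensitive).
#' @return Data frame with `t` (fs) and integer `count`.
#' @export
count_bonds <- function(bond_series, pair_type) {
  key <- canonical_pair(pair_type)
  if (!key %in% colnames(bond_series$counts)) {
    stop("pair type '", pair_type, "' not in the criteria table")
  }
  data.frame(t = bond_series$times,
             count = as.integer(bond_series$counts[, key]))
}

#' Partial radial distribution function
#'
#' g_AB(r) histogrammed over frames, normalised so that an ideal gas gives
#' g = 1 at all r.
#'
#' @param trajectory An [md_trajectory()].
#' @param pair Character vector `c("A", "B")` of element symbols.
#' @param bin_width Bin width (A).
#' @param r_max Maximum distance (A); defaults to half the smallest cell
#'   edge of the first frame.
#' @param frame_stride Use every `frame_stride`-th frame.
#' @return Data frame with bin centre `r` and `g`.
#' @export
partial_rdf <- function(trajectory, pair, bin_width = 0.05, r_max = NULL,
                        frame_stride = 1L) {
  stopifnot(length(pair) == 2, bin_width > 0)
  el <- trajectory$elements
  ia <- which(el == pair[1]); ib <- which(el == pair[2])
  if (!length(ia) || !length(ib)) {
    stop("no atoms of requested element(s) ",
         paste(setdiff(pair, unique(el)), collapse = ", "))
  }
  same <- pair[1] == pair[2]
  if (same && length(ia) < 2) stop("need at least two atoms of ", pair[1])
  h1 <- trajectory$cells[, , 1]
  if (is.null(r_max)) r_max <- min(svd(h1)$d) / 2
  if (same) {
    cmb <- utils::combn(ia, 2); pa <- cmb[1, ]; pb <- cmb[2, ]
  } else {
    gr <- expand.grid(ia, ib); pa <- gr[, 1]; pb <- gr[, 2]
  }
  frames <- seq.int(1L, n_frames(trajectory), by = frame_stride)
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1L
  hist_acc <- numeric(nb)
  vol_acc <- 0
  for (k in frames) {
    pos <- trajectory$positions[, , k]
    h <- trajectory$cells[, , k]
    d <- min_image_displacement(pos[pa, , drop = FALSE] -
                                pos[pb, , drop = FALSE], h)
    r <- sqrt(rowSums(d * d))
    r <- r[r < r_max]
    hist_acc <- hist_acc + tabulate(pmin(floor(r / bin_width) + 1L, nb), nb)
    vol_acc <- vol_acc + cell_volume(h)
  }
  nfr <- length(frames)
  Vbar <- vol_acc / nfr
  rc <- breaks[-1] - bin_width / 2
  shell <- 4 * pi * rc^2 * bin_width
  npairs <- if (same) length(ia) * (length(ia) - 1) / 2
            else length(ia) * length(ib)
  # ideal-gas pair count in each shell
  ideal <- npairs * shell / Vbar
  data.frame(r = rc, g = hist_acc / (nfr * ideal))
}

#' First minimum of a radial distribution function
#'
#' Smooths g(r) with a 5-bin moving average, finds the first peak, and
#' returns the location of the following local minimum — the standard
#' bond-cutoff construction.
#'
#' @param rdf Data frame with columns `r` and `g` (e.g. [partial_rdf()]).
#' @param smooth Moving-average window (bins, odd).
#' @param min_peak Minimum smoothed g value for a bin to qualify as the
#'   first peak.
#' @return Radius of the first minimum (A).
#' @export
first_minimum <- function(rdf, smooth = 5, min_peak = 1) {
  g <- rdf$g
  n <- length(g)
  if (smooth > 1) {
    kern <- rep(1 / smooth, smooth)
    g <- stats::filter(g, kern, sides = 2)
    g[is.na(g)] <- rdf$g[is.na(g)]
    g <- as.numeric(g)
  }
  peak <- NA_integer_
  for (k in 2:(n - 1)) {
    if (g[k] >= g[k - 1] && g[k] >= g[k + 1] && g[k] >= min_peak) {
      peak <- k; break
    }
  }
  if (is.na(peak)) stop("no peak found in g(r)")
  for (k in (peak + 1):(n - 1)) {
    if (g[k] <= g[k - 1] && g[k] <= g[k + 1]) return(rdf$r[k])
  }
  stop("no minimum found after the first peak of g(r)")
}
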