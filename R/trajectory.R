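# Frame and trajectory containers plus extended-XYZ I/O.
#
# A trajectory stores positions as an n_atoms x 3 x n_frames array together
# with a 3 x 3 x n_frames array of lattice matrices, so per-frame cells
# (needed under shock compression) are first-class. Positions are kept as
# given by the producer; `unwrapped`, when present, carries the
# displacement-preserving coordinates used for mean-squared-displacement
# analysis (wrapping destroys displacement statistics).

#' Construct a single frame
#'
#' @param elements Character vector of element symbols.
#' @param positions n x 3 matrix of Cartesian coordinates (A).
#' @param cell 3x3 lattice matrix or length-3 orthorhombic edges (A).
#' @param velocities Optional n x 3 matrix (A/fs).
#' @param time Time stamp (fs).
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(elements, positions, cell, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(elements) == nrow(positions))
  cell <- simulation_cell(if (is.matrix(cell)) cell else as.numeric(cell))
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(all(dim(velocities) == dim(positions)))
  }
  structure(list(elements = as.character(elements), positions = positions,
                 velocities = velocities, cell = cell, time = time),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param elements Character vector of element symbols (constant over time).
#' @param positions n x 3 x n_frames array of Cartesian coordinates (A).
#' @param cells 3 x 3 x n_frames array of lattice matrices, or a single 3x3
#'   matrix / length-3 edge vector reused for every frame.
#' @param times Numeric vector of frame times (fs), strictly increasing.
#' @param velocities Optional n x 3 x n_frames array (A/fs).
#' @param unwrapped Optional n x 3 x n_frames array of unwrapped positions.
#' @param metadata Optional list (composition, seed, provenance, ...).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(elements, positions, cells, times,
                          velocities = NULL, unwrapped = NULL,
                          metadata = list()) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[2] == 3)
  n <- dim(positions)[1]
  nf <- dim(positions)[3]
  stopifnot(length(elements) == n, length(times) == nf)
  if (nf > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!(is.array(cells) && length(dim(cells)) == 3)) {
    h <- simulation_cell(if (is.matrix(cells)) cells else as.numeric(cells))
    cells <- array(h, dim = c(3, 3, nf))
  }
  stopifnot(all(dim(cells) == c(3, 3, nf)))
  structure(list(elements = as.character(elements), positions = positions,
                 velocities = velocities, cells = cells, times = times,
                 unwrapped = unwrapped, metadata = metadata),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  comp <- composition(x)
  cat("md_trajectory:", n_atoms(x), "atoms,", n_frames(x), "frames\n")
  cat("  composition:",
      paste(sprintf("%s:%d", names(comp), comp), collapse = " "), "\n")
  cat(sprintf("  time span: %.4g .. %.4g fs (dt = %.4g fs)\n",
              x$times[1], x$times[n_frames(x)], trajectory_dt(x)))
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj An `md_trajectory`.
#' @return `n_frames`/`n_atoms`: integer counts; `get_frame`: an
#'   [md_frame()]; `trajectory_dt`: the (uniform) time step in fs;
#'   `composition`: named count vector of elements.
#' @rdname trajectory-accessors
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' @rdname trajectory-accessors
#' @export
n_atoms <- function(traj) dim(traj$positions)[1]

#' @rdname trajectory-accessors
#' @param k Frame index (1-based).
#' @export
get_frame <- function(traj, k) {
  stopifnot(k >= 1, k <= n_frames(traj))
  md_frame(traj$elements, traj$positions[, , k],
           traj$cells[, , k],
           velocities = if (!is.null(traj$velocities))
             traj$velocities[, , k] else NULL,
           time = traj$times[k])
}

#' @rdname trajectory-accessors
#' @export
trajectory_dt <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-9 * max(abs(dts[1]), 1)) {
    stop("trajectory time step is not uniform")
  }
  dts[1]
}

#' @rdname trajectory-accessors
#' @param x A trajectory or frame.
#' @export
composition <- function(x) {
  tab <- table(x$elements)
  structure(as.integer(tab), names = names(tab))
}

# ---------------------------------------------------------------------------
# extended XYZ

#' Read an extended-XYZ trajectory
#'
#' Understands the de-facto standard dialect: per-frame comment line with a
#' `Lattice="..."` 9-number row-major record and
#' `Properties=species:S:1:pos:R:3[:vel:R:3]`.
#'
#' @param path Path to the file.
#' @return An [md_trajectory()]. Raw coordinates are stored in `unwrapped`;
#'   `positions` are wrapped into the cell.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  i <- 1L
  fi <- 0L
  elements <- NULL
  pos_list <- list()
  vel_list <- list()
  cell_list <- list()
  times <- numeric()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fi <- fi + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) {
      stop("malformed atom-count header at frame ", fi)
    }
    if (i + 1L > length(lines)) stop("truncated header at frame ", fi)
    comment <- lines[i + 1L]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    if (length(lat) != 1) stop("missing Lattice record at frame ", fi)
    latnum <- as.numeric(strsplit(gsub('Lattice="|"', "", lat),
                                  "[[:space:]]+")[[1]])
    latnum <- latnum[!is.na(latnum)]
    if (length(latnum) != 9) stop("malformed Lattice record at frame ", fi)
    # row-major: first three numbers are the first lattice vector, which is
    # column 1 of h
    h <- matrix(latnum, 3, 3)
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    t_fs <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else fi - 1
    has_vel <- grepl("vel:R:3", comment, fixed = TRUE)
    if (i + 1L + nat > length(lines)) {
      stop("truncated frame at frame ", fi)
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    ncols <- lengths(toks)
    need <- if (has_vel) 7L else 4L
    if (any(ncols < need)) {
      stop("malformed atom line in frame ", fi)
    }
    el <- vapply(toks, `[[`, "", 1L)
    num <- matrix(as.numeric(unlist(lapply(toks, function(tk)
      tk[2:need]))), nrow = nat, byrow = TRUE)
    if (anyNA(num)) stop("non-numeric coordinate in frame ", fi)
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements) || any(el != elements)) {
      stop("inconsistent atom count or ordering at frame ", fi)
    }
    pos_list[[fi]] <- num[, 1:3, drop = FALSE]
    if (has_vel) vel_list[[fi]] <- num[, 4:6, drop = FALSE]
    cell_list[[fi]] <- h
    times[fi] <- t_fs
    i <- i + 2L + nat
  }
  if (fi == 0L) stop("no frames found in ", path)
  n <- length(elements)
  raw <- array(unlist(pos_list), dim = c(n, 3, fi))
  cells <- array(unlist(cell_list), dim = c(3, 3, fi))
  wrapped <- raw
  for (k in seq_len(fi)) {
    wrapped[, , k] <- wrap_positions(raw[, , k], cells[, , k])
  }
  vels <- if (length(vel_list) == fi && fi > 0 && !is.null(vel_list[[1]])) {
    array(unlist(vel_list), dim = c(n, 3, fi))
  } else NULL
  md_trajectory(elements, wrapped, cells, times, velocities = vels,
                unwrapped = raw,
                metadata = list(source = path))
}

#' Write a trajectory as extended XYZ
#'
#' @param traj An [md_trajectory()] (or single [md_frame()]).
#' @param path Output path.
#' @param digits Significant digits for coordinates.
#' @param use_unwrapped Write unwrapped coordinates when available.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, path, digits = 10, use_unwrapped = FALSE) {
  if (inherits(traj, "md_frame")) {
    traj <- md_trajectory(traj$elements,
                          array(traj$positions,
                                dim = c(nrow(traj$positions), 3, 1)),
                          traj$cell, times = traj$time,
                          velocities = if (!is.null(traj$velocities))
                            array(traj$velocities,
                                  dim = c(nrow(traj$positions), 3, 1))
                          else NULL)
  }
  con <- file(path, "w")
  on.exit(close(con))
  pos <- if (use_unwrapped && !is.null(traj$unwrapped)) traj$unwrapped
         else traj$positions
  has_vel <- !is.null(traj$velocities)
  props <- if (has_vel) "species:S:1:pos:R:3:vel:R:3" else "species:S:1:pos:R:3"
  fmt <- paste0("%.", digits, "g")
  for (k in seq_len(n_frames(traj))) {
    h <- traj$cells[, , k]
    lat <- paste(sprintf(fmt, as.numeric(h)), collapse = " ")
    writeLines(as.character(n_atoms(traj)), con)
    writeLines(sprintf('Lattice="%s" Properties=%s Time=%s',
                       lat, props, sprintf(fmt, traj$times[k])), con)
    mat <- pos[, , k]
    body <- if (has_vel) cbind(mat, traj$velocities[, , k]) else mat
    writeLines(paste(traj$elements,
                     apply(body, 1, function(r)
                       paste(sprintf(fmt, r), collapse = " "))), con)
  }
  invisible(path)
}
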