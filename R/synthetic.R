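# Synthetic-data generators: every input the pipeline needs is produced
# here, seeded and bit-reproducible. Chemistry in fixtures is encoded by
# geometry alone (distances against cutoffs): scripted events reposition
# atoms, background jitter adds per-frame Gaussian noise that never crosses
# a bonded pair out of its cutoff (bonded distances are kept at least six
# jitter standard deviations inside the cutoff), and spurious bond creation
# is suppressed by the lifetime filter itself.

reference_composition <- function() c(Fe = 36L, N = 32L, O = 38L, H = 76L)

reference_cell <- function() simulation_cell(c(29.72, 8.580, 8.580))

# --- molecular building blocks (local coordinates, A) ----------------------

.tet_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                   c(-1, -1, 1)) / sqrt(3)

unit_water <- function(r_oh = 0.8, angle = 140) {
  a <- angle / 2 * pi / 180
  list(el = c("O", "H", "H"),
       xyz = rbind(c(0, 0, 0),
                   r_oh * c(cos(a), sin(a), 0),
                   r_oh * c(cos(a), -sin(a), 0)))
}

unit_oh <- function(r_oh = 0.8) {
  list(el = c("O", "H"), xyz = rbind(c(0, 0, 0), c(r_oh, 0, 0)))
}

unit_h3o <- function(r_oh = 0.8) {
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  list(el = c("O", "H", "H", "H"),
       xyz = rbind(c(0, 0, 0), r_oh * cbind(cos(ang), sin(ang), 0)))
}

unit_nh3 <- function(r_nh = 1.0) {
  list(el = c("N", "H", "H", "H"),
       xyz = rbind(c(0, 0, 0), r_nh * .tet_dirs[1:3, ]))
}

unit_n2 <- function(r_nn = 1.10) {
  list(el = c("N", "N"), xyz = rbind(c(0, 0, 0), c(r_nn, 0, 0)))
}

# O bridging 4 Fe twice (8 O-Fe bonds at 1.05 A, below the 1.50 A cutoff)
unit_fe4o2 <- function() {
  fe <- rbind(c(0.6, 0.6, 0), c(0.6, -0.6, 0),
              c(-0.6, 0.6, 0), c(-0.6, -0.6, 0))
  z <- sqrt(1.05^2 - 0.72)
  list(el = c(rep("Fe", 4), "O", "O"),
       xyz = rbind(fe, c(0, 0, z), c(0, 0, -z)))
}

# O bridging 3 Fe twice (6 O-Fe bonds)
unit_fe3o2 <- function() {
  r <- 1.2 / sqrt(3)
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  fe <- r * cbind(cos(ang), sin(ang), 0)
  z <- sqrt(1.05^2 - r^2)
  list(el = c(rep("Fe", 3), "O", "O"),
       xyz = rbind(fe, c(0, 0, z), c(0, 0, -z)))
}

unit_feo <- function() {
  list(el = c("Fe", "O"), xyz = rbind(c(0, 0, 0), c(1.05, 0, 0)))
}

unit_atom <- function(el) list(el = el, xyz = rbind(c(0, 0, 0)))

# Fe-H-Fe bridges in a chain: n_h H, n_h + 1 Fe, 2 n_h H-Fe bonds at 1.7 A
unit_feh_chain <- function(n_h = 9, spacing = 3.4) {
  fe_x <- (0:n_h) * spacing
  h_x <- fe_x[-1] - spacing / 2
  list(el = c(rep("Fe", n_h + 1), rep("H", n_h)),
       xyz = rbind(cbind(fe_x, 0, 0), cbind(h_x, 0, 0)))
}

assemble_units <- function(units, centers, cell) {
  el <- character(); xyz <- NULL
  for (k in seq_along(units)) {
    el <- c(el, units[[k]]$el)
    xyz <- rbind(xyz, sweep(units[[k]]$xyz, 2, -centers[k, ]))
  }
  md_frame(el, xyz, cell)
}

#' Scripted bond-inventory fixture
#'
#' A static 182-atom arrangement (the reference Fe36/N2/H2O composition)
#' whose lifetime-filtered bond counts are, by construction, exactly
#' (H-O, O-Fe, H-N, H-Fe) = (43, 47, 24, 18): 19 intact waters and 5
#' hydroxyls (43 H-O), iron-oxide clusters totalling 47 O-Fe bonds, 8
#' ammonia molecules (24 H-N), and an Fe-H-Fe bridge chain (18 H-Fe),
#' plus 12 N2 and spectator atoms. Per-frame Gaussian jitter rides on top.
#'
#' @param duration Trajectory span (fs).
#' @param dt Frame spacing (fs).
#' @param jitter Per-atom, per-frame Gaussian displacement amplitude (A).
#' @param seed Integer seed.
#' @return An [md_trajectory()]; `metadata$expected_counts` records the
#'   engineered inventory.
#' @export
bond_inventory_fixture <- function(duration = 4000, dt = 0.242,
                                   jitter = 0.05, seed = 1) {
  cell <- simulation_cell(c(56, 56, 56))
  units <- c(replicate(19, unit_water(), simplify = FALSE),
             replicate(5, unit_oh(), simplify = FALSE),
             replicate(8, unit_nh3(), simplify = FALSE),
             replicate(12, unit_n2(), simplify = FALSE),
             replicate(5, unit_fe4o2(), simplify = FALSE),
             list(unit_fe3o2(), unit_feo(), unit_atom("O"),
                  unit_atom("Fe"), unit_atom("Fe")))
  grid <- as.matrix(expand.grid(seq(6, 42, by = 12), seq(6, 42, by = 12),
                                seq(6, 42, by = 12)))
  stopifnot(length(units) <= nrow(grid))
  frame <- assemble_units(units, grid[seq_along(units), , drop = FALSE],
                          cell)
  chain <- unit_feh_chain()
  frame <- md_frame(c(frame$elements, chain$el),
                    rbind(frame$positions,
                          sweep(chain$xyz, 2, -c(6, 50, 50))),
                    cell)
  stopifnot(identical(composition(frame)[names(reference_composition())],
                      reference_composition()))
  traj <- jitter_trajectory(frame, duration, dt, jitter, seed)
  traj$metadata$expected_counts <- c("H-O" = 43L, "Fe-O" = 47L,
                                     "H-N" = 24L, "Fe-H" = 18L)
  traj
}

# static frame + per-frame Gaussian jitter, seeded
jitter_trajectory <- function(frame, duration, dt, jitter, seed,
                              base_series = NULL) {
  nf <- round(duration / dt) + 1L
  n <- nrow(frame$positions)
  set.seed(seed)
  pos <- array(stats::rnorm(n * 3 * nf, sd = jitter), c(n, 3, nf))
  if (is.null(base_series)) {
    pos <- pos + as.numeric(frame$positions)
  } else {
    for (seg in base_series) {
      pos[, , seg$from:seg$to] <- pos[, , seg$from:seg$to] +
        as.numeric(seg$base)
    }
  }
  md_trajectory(frame$elements, pos, frame$cell, times = (0:(nf - 1)) * dt,
                metadata = list(seed = seed, jitter = jitter, dt = dt))
}

#' Event script for scripted reactive trajectories
#'
#' An event repositions one atom at a given time: its new position is an
#' offset from an anchor atom (or absolute when `anchor` is NA). Kinds
#' label the chemistry being emulated (proton_transfer, protonation,
#' bond_scission, adsorption); mechanically all kinds are repositionings.
#'
#' @param time Event times (fs).
#' @param kind Character vector of event kinds.
#' @param atom Atom moved (index).
#' @param anchor Anchor atom index or NA.
#' @param dx,dy,dz Offset from the anchor (A).
#' @return An `event_script` data.frame, ordered by time.
#' @export
event_script <- function(time, kind, atom, anchor = NA_integer_,
                         dx = 0, dy = 0, dz = 0) {
  kinds <- c("proton_transfer", "protonation", "bond_scission",
             "adsorption")
  if (!all(kind %in% kinds)) {
    stop("unknown event kind(s): ",
         paste(setdiff(kind, kinds), collapse = ", "))
  }
  n <- length(time)
  df <- data.frame(time = time, kind = kind, atom = atom,
                   anchor = rep_len(anchor, n), dx = rep_len(dx, n),
                   dy = rep_len(dy, n), dz = rep_len(dz, n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_script", "data.frame")
  df
}

#' Read/write an event script as YAML
#'
#' Schema: a list of events, each with fields `time` (fs), `kind`, `atom`,
#' optional `anchor`, and `offset` (3 numbers, A).
#'
#' @param script An [event_script()].
#' @param path File path.
#' @return `read_event_script` returns an [event_script()].
#' @export
write_event_script <- function(script, path) {
  ev <- lapply(seq_len(nrow(script)), function(k) {
    e <- script[k, ]
    list(time = e$time, kind = e$kind, atom = e$atom,
         anchor = if (is.na(e$anchor)) NULL else e$anchor,
         offset = c(e$dx, e$dy, e$dz))
  })
  yaml::write_yaml(list(events = ev), path)
  invisible(path)
}

#' @rdname write_event_script
#' @export
read_event_script <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$events)) stop("no 'events' list in ", path)
  ev <- raw$events
  event_script(
    time = vapply(ev, function(e) as.numeric(e$time), 0),
    kind = vapply(ev, function(e) as.character(e$kind), ""),
    atom = vapply(ev, function(e) as.integer(e$atom), 0L),
    anchor = vapply(ev, function(e)
      if (is.null(e$anchor)) NA_integer_ else as.integer(e$anchor), 0L),
    dx = vapply(ev, function(e) as.numeric(e$offset[1]), 0),
    dy = vapply(ev, function(e) as.numeric(e$offset[2]), 0),
    dz = vapply(ev, function(e) as.numeric(e$offset[3]), 0))
}

#' Scripted reactive trajectory
#'
#' Holds the initial geometry fixed except where events reposition atoms,
#' with per-frame Gaussian jitter on top. Deterministic given the seed.
#' Each event takes effect at the frame nearest its time; after an event
#' the minimum interatomic distance must remain >= 0.7 A, otherwise the
#' generator stops naming the offending event.
#'
#' @param initial_frame An [md_frame()].
#' @param script An [event_script()].
#' @param duration Trajectory span (fs).
#' @param dt Frame spacing (fs).
#' @param jitter Gaussian jitter amplitude (A).
#' @param seed Integer seed.
#' @return An [md_trajectory()].
#' @export
script_reactive_trajectory <- function(initial_frame, script,
                                       duration = 4000, dt = 0.242,
                                       jitter = 0.05, seed = 1) {
  nf <- round(duration / dt) + 1L
  if (nrow(script) && (min(script$time) < 0 ||
                       max(script$time) > duration)) {
    stop("event times must lie within the trajectory span")
  }
  base <- initial_frame$positions
  segs <- list()
  ev_frames <- if (nrow(script)) round(script$time / dt) + 1L else integer()
  bounds <- c(1L, ev_frames, nf + 1L)
  cur <- base
  for (k in seq_len(length(bounds) - 1L)) {
    if (k > 1L) {
      e <- script[k - 1L, ]
      anchor_pos <- if (is.na(e$anchor)) c(0, 0, 0) else cur[e$anchor, ]
      cur[e$atom, ] <- anchor_pos + c(e$dx, e$dy, e$dz)
      dmin <- min_pair_distance(cur, initial_frame$cell)
      if (dmin < 0.7) {
        stop("event ", k - 1L, " (", e$kind, " at ", e$time,
             " fs) brings atoms within ", signif(dmin, 3), " A")
      }
    }
    from <- bounds[k]; to <- bounds[k + 1L] - 1L
    if (from <= to) {
      segs[[length(segs) + 1L]] <- list(from = from, to = to, base = cur)
    }
  }
  traj <- jitter_trajectory(initial_frame, duration, dt, jitter, seed,
                            base_series = segs)
  traj$metadata$script <- script
  traj
}

min_pair_distance <- function(pos, cell) {
  n <- nrow(pos)
  cmb <- utils::combn(n, 2)
  d <- min_image_displacement(pos[cmb[1, ], , drop = FALSE] -
                              pos[cmb[2, ], , drop = FALSE], cell)
  sqrt(min(rowSums(d * d)))
}

#' Scripted ammonia-formation fixture
#'
#' Three N2 molecules, a pool of free hydrogens and one hydronium in a
#' large periodic box. For each requested formation time the script first
#' cleaves the N-N pair (the partner N is parked on a free site), then
#' teleports three hydrogens onto the tracked N so that the third N-H bond
#' completes its 10-frame lifetime exactly at the requested frame; one
#' product is later protonated to NH4 by a hydronium proton, which must
#' not change the cumulative NH3 count.
#'
#' @param times_ps Target formation times (ps).
#' @param protonation_ps Time of the NH3 -> NH4 proton transfer (ps); NA
#'   disables it.
#' @inheritParams script_reactive_trajectory
#' @return List with `trajectory`, `script`, `tracked_n` (atom ids) and
#'   `target_frames`.
#' @export
ammonia_event_fixture <- function(times_ps = c(1.343, 2.044, 3.674),
                                  protonation_ps = 2.5,
                                  duration = 4000, dt = 0.242,
                                  jitter = 0.05, seed = 1) {
  stopifnot(length(times_ps) >= 1)
  cell <- simulation_cell(c(30, 30, 30))
  kn <- length(times_ps)
  units <- c(replicate(kn, unit_n2(), simplify = FALSE),
             list(unit_h3o()),
             replicate(3 * kn, unit_atom("H"), simplify = FALSE))
  grid <- as.matrix(expand.grid(seq(5, 25, by = 10), seq(5, 25, by = 10),
                                seq(5, 25, by = 10)))
  need <- length(units) + kn # extra sites to park cleaved partners
  stopifnot(need <= nrow(grid))
  frame <- assemble_units(units, grid[seq_along(units), , drop = FALSE],
                          cell)
  park <- grid[seq.int(length(units) + 1L, need), , drop = FALSE]
  el <- frame$elements
  n_ids <- which(el == "N")           # pairs: (1,2), (3,4), ...
  h_free <- which(el == "H")[-(1:3)]  # first three H belong to the H3O
  h3o_h <- which(el == "H")[1:3]
  lifetime_frames <- 10L
  ev <- list()
  add <- function(...) ev[[length(ev) + 1L]] <<- list(...)
  for (k in seq_len(kn)) {
    tf <- round(times_ps[k] * 1000 / dt) + 1L # 1-based target frame
    na <- n_ids[2 * k - 1]; nb <- n_ids[2 * k]
    t_sciss <- (tf - 60L - 1L) * dt
    add(time = t_sciss, kind = "bond_scission", atom = nb,
        anchor = NA_integer_, off = park[k, ])
    hs <- h_free[(3 * k - 2):(3 * k)]
    arrive <- c(tf - 30L, tf - 30L, tf - (lifetime_frames - 1L))
    for (q in 1:3) {
      add(time = (arrive[q] - 1L) * dt, kind = "proton_transfer",
          atom = hs[q], anchor = na, off = .tet_dirs[q, ])
    }
  }
  if (!is.na(protonation_ps)) {
    add(time = round(protonation_ps * 1000 / dt) * dt,
        kind = "protonation", atom = h3o_h[1], anchor = n_ids[1],
        off = .tet_dirs[4, ])
  }
  script <- event_script(
    time = vapply(ev, `[[`, 0, "time"),
    kind = vapply(ev, `[[`, "", "kind"),
    atom = vapply(ev, `[[`, 0L, "atom"),
    anchor = vapply(ev, function(e) e$anchor %||% NA_integer_, 0L),
    dx = vapply(ev, function(e) e$off[1], 0),
    dy = vapply(ev, function(e) e$off[2], 0),
    dz = vapply(ev, function(e) e$off[3], 0))
  traj <- script_reactive_trajectory(frame, script, duration, dt, jitter,
                                     seed)
  list(trajectory = traj, script = script,
       tracked_n = n_ids[seq(1, 2 * kn, by = 2)],
       target_frames = round(times_ps * 1000 / dt) + 1L)
}

#' Brownian walker specification and trajectory
#'
#' Independent Gaussian displacements per atom and axis with variance
#' 2 D dt, the standard discrete Brownian fixture for testing the MSD
#' estimator. Coordinates are unwrapped.
#'
#' @param n_atoms Number of walkers.
#' @param D Diffusion coefficient (cm^2/s).
#' @param duration Span (fs).
#' @param dt Step (fs).
#' @param seed Integer seed.
#' @param element Element label for the walkers.
#' @return `brownian_spec`: the validated spec; `brownian_trajectory`: an
#'   [md_trajectory()] with `metadata$D_true`.
#' @export
brownian_spec <- function(n_atoms = 36, D = 2.35e-5, duration = 4000,
                          dt = 0.242, seed = 1, element = "Fe") {
  stopifnot(n_atoms >= 1, D >= 0, duration > dt, dt > 0)
  structure(list(n_atoms = n_atoms, D = D, duration = duration, dt = dt,
                 seed = seed, element = element), class = "brownian_spec")
}

#' @rdname brownian_spec
#' @param spec A `brownian_spec`.
#' @export
brownian_trajectory <- function(spec) {
  stopifnot(inherits(spec, "brownian_spec"))
  nf <- round(spec$duration / spec$dt) + 1L
  n <- spec$n_atoms
  D_int <- spec$D / .a2fs_cm2s # A^2/fs
  sd_step <- sqrt(2 * D_int * spec$dt)
  set.seed(spec$seed)
  steps <- matrix(stats::rnorm(3 * n * (nf - 1L), sd = sd_step), 3 * n)
  P <- cbind(0, t(apply(steps, 1, cumsum)))
  pos <- aperm(array(P, c(3, n, nf)), c(2, 1, 3))
  # start walkers on a loose grid inside a large box
  L <- 1000
  set.seed(spec$seed + 1L)
  origin <- matrix(stats::runif(3 * n, 100, 900), n, 3)
  pos <- pos + as.numeric(origin)
  md_trajectory(rep(spec$element, n), pos, c(L, L, L),
                times = (0:(nf - 1L)) * spec$dt,
                unwrapped = pos,
                metadata = list(D_true = spec$D, seed = spec$seed,
                                spec = spec))
}

#' Shock-profile state-table fixture
#'
#' Sigmoidal compression history V/V0(t) relaxing to `final_compression`
#' around `rise_time`, with P and Up derived from the instantaneous
#' compression through the jump relations, so every row satisfies them
#' identically.
#'
#' @param Vs Shock speed (km/s).
#' @param final_compression Asymptotic V/V0 in (0, 1).
#' @param rise_time Centre of the transition (fs).
#' @param width Transition width (fs); `rise_time/6` by default.
#' @param duration,dt Table span and spacing (fs).
#' @param rho0 Unshocked density (g/cm^3); defaults to the reference
#'   Fe36/16 N2/38 H2O cell.
#' @param P0 Unshocked pressure (GPa).
#' @return Data frame: t, V_ratio, P, Up.
#' @export
shock_profile_fixture <- function(Vs, final_compression, rise_time = 300,
                                  width = NULL, duration = 4000, dt = 4,
                                  rho0 = NULL, P0 = 0) {
  stopifnot(final_compression > 0, final_compression < 1)
  if (is.null(width)) width <- rise_time / 6
  if (is.null(rho0)) {
    rho0 <- initial_density(reference_composition(), reference_cell())
  }
  t <- seq(0, duration, by = dt)
  sig <- if (width <= 0) as.numeric(t >= rise_time)
         else 1 / (1 + exp(-(t - rise_time) / width))
  vr <- 1 - (1 - final_compression) * sig
  Up <- Vs * (1 - vr)
  P <- P0 + rho0 * Vs * Up
  data.frame(t = t, V_ratio = vr, P = P, Up = Up)
}

#' Build the reference shocked-system supercell
#'
#' 182 atoms: a 2 x 3 x 3 bcc Fe36 slab (a = 2.86 A) centred along x in
#' the 29.72 x 8.580 x 8.580 A cell, immersed in 38 waters with 16 N2
#' molecules substituted at random molecular sites (seeded rejection
#' sampling, minimum interatomic distance 0.7 A).
#'
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per site.
#' @return An [md_frame()].
#' @export
build_initial_system <- function(seed = 1, max_tries = 20000) {
  cell <- reference_cell()
  L <- diag(cell)
  a <- 2.86
  # bcc slab: 2 x 3 x 3 cells, 2 atoms per cell, centred in x
  cells <- as.matrix(expand.grid(0:1, 0:2, 0:2))
  base <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.5))
  fe <- NULL
  for (k in seq_len(nrow(cells))) {
    fe <- rbind(fe, sweep(base * a, 2, -as.numeric(cells[k, ]) * a))
  }
  fe[, 1] <- fe[, 1] + (L[1] - 2 * a) / 2
  set.seed(seed)
  n_sites <- 38 + 16
  # molecular centres on a jittered grid filling the water slabs either
  # side of the Fe slab (Fe x extent: 12.0 to 16.3 A)
  fe_lo <- (L[1] - 2 * a) / 2
  x_planes <- c(fe_lo - 10.0, fe_lo - 7.0, fe_lo - 4.0,
                fe_lo + 1.5 * a + 3.0, fe_lo + 1.5 * a + 6.0,
                fe_lo + 1.5 * a + 9.0, fe_lo + 1.5 * a + 12.0)
  yz <- a * (0:2) + a / 2
  grid <- as.matrix(expand.grid(x_planes, yz, yz))
  stopifnot(nrow(grid) >= n_sites)
  sites <- grid[sample.int(nrow(grid), n_sites), , drop = FALSE]
  sites <- sites + matrix(stats::runif(3 * n_sites, -0.15, 0.15),
                          n_sites, 3)
  n2_sites <- sample.int(n_sites, 16)
  el <- rep("Fe", nrow(fe))
  xyz <- fe
  for (s in seq_len(n_sites)) {
    # rejection-sample the molecular orientation until every new atom
    # keeps at least 0.72 A from everything already placed
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- random_unit_vector()
      if (s %in% n2_sites) {
        new_el <- c("N", "N")
        new_xyz <- rbind(sites[s, ] - 0.55 * u, sites[s, ] + 0.55 * u)
      } else {
        # water: O at the site, two H at 0.97 A, 104.5 degree angle
        v <- random_unit_vector()
        v <- v - sum(v * u) * u
        v <- v / sqrt(sum(v^2))
        a1 <- 104.5 / 2 * pi / 180
        new_el <- c("O", "H", "H")
        new_xyz <- rbind(sites[s, ],
                         sites[s, ] + 0.97 * (cos(a1) * u + sin(a1) * v),
                         sites[s, ] + 0.97 * (cos(a1) * u - sin(a1) * v))
      }
      dmin <- min(vapply(seq_len(nrow(new_xyz)), function(q) {
        d <- min_image_displacement(sweep(xyz, 2, new_xyz[q, ], "-"), cell)
        sqrt(min(rowSums(d^2)))
      }, 0))
      if (dmin >= 0.72) { ok <- TRUE; break }
    }
    if (!ok) stop("could not orient molecule at site ", s)
    el <- c(el, new_el)
    xyz <- rbind(xyz, new_xyz)
  }
  frame <- md_frame(el, wrap_positions(xyz, cell), cell)
  stopifnot(min_pair_distance(frame$positions, cell) >= 0.7)
  frame
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

#' Face-centred-cubic crystal frame
#'
#' Periodic fcc crystal, the standard fixture for the Lennard-Jones
#' dynamics tests.
#'
#' @param cells Integer vector: unit cells along x, y, z.
#' @param a Lattice constant (A).
#' @param element Element symbol.
#' @return An [md_frame()].
#' @export
fcc_crystal <- function(cells = c(2, 2, 2), a = 3.492, element = "Fe") {
  basis <- rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5),
                 c(0.5, 0.5, 0))
  grid <- as.matrix(expand.grid(seq_len(cells[1]) - 1,
                                seq_len(cells[2]) - 1,
                                seq_len(cells[3]) - 1))
  pos <- NULL
  for (k in seq_len(nrow(grid))) {
    pos <- rbind(pos, sweep(basis, 2, -as.numeric(grid[k, ])) * a)
  }
  md_frame(rep(element, nrow(pos)), pos, cells * a)
}
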