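test_that("lifetime filter reports bonds only after L consecutive frames", {
  nf <- 30
  pos <- array(0, c(2, 3, nf))
  pos[2, 1, ] <- 3.0
  pos[2, 1, 6:15] <- 1.0 # inside the H-O cutoff for exactly 10 frames
  tr <- md_trajectory(c("H", "O"), pos, c(20, 20, 20),
                      times = (0:(nf - 1)) * 0.242)
  bs <- suppressWarnings(detect_bonds(tr, bond_criteria()))
  on <- which(vapply(bs$bonded, length, 1L) > 0)
  expect_identical(on, 15L) # completes at the 10th frame, drops next

  # 9 frames only: never bonded
  pos[2, 1, ] <- 3.0
  pos[2, 1, 6:14] <- 1.0
  tr9 <- md_trajectory(c("H", "O"), pos, c(20, 20, 20),
                       times = (0:(nf - 1)) * 0.242)
  bs9 <- suppressWarnings(detect_bonds(tr9, bond_criteria()))
  expect_identical(sum(lengths(bs9$bonded)), 0L)

  # lifetime must divide the frame spacing
  expect_error(
    suppressWarnings(detect_bonds(tr, bond_criteria(lifetime = 0.3))),
    "integer number of frames")
})

test_that("lifetime = one frame reduces to the plain cutoff criterion and
           the filter matches the sliding-window oracle", {
  set.seed(21)
  for (rep in 1:5) {
    nf <- 50
    n <- 8
    el <- c("H", "H", "H", "O", "O", "N", "Fe", "Fe")
    pos <- array(stats::runif(n * 3 * nf, 0, 6), c(n, 3, nf))
    # random walks so pairs wander through the cutoffs
    for (k in 2:nf) {
      pos[, , k] <- pos[, , k - 1] +
        matrix(stats::rnorm(n * 3, sd = 0.3), n, 3)
    }
    tr <- md_trajectory(el, pos, c(50, 50, 50),
                        times = (0:(nf - 1)) * 0.242)
    crit <- full_bond_criteria()
    bs <- suppressWarnings(detect_bonds(tr, crit))
    # oracle: recompute within-cutoff matrix for the same candidate pairs
    np <- nrow(bs$pairs)
    within <- matrix(FALSE, nf, np)
    for (k in seq_len(nf)) {
      for (p in seq_len(np)) {
        d <- sqrt(sum((pos[bs$pairs$i[p], , k] -
                       pos[bs$pairs$j[p], , k])^2))
        within[k, p] <- d <= crit$cutoffs[[bs$pairs$type[p]]]
      }
    }
    oracle <- brute_lifetime_filter(within, bs$lifetime_frames)
    for (k in seq_len(nf)) {
      expect_identical(sort(bs$bonded[[k]]), which(oracle[k, ]))
    }
    # L = 1: plain cutoff
    crit1 <- full_bond_criteria(lifetime = 0.242)
    bs1 <- suppressWarnings(detect_bonds(tr, crit1))
    for (k in seq_len(nf)) {
      expect_identical(sort(bs1$bonded[[k]]), which(within[k, ]))
    }
    # filtered counts never exceed plain cutoff counts
    expect_true(all(bs$counts <= bs1$counts))
  }
})

test_that("intact waters give two H-O bonds per molecule", {
  units <- replicate(38, shockmd:::unit_water(), simplify = FALSE)
  centers <- as.matrix(expand.grid(seq(4, 44, by = 8), seq(4, 44, by = 8),
                                   seq(4, 20, by = 8)))[1:38, ]
  fr <- shockmd:::assemble_units(units, centers,
                                 simulation_cell(c(48, 48, 28)))
  tr <- shockmd:::jitter_trajectory(fr, duration = 0.242 * 29, dt = 0.242,
                                    jitter = 0.03, seed = 1)
  bs <- suppressWarnings(detect_bonds(tr, bond_criteria()))
  cnt <- count_bonds(bs, "H-O")
  expect_equal(cnt$count[length(cnt$count)], 76)
  # counts for isolated atoms are all zero
  iso <- md_trajectory(c("H", "O", "Fe", "N"),
                       array(c(diag(3) * 8, 1, 1, 1), c(4, 3, 1)) * 0 +
                         array(rep(c(1, 8, 16, 24), 3), c(4, 3, 1)),
                       c(40, 40, 40), times = 0)
  bsi <- suppressWarnings(detect_bonds(iso, bond_criteria()))
  expect_true(all(bsi$counts == 0))
  expect_error(count_bonds(bs, "C-C"), "not in the criteria")
})

test_that("partial RDF is normalised and peaks at the lattice spacing", {
  set.seed(5)
  pos <- array(stats::runif(200 * 3 * 8, 0, 18), c(200, 3, 8))
  gas <- md_trajectory(rep("Ar", 200), pos, c(18, 18, 18), times = 0:7)
  g <- partial_rdf(gas, c("Ar", "Ar"), bin_width = 0.25)
  expect_equal(mean(g$g[g$r > 3]), 1, tolerance = 0.05)

  fr <- fcc_crystal(c(3, 3, 3))
  tr <- shockmd:::jitter_trajectory(fr, duration = 0.242 * 4, dt = 0.242,
                                    jitter = 0.04, seed = 2)
  gc <- partial_rdf(tr, c("Fe", "Fe"), bin_width = 0.05)
  nn <- 3.492 / sqrt(2)
  expect_equal(gc$r[which.max(gc$g)], nn, tolerance = 0.05)

  expect_error(partial_rdf(gas, c("Ar", "Kr")), "no atoms")
})

test_that("first_minimum finds the valley of a bimodal g(r)", {
  r <- seq(0.025, 4, by = 0.05)
  g <- 2.5 * exp(-((r - 0.95) / 0.12)^2) +
       1.6 * exp(-((r - 1.8) / 0.25)^2) + 1 / (1 + exp(-(r - 2.5)))
  cutoff <- first_minimum(data.frame(r = r, g = g))
  expect_equal(cutoff, 1.25, tolerance = 0.08)
  expect_error(first_minimum(data.frame(r = r, g = rep(0, length(r)))),
               "no peak")
})
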