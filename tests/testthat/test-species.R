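census_of_graph <- function(gr) {
  memb <- shockmd:::bond_components(gr$n, as.data.frame(gr$edges))
  shockmd:::census_from_membership(memb, gr$elements)
}

test_that("isolated N + 3 H within cutoff is one ammonia", {
  pos <- array(0, c(4, 3, 12))
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  base <- rbind(c(10, 10, 10),
                sweep(dirs, 2, -c(10, 10, 10)))
  for (k in 1:12) pos[, , k] <- base
  tr <- md_trajectory(c("N", "H", "H", "H"), pos, c(20, 20, 20),
                      times = (0:11) * 0.242)
  bs <- suppressWarnings(detect_bonds(tr, full_bond_criteria()))
  cen <- species_census(bs, 12)
  expect_equal(unname(cen$flags["NH3"]), 1L)
  expect_equal(length(cen$members), 1L)
})

test_that("hydrazinium-like chains are flagged by formula", {
  # N2H5: two bonded N, one carrying 3 H, the other 2
  gr <- list(n = 7, elements = c("N", "N", "H", "H", "H", "H", "H"),
             edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6),
                           c(2, 7)))
  cen <- census_of_graph(gr)
  expect_equal(unname(cen$flags["N2H5"]), 1L)
  expect_true("H5N2" %in% cen$formulas)
})

test_that("census conserves the composition on random bond graphs", {
  for (s in 1:100) {
    gr <- random_bond_graph(s)
    cen <- census_of_graph(gr)
    expect_equal(sum(lengths(cen$members)), gr$n)
    # formulas re-aggregate to the total composition
    total <- integer(0)
    for (f in cen$formulas) {
      cnt <- shockmd:::parse_formula(f)
      for (e in names(cnt)) {
        total[e] <- (if (is.na(total[e])) 0L else total[e]) + cnt[[e]]
      }
    }
    comp <- table(gr$elements)
    expect_identical(total[sort(names(total))],
                     structure(as.integer(comp), names = names(comp)))
  }
})

test_that("formation events are cumulative and survive protonation", {
  fx <- ammonia_event_fixture(times_ps = c(0.3), protonation_ps = 0.6,
                              duration = 1000, seed = 3)
  bs <- suppressWarnings(detect_bonds(fx$trajectory,
                                      full_bond_criteria()))
  ev <- cumulative_formation_events(bs, "NH3")
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$time, 300, tolerance = 0.242)
  # protonation to NH4 does not decrement the cumulative count
  expect_equal(ev$cumulative[length(ev$cumulative)], 1L)
  cen <- species_census(bs, length(bs$bonded))
  expect_equal(unname(cen$flags["NH4"]), 1L)
  expect_equal(unname(cen$flags["NH3"]), 0L)
  # monotone non-decreasing
  expect_true(all(diff(ev$cumulative) >= 0))

  # no N-H bonds anywhere: empty event list
  pos <- array(rep(c(2, 10, 18), each = 3), c(3, 3, 5))
  tr <- md_trajectory(c("N", "N", "O"), pos, c(24, 24, 24),
                      times = (0:4) * 0.242)
  bs0 <- suppressWarnings(detect_bonds(tr,
                                       full_bond_criteria(lifetime = 0.242)))
  ev0 <- cumulative_formation_events(bs0, "NH3")
  expect_equal(nrow(ev0$events), 0L)
  expect_true(all(ev0$cumulative == 0L))
})

test_that("Mulliken charges follow Q = Z0 - Z with conservation", {
  expect_equal(unname(mulliken_charge(5, "N")[1, 1]), 0)
  expect_equal(unname(mulliken_charge(5.4, "N")[1, 1]), -0.4)
  # closed system: sum of charges is fixed when sum of Z is fixed
  set.seed(2)
  el <- c("N", "N", "O", "H", "H", "Fe")
  Z0 <- c(N = 5, O = 6, H = 1, Fe = 8)
  Z <- matrix(stats::runif(6 * 4), 6, 4)
  Z <- sweep(Z, 2, colSums(Z) / 6) + sum(Z0[el]) / 6 # fix column sums
  Q <- mulliken_charge(Z, el, Z0)
  expect_equal(diff(range(colSums(Q))), 0, tolerance = 1e-9)
  expect_error(mulliken_charge(1, "C", Z0), "missing from the Z0")
})
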