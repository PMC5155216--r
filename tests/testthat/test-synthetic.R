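test_that("the reference supercell matches composition, cell and spacing", {
  fr <- build_initial_system(seed = 1)
  expect_identical(composition(fr)[c("Fe", "N", "O", "H")],
                   c(Fe = 36L, N = 32L, O = 38L, H = 76L))
  expect_equal(cell_volume(fr$cell), 29.72 * 8.580 * 8.580)
  expect_gte(shockmd:::min_pair_distance(fr$positions, fr$cell), 0.7)
  fr2 <- build_initial_system(seed = 1)
  expect_identical(fr$positions, fr2$positions)
  fr3 <- build_initial_system(seed = 2)
  expect_false(identical(fr$positions, fr3$positions))
})

test_that("Brownian steps have variance 2 D dt and freeze at D = 0", {
  spec <- brownian_spec(n_atoms = 60, D = 2.35e-5, duration = 400,
                        dt = 0.242, seed = 5)
  tr <- brownian_trajectory(spec)
  steps <- tr$positions[, , -1] - tr$positions[, , -n_frames(tr)]
  v_emp <- stats::var(as.numeric(steps))
  v_true <- 2 * (2.35e-5 / 0.1) * 0.242
  n <- length(steps)
  se <- v_true * sqrt(2 / (n - 1))
  expect_lt(abs(v_emp - v_true), 3 * se)

  frz <- brownian_trajectory(brownian_spec(n_atoms = 4, D = 0,
                                           duration = 10, seed = 1))
  expect_equal(max(abs(frz$positions -
                         as.numeric(frz$positions[, , 1]))), 0)
  # reproducible under the seed
  tr2 <- brownian_trajectory(spec)
  expect_identical(tr$positions, tr2$positions)
})

test_that("shock-profile fixtures satisfy the jump relations row by row", {
  st <- shock_profile_fixture(Vs = 5, final_compression = 0.58,
                              rise_time = 300)
  rho0 <- initial_density(c(Fe = 36, N = 32, O = 38, H = 76),
                          c(29.72, 8.580, 8.580))
  expect_equal(st$Up, 5 * (1 - st$V_ratio), tolerance = 1e-12)
  expect_equal(st$P, rho0 * 5 * st$Up, tolerance = 1e-12)
  # asymptotic particle velocity from the mass jump condition
  expect_equal(st$Up[nrow(st)], 2.10, tolerance = 1e-3)
  expect_equal(st$V_ratio[1], 1, tolerance = 1e-2)
  # zero-width rise is a step function
  s2 <- shock_profile_fixture(5, 0.58, rise_time = 300, width = 0)
  expect_true(all(s2$V_ratio[s2$t < 300] == 1))
  expect_true(all(s2$V_ratio[s2$t >= 300] == 0.58))
})

test_that("scripted trajectories change the bond graph exactly as scripted", {
  # empty script: constant counts
  fr <- shockmd:::assemble_units(list(shockmd:::unit_water(),
                                      shockmd:::unit_nh3()),
                                 rbind(c(5, 5, 5), c(15, 15, 15)),
                                 simulation_cell(c(20, 20, 20)))
  tr <- script_reactive_trajectory(fr, event_script(numeric(), character(),
                                                    integer()),
                                   duration = 24.2, dt = 0.242, seed = 2)
  bs <- suppressWarnings(detect_bonds(tr, full_bond_criteria()))
  late <- bs$counts[10:nrow(bs$counts), ]
  expect_true(all(apply(late, 2, function(x) length(unique(x)) == 1)))

  # a scripted proton transfer rebonds exactly one H
  sc <- event_script(time = 12.1, kind = "proton_transfer", atom = 2,
                     anchor = 4, dx = 1.0)
  tr2 <- script_reactive_trajectory(fr, sc, duration = 24.2, dt = 0.242,
                                    seed = 2)
  bs2 <- suppressWarnings(detect_bonds(tr2, full_bond_criteria()))
  cen <- species_census(bs2, length(bs2$bonded))
  expect_equal(unname(cen$flags["OH"]), 1L)
  expect_equal(unname(cen$flags["NH4"]), 1L)

  # impossible events abort with the event named
  bad <- event_script(time = 12.1, kind = "proton_transfer", atom = 2,
                      anchor = 4, dx = 0.1)
  expect_error(script_reactive_trajectory(fr, bad, duration = 24.2),
               "event 1")
  out <- event_script(time = 99, kind = "adsorption", atom = 1)
  expect_error(script_reactive_trajectory(fr, out, duration = 24.2),
               "span")
})

test_that("event scripts round-trip through their YAML schema", {
  sc <- event_script(time = c(10, 5), kind = c("protonation",
                                               "bond_scission"),
                     atom = c(3, 7), anchor = c(1, NA), dx = c(1, 4),
                     dy = 0, dz = c(0, 2))
  tmp <- withr::local_tempfile(fileext = ".yml")
  write_event_script(sc, tmp)
  sc2 <- read_event_script(tmp)
  expect_equal(as.data.frame(sc2), as.data.frame(sc))
  # sorted by time on construction
  expect_equal(sc$time, c(5, 10))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- bond_inventory_fixture(duration = 2, seed = 9)
  b <- bond_inventory_fixture(duration = 2, seed = 9)
  expect_identical(a$positions, b$positions)
  fa <- ammonia_event_fixture(times_ps = 0.05, protonation_ps = NA,
                              duration = 100, seed = 4)
  fb <- ammonia_event_fixture(times_ps = 0.05, protonation_ps = NA,
                              duration = 100, seed = 4)
  expect_identical(fa$trajectory$positions, fb$trajectory$positions)
})
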