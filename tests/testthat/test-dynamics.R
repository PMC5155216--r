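test_that("NVE dynamics conserves energy and momentum", {
  fr <- fcc_crystal(c(2, 2, 2))
  run <- run_nve(fr, lj_pot(), dt = 0.242, n_steps = 1500, T0 = 300,
                 seed = 3, stride = 10)
  ec <- run$states$E_cons
  span_ps <- (run$states$t[length(ec)] - run$states$t[1]) / 1000
  drift <- abs(ec[length(ec)] - ec[1]) / n_atoms(run$trajectory) / span_ps
  expect_lt(drift, 1e-5)
  # periodic NVE conserves total momentum to machine precision
  m <- atomic_masses(fr$elements)
  vlast <- run$trajectory$velocities[, , n_frames(run$trajectory)]
  expect_lt(max(abs(colSums(m * vlast))), 1e-12)
})

test_that("Nose-Hoover dynamics holds the target temperature", {
  fr <- fcc_crystal(c(2, 2, 2))
  run <- run_nvt(fr, lj_pot(), T = 300, dt = 0.242, n_steps = 4000,
                 seed = 4, stride = 5)
  Ts <- run$states$T
  half <- Ts[(length(Ts) %/% 2):length(Ts)]
  se <- shockmd:::block_se(half)
  expect_lt(abs(mean(half) - 300), 3 * max(se, 0.5))
})

test_that("zero-temperature equilibrium lattice stays put", {
  fr <- fcc_crystal(c(2, 2, 2))
  fr$velocities <- matrix(0, 32, 3)
  run <- run_nve(fr, lj_pot(), dt = 0.242, n_steps = 100, stride = 20)
  expect_lt(max(abs(run$trajectory$positions[, , 6] -
                    run$trajectory$positions[, , 1])), 1e-9)
})

test_that("identical seeds give bit-identical trajectories", {
  fr <- fcc_crystal(c(2, 2, 2))
  r1 <- run_nvt(fr, lj_pot(), T = 300, n_steps = 200, seed = 9, stride = 5)
  r2 <- run_nvt(fr, lj_pot(), T = 300, n_steps = 200, seed = 9, stride = 5)
  expect_identical(r1$trajectory$positions, r2$trajectory$positions)
  r3 <- run_nvt(fr, lj_pot(), T = 300, n_steps = 200, seed = 10, stride = 5)
  expect_false(identical(r1$trajectory$positions,
                         r3$trajectory$positions))
})

test_that("overlapping atoms abort with a step diagnostic", {
  fr <- md_frame(c("Fe", "Fe"), rbind(c(1, 1, 1), c(1, 1, 1 + 1e-12)),
                 c(10, 10, 10))
  expect_error(run_nve(fr, lj_pot(), n_steps = 10), "step")
})

test_that("constraint recovers the harmonic mean force and residual", {
  hd <- harmonic_dimer(0.9)
  w <- constrained_window(hd$frame, hd$pot, c(1, 2), 0.9, T = 1e-4,
                          duration = 150, seed = 1)
  # compressed by 0.1 A against k = 30 eV/A^2: lambda = +3 eV/A
  expect_equal(w$lambda_mean, 3.0, tolerance = 1e-4)

  hd0 <- harmonic_dimer(1.0)
  w0 <- constrained_window(hd0$frame, hd0$pot, c(1, 2), 1.0, T = 1e-4,
                           duration = 150, seed = 1)
  expect_lt(abs(w0$lambda_mean), 1e-6)

  # residual below tolerance every recorded frame
  tr <- w$run$trajectory
  for (k in seq_len(n_frames(tr))) {
    expect_lt(abs(minimum_image_distance(get_frame(tr, k), 1, 2) - 0.9),
              1e-7)
  }
  # starting too far from the target is rejected
  expect_error(constrained_window(hd$frame, hd$pot, c(1, 2), 2.0,
                                  duration = 50), "0.5 A")
})

test_that("doubling the constrained window shrinks the standard error", {
  hd <- harmonic_dimer(0.9)
  w1 <- constrained_window(hd$frame, hd$pot, c(1, 2), 0.9, T = 300,
                           duration = 500, seed = 2)
  w2 <- constrained_window(hd$frame, hd$pot, c(1, 2), 0.9, T = 300,
                           duration = 1000, seed = 2)
  ratio <- w1$lambda_se / w2$lambda_se
  # expect roughly sqrt(2); block estimates on correlated data are noisy
  expect_gt(ratio, 1.0)
  expect_lt(ratio, 2.6)
  # thermal mean force carries the 2 kT / r centrifugal term
  kT <- shock_constants()$kB * 300
  expect_equal(w2$lambda_mean, 3.0 + 2 * kT / 0.9, tolerance = 0.02)
})
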