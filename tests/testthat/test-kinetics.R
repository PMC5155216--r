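test_that("MSD is zero for frozen atoms and quadratic for ballistic ones", {
  pos <- array(rep(c(1, 2, 3), each = 2), c(2, 3, 60))
  tr <- md_trajectory(c("Fe", "Fe"), pos, c(50, 50, 50),
                      times = (0:59) * 0.242)
  m0 <- msd(tr, max_lag = 20, origin_stride = 2)
  expect_true(all(m0$msd == 0))
  expect_equal(diffusion_coefficient(m0), 0)

  v <- 0.01
  posb <- array(0, c(1, 3, 101))
  posb[1, 1, ] <- v * (0:100)
  trb <- md_trajectory("Fe", posb, c(100, 100, 100), times = 0:100)
  mb <- msd(trb, max_lag = 50, origin_stride = 1)
  expect_equal(mb$msd, (v * mb$lag)^2, tolerance = 1e-10)

  expect_error(msd(tr, species = "Xe"), "no atoms")
  expect_error(msd(tr, max_lag = 100), "smaller")
})

test_that("diffusion fit recovers an exact analytic line", {
  D <- 2.35e-5                      # cm^2/s
  lag <- seq(2, 400, by = 2)        # fs
  curve <- data.frame(lag = lag, msd = 6 * (D / 0.1) * lag)
  class(curve) <- c("msd_curve", "data.frame")
  expect_equal(diffusion_coefficient(curve), D, tolerance = 1e-12)
  expect_error(diffusion_coefficient(curve[1:2, ]), "3 points")
})

test_that("Brownian fixtures are recovered within the estimator noise", {
  spec <- brownian_spec(n_atoms = 36, D = 2.35e-5, duration = 4000,
                        dt = 0.242, seed = 77)
  tr <- brownian_trajectory(spec)
  Dhat <- diffusion_coefficient(msd(tr, origin_stride = 10))
  expect_equal(Dhat, 2.35e-5, tolerance = 0.25)
  # estimator error shrinks as the trajectory grows (two lengths)
  err <- function(dur, seeds) {
    mean(vapply(seeds, function(s) {
      t2 <- brownian_trajectory(brownian_spec(duration = dur, seed = s))
      abs(diffusion_coefficient(msd(t2, origin_stride = 10)) - 2.35e-5)
    }, 0))
  }
  expect_lt(err(4000, 1:8), err(250, 1:8))
})

test_that("free-energy integration matches the harmonic closed form", {
  # lambda = k0 (r0 - r) for a harmonic well: dF = k0 (r0 - r)^2 / 2
  k0 <- 4
  r <- seq(2.0, 1.0, by = -0.02)
  prof <- free_energy_profile(data.frame(r = r, lambda = k0 * (2.0 - r)))
  expect_equal(prof$dF, k0 * (2.0 - r)^2 / 2, tolerance = 1e-3)
  expect_equal(prof$dF[1], 0)

  # flat lambda: dF identically zero
  z <- free_energy_profile(data.frame(r = r, lambda = 0 * r))
  expect_true(all(z$dF == 0))
  expect_equal(barrier_height(z), 0)

  # linearity in a uniform scaling of lambda
  p2 <- free_energy_profile(data.frame(r = r, lambda = 3 * k0 * (2.0 - r)))
  expect_equal(p2$dF, 3 * prof$dF)

  expect_error(free_energy_profile(data.frame(r = rev(r), lambda = 0 * r)),
               "decreasing")
  expect_error(free_energy_profile(data.frame(r = r[1:2],
                                              lambda = c(0, 0))),
               "3 window points")
})

test_that("a triangular mean-force profile yields the engineered barrier", {
  # lambda crosses zero at the transition state; area to there is 0.09 eV
  r <- seq(2.0, 1.0, by = -0.025)
  lam <- 0.72 * (r - 1.5)
  prof <- free_energy_profile(data.frame(r = r, lambda = lam))
  expect_equal(barrier_height(prof), 0.09, tolerance = 1e-6)
  expect_equal(attr(prof, "r_barrier"), 1.5)
  expect_equal(prof$dF[length(r)], 0, tolerance = 1e-9)
})

test_that("TST rates are monotone in temperature and barrier", {
  expect_equal(tst_rate(0, 300),
               shock_constants()$kB * 300 / shock_constants()$h * 1e-12)
  Ts <- seq(300, 3000, by = 300)
  ks <- vapply(Ts, function(tt) tst_rate(0.09, tt), 0)
  expect_true(all(diff(ks) > 0))
  bs <- seq(0, 1, by = 0.1)
  kb <- vapply(bs, function(b) tst_rate(b, 1200), 0)
  expect_true(all(diff(kb) < 0))
  expect_warning(tst_rate(-0.1, 300), "attempt frequency")
})

test_that("jump conditions hold simultaneously and reject rarefaction", {
  s <- hugoniot_jump(2.386, 5, Up = 2.30, P0 = 0.5)
  expect_equal(s$Up, s$Vs * (1 - s$compression), tolerance = 1e-12)
  expect_equal(s$P, s$P0 + s$rho0 * s$Vs * s$Up, tolerance = 1e-12)
  expect_equal(s$dE,
               0.5 * (s$P + s$P0) * (1 / s$rho0) * (1 - s$compression),
               tolerance = 1e-12)
  z <- hugoniot_jump(2.386, 5, Up = 0)
  expect_equal(z$P, z$P0)
  expect_equal(z$dE, 0)
  expect_error(hugoniot_jump(2.386, 5, compression = 1.2), "rarefaction")
  expect_error(hugoniot_jump(2.386, 5), "exactly one")
  expect_error(hugoniot_jump(2.386, 5, compression = 0.5, Up = 1),
               "exactly one")
})

test_that("production ratio is plain percentage arithmetic", {
  expect_equal(production_ratio(1, 1), 100)
  expect_equal(production_ratio(4.3e7, 1.59e8), 27.0, tolerance = 0.002)
  expect_error(production_ratio(1, 0), "reference")
})
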