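# Transport, free-energy, rate and shock-thermodynamics calculators.

#' Mean squared displacement with multiple time origins
#'
#' MSD(tau) = (1/N) sum_i < |r_i(t0 + tau) - r_i(t0)|^2 > averaged over
#' time origins t0 on the given stride. Uses unwrapped coordinates (the
#' trajectory's `unwrapped` slot when present, otherwise `positions`).
#'
#' @param trajectory An [md_trajectory()].
#' @param species Optional element symbol to restrict to (e.g. "Fe").
#' @param max_lag Largest lag in frames; default 25% of the trajectory.
#' @param origin_stride Spacing of time origins in frames.
#' @param n_lags Approximate number of lag points evaluated.
#' @return An `msd_curve`: data.frame with `lag` (fs) and `msd` (A^2),
#'   attributes `n_origins` (per lag), `species`.
#' @export
msd <- function(trajectory, species = NULL, max_lag = NULL,
                origin_stride = 10L, n_lags = 200L) {
  nf <- n_frames(trajectory)
  stopifnot(nf >= 3)
  if (is.null(max_lag)) max_lag <- max(2L, floor(nf / 4))
  if (max_lag >= nf) stop("max_lag must be smaller than the trajectory")
  pos <- if (!is.null(trajectory$unwrapped)) trajectory$unwrapped
         else trajectory$positions
  if (!is.null(species)) {
    sel <- which(trajectory$elements == species)
    if (!length(sel)) stop("no atoms of species '", species, "'")
    pos <- pos[sel, , , drop = FALSE]
  }
  n <- dim(pos)[1]
  # flatten to (3n) x nf for fast column slicing
  P <- matrix(aperm(pos, c(2, 1, 3)), nrow = 3 * n)
  lags <- unique(round(seq(1, max_lag, length.out = min(n_lags, max_lag))))
  msd_v <- numeric(length(lags))
  n_or <- integer(length(lags))
  for (q in seq_along(lags)) {
    tau <- lags[q]
    origins <- seq.int(1L, nf - tau, by = origin_stride)
    d <- P[, origins + tau, drop = FALSE] - P[, origins, drop = FALSE]
    msd_v[q] <- sum(d * d) / (n * length(origins))
    n_or[q] <- length(origins)
  }
  dt <- trajectory_dt(trajectory)
  out <- data.frame(lag = lags * dt, msd = msd_v)
  attr(out, "n_origins") <- n_or
  attr(out, "species") <- species
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$lag, x$msd, type = "l", xlab = "lag (fs)",
       ylab = expression(MSD ~ (ring(A)^2)), ...)
  invisible(x)
}

#' Self-diffusion coefficient from an MSD slope
#'
#' D = slope/6 by least squares over the window, converted to cm^2/s.
#'
#' @param msd_curve An [msd()] result (data.frame lag, msd).
#' @param fit_window Fractions of the largest lag delimiting the fit
#'   window (default 20-80%, inside the diffusive regime).
#' @return D in cm^2/s.
#' @export
diffusion_coefficient <- function(msd_curve, fit_window = c(0.2, 0.8)) {
  stopifnot(length(fit_window) == 2, fit_window[1] < fit_window[2])
  lag <- msd_curve$lag
  lo <- fit_window[1] * max(lag); hi <- fit_window[2] * max(lag)
  sel <- lag >= lo & lag <= hi
  if (sum(sel) < 3) stop("fit window contains fewer than 3 points")
  fit <- stats::lm(msd ~ lag, data = msd_curve[sel, ])
  slope <- unname(stats::coef(fit)[2]) # A^2/fs
  slope / 6 * .a2fs_cm2s
}

#' Free-energy profile by thermodynamic integration
#'
#' Integrates the mean constraint force along the (decreasing) reaction
#' coordinate: dF(r) = integral from r to r0 of <lambda> dr', by the
#' trapezoidal rule. With the sign convention of [constrained_window()]
#' (lambda > 0 when the potential pushes the pair apart) a barrier between
#' the equilibrium distance r0 and the product distance r_d comes out
#' positive.
#'
#' @param lambda_profile Data frame with columns `r` (A, strictly
#'   decreasing from r0) and `lambda` (eV/A); an optional `se` column is
#'   carried through.
#' @return A `free_energy_profile`: data.frame `r`, `dF` (eV) with
#'   attribute `barrier` (max dF) and `r_barrier`.
#' @export
free_energy_profile <- function(lambda_profile) {
  r <- lambda_profile$r
  lam <- lambda_profile$lambda
  stopifnot(length(r) == length(lam))
  if (length(r) < 3) stop("need at least 3 window points including r0")
  if (any(diff(r) >= 0)) {
    stop("r values must be strictly decreasing from the equilibrium ",
         "distance r0")
  }
  dF <- c(0, cumsum(0.5 * (lam[-1] + lam[-length(lam)]) * (-diff(r))))
  out <- data.frame(r = r, dF = dF)
  attr(out, "barrier") <- max(dF)
  attr(out, "r_barrier") <- r[which.max(dF)]
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  plot(x$r, x$dF, type = "b", xlab = "r (A)",
       ylab = expression(Delta * F ~ (eV)), ...)
  invisible(x)
}

#' Barrier height of a free-energy profile
#'
#' @param profile A [free_energy_profile()].
#' @return Barrier (eV).
#' @export
barrier_height <- function(profile) attr(profile, "barrier")

#' Transition-state-theory rate
#'
#' k = (kB T / h) exp(-dF / kB T), returned in ps^-1.
#'
#' @param barrier Free-energy barrier dF (eV).
#' @param T Temperature (K), > 0.
#' @return Rate in ps^-1.
#' @examples
#' tst_rate(0.09, 2100) # about 26.6 ps^-1
#' tst_rate(0.09, 1200) # about 10.5 ps^-1
#' @export
tst_rate <- function(barrier, T) {
  stopifnot(T > 0)
  if (any(barrier < 0)) {
    warning("negative barrier: rate exceeds the attempt frequency")
  }
  cst <- shock_constants()
  kBT <- cst$kB * T
  (kBT / cst$h) * exp(-barrier / kBT) * 1e-12
}

#' Rankine-Hugoniot jump conditions
#'
#' Given the unshocked density and the shock speed plus either the
#' compression ratio V/V0 or the particle velocity Up, returns the state
#' satisfying all three jump relations: mass `Up = Vs (1 - V/V0)`,
#' momentum `P = P0 + rho0 Vs Up`, energy
#' `dE = (P + P0)(v0 - v)/2` per unit initial mass.
#'
#' @param rho0 Unshocked density (g/cm^3).
#' @param Vs Shock speed (km/s).
#' @param compression V/V0 in (0, 1]; give this or `Up`.
#' @param Up Particle velocity (km/s).
#' @param P0 Unshocked pressure (GPa).
#' @return A `shock_state` list: rho0, Vs, compression, Up, P (GPa), P0,
#'   dE (MJ/kg).
#' @examples
#' hugoniot_jump(2.386, 5, Up = 2.30)$P # about 27.4 GPa
#' @export
hugoniot_jump <- function(rho0, Vs, compression = NULL, Up = NULL, P0 = 0) {
  stopifnot(rho0 > 0, Vs > 0)
  if (is.null(compression) == is.null(Up)) {
    stop("give exactly one of compression (V/V0) or Up")
  }
  if (is.null(Up)) {
    if (compression > 1) {
      stop("V/V0 > 1 with Vs > 0: rarefaction is not modelled")
    }
    if (compression <= 0) stop("compression must be positive")
    Up <- Vs * (1 - compression)
  } else {
    if (Up < 0) stop("Up must be non-negative")
    compression <- 1 - Up / Vs
    if (compression <= 0) stop("Up >= Vs implies full collapse")
  }
  P <- P0 + rho0 * Vs * Up # g/cm^3 km^2/s^2 = GPa
  v0 <- 1 / rho0           # cm^3/g
  dE <- 0.5 * (P + P0) * v0 * (1 - compression) # GPa cm^3/g = MJ/kg
  structure(list(rho0 = rho0, Vs = Vs, compression = compression, Up = Up,
                 P = P, P0 = P0, dE = dE),
            class = "shock_state")
}

#' @export
print.shock_state <- function(x, ...) {
  cat(sprintf(paste0("shock_state: Vs = %.3g km/s, V/V0 = %.4g, ",
                     "Up = %.4g km/s, P = %.4g GPa, dE = %.4g MJ/kg\n"),
              x$Vs, x$compression, x$Up, x$P, x$dE))
  invisible(x)
}

#' Production ratio in percent
#'
#' @param rate Production rate (any unit).
#' @param reference_rate Reference rate (same unit), > 0.
#' @return 100 * rate / reference_rate.
#' @examples
#' production_ratio(1.08e7, 1.59e8) # about 6.8, i.e. ~7%
#' @export
production_ratio <- function(rate, reference_rate) {
  stopifnot(reference_rate > 0)
  100 * rate / reference_rate
}
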