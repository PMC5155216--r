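#' shockmd: shock-compression molecular dynamics and reactive analysis
#'
#' Internal unit system: length in Angstrom (A), time in femtoseconds (fs),
#' mass in atomic mass units (amu), energy in electronvolts (eV). Derived
#' units used at the interfaces: pressure in GPa, velocity in km/s, mass
#' density in g/cm^3, diffusion coefficients in cm^2/s, temperature in K.
#'
#' @keywords internal
"_PACKAGE"

# CODATA 2018; the elementary charge and the dalton are the only inputs the
# whole conversion layer needs.
.ev_J <- 1.602176634e-19
.amu_kg <- 1.66053906660e-27

# (eV/A)/amu -> A/fs^2: (eV/A in N) / (amu in kg) gives m/s^2; one m/s^2
# is 1e-20 A/fs^2
.acc_conv <- (.ev_J / 1e-10) / .amu_kg * 1e-20
# amu A^2/fs^2 -> eV
.ke_conv <- 1 / .acc_conv
# eV/A^3 -> GPa
.eva3_gpa <- .ev_J * 1e30 / 1e9
# amu/A^3 -> g/cm^3
.amua3_gcm3 <- .amu_kg * 1e27
# km/s -> A/fs
.kms_afs <- 1e-2
# A^2/fs -> cm^2/s
.a2fs_cm2s <- 1e-1

# SI value of one internal (or interface) unit per quantity
.si_factor <- c(
  length      = 1e-10,    # A -> m
  time        = 1e-15,    # fs -> s
  mass        = 1.66053906660e-27, # amu -> kg
  energy      = 1.602176634e-19,   # eV -> J
  pressure    = 1e9,      # GPa -> Pa
  velocity    = 1e3,      # km/s -> m/s
  temperature = 1,        # K -> K
  force       = 1.602176634e-19 / 1e-10, # eV/A -> N
  density     = 1e3,      # g/cm^3 -> kg/m^3
  diffusion   = 1e-4      # cm^2/s -> m^2/s
)

#' Physical constants in the package unit system
#'
#' @return Named list: `kB` Boltzmann constant (eV/K), `h` Planck constant
#'   (eV s), `amu_kg` dalton in kg, `ev_J` electronvolt in J, and the
#'   conversion factors between internal mechanical units and interface
#'   units (`acc_conv`: (eV/A)/amu to A/fs^2; `ke_conv`: amu A^2/fs^2 to eV;
#'   `eva3_gpa`: eV/A^3 to GPa; `amua3_gcm3`: amu/A^3 to g/cm^3;
#'   `kms_afs`: km/s to A/fs; `a2fs_cm2s`: A^2/fs to cm^2/s).
#' @examples
#' shock_constants()$kB * 300 # thermal energy at 300 K, eV
#' @export
shock_constants <- function() {
  list(
    kB = 8.617333262e-5,
    h = 4.135667696e-15,
    amu_kg = .amu_kg,
    ev_J = .ev_J,
    acc_conv = .acc_conv,
    ke_conv = .ke_conv,
    eva3_gpa = .eva3_gpa,
    amua3_gcm3 = .amua3_gcm3,
    kms_afs = .kms_afs,
    a2fs_cm2s = .a2fs_cm2s
  )
}

#' Convert a quantity between package units and SI
#'
#' Package units are A (length), fs (time), amu (mass), eV (energy), GPa
#' (pressure), km/s (velocity), K (temperature), eV/A (force), g/cm^3
#' (density) and cm^2/s (diffusion).
#'
#' @param x Numeric vector in package units (`to_si`) or SI (`from_si`).
#' @param quantity One of `names(.si_factor)`, e.g. "pressure".
#' @return Numeric vector in the other unit system.
#' @examples
#' to_si(1, "pressure")       # 1 GPa in Pa
#' from_si(to_si(2.3, "velocity"), "velocity")
#' @export
to_si <- function(x, quantity) {
  x * .si_unit(quantity)
}

#' @rdname to_si
#' @export
from_si <- function(x, quantity) {
  x / .si_unit(quantity)
}

.si_unit <- function(quantity) {
  stopifnot(is.character(quantity), length(quantity) == 1)
  if (!quantity %in% names(.si_factor)) {
    stop("unknown quantity '", quantity, "'; expected one of: ",
         paste(names(.si_factor), collapse = ", "))
  }
  .si_factor[[quantity]]
}

#' IUPAC standard atomic weights (amu)
#'
#' Conventional values for the elements the pipeline handles.
#'
#' @param elements Optional character vector of element symbols; if given,
#'   returns their masses (error on unknown symbols).
#' @return Named numeric vector of masses in amu.
#' @examples
#' atomic_masses(c("Fe", "N", "O", "H"))
#' @export
atomic_masses <- function(elements = NULL) {
  m <- c(H = 1.008, He = 4.002602, C = 12.011, N = 14.007, O = 15.999,
         Na = 22.98976928, Mg = 24.305, Si = 28.085, P = 30.973761998,
         S = 32.06, Ar = 39.95, Fe = 55.845, Ni = 58.6934)
  if (is.null(elements)) return(m)
  bad <- setdiff(unique(elements), names(m))
  if (length(bad)) {
    stop("no standard atomic weight for element(s): ",
         paste(bad, collapse = ", "))
  }
  m[elements]
}
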