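#' Physical constants used throughout the package
#'
#' All physical constants are CODATA 2018 values, collected in one place so
#' every module converts units identically. Energies are carried in hartree
#' internally and converted to kcal/mol only at reporting boundaries.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{h}{Planck constant, J s}
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{N_A}{Avogadro constant, 1/mol}
#'     \item{c}{speed of light, cm/s (spectroscopic convention)}
#'     \item{amu}{atomic mass constant, kg}
#'     \item{R_kcal}{molar gas constant, kcal mol^-1 K^-1}
#'     \item{R_J}{molar gas constant, J mol^-1 K^-1}
#'     \item{hartree_kcal}{hartree -> kcal/mol conversion}
#'     \item{bar_Pa}{1 bar in Pa}
#'   }
#' @export
physical_constants <- function() {
  list(
    h           = 6.62607015e-34,
    kB          = 1.380649e-23,
    N_A         = 6.02214076e23,
    c           = 2.99792458e10,
    amu         = 1.66053906660e-27,
    R_kcal      = 1.987204259e-3,
    R_J         = 8.31446261815324,
    hartree_kcal = 627.509474,
    bar_Pa      = 1e5
  )
}

# Most-abundant-isotope atomic masses (amu), IUPAC/CODATA.
.atomic_masses <- c(
  H = 1.00782503207, D = 2.01410177812, He = 4.00260325413,
  Li = 7.0160034366, Be = 9.012183065, B = 11.00930536,
  C = 12.0, N = 14.0030740048, O = 15.9949146196, F = 18.9984031627,
  Ne = 19.9924401762, Na = 22.9897692820, Mg = 23.985041697,
  Al = 26.98153853, Si = 27.97692653465, P = 30.97376199842,
  S = 31.9720711744, Cl = 34.968852682, Ar = 39.9623831237,
  K = 38.9637064864, Ca = 39.962590863, Fe = 55.93493633,
  Zn = 63.92914201, Br = 78.9183376, I = 126.9044719
)

# Covalent radii (Angstrom), Cordero et al. consensus values; used for bond
# perception with an additive tolerance (see detect_bonds).
.covalent_radii <- c(
  H = 0.31, D = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84,
  C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Fe = 1.32,
  Zn = 1.22, Br = 1.20, I = 1.39
)

#' Atomic masses of the most abundant isotopes
#'
#' @param elements character vector of element symbols.
#' @return Numeric vector of masses in amu.
#' @export
atomic_masses <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Check element symbols against the supported periodic-table subset
#'
#' @param elements character vector of element symbols.
#' @return TRUE invisibly; errors naming the first invalid symbol otherwise.
#' @keywords internal
validate_elements <- function(elements) {
  bad <- setdiff(elements, names(.atomic_masses))
  if (length(bad) > 0L) {
    stop("invalid element symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# Vocabulary of electronic-energy level labels exchanged in energy tables.
.energy_levels <- c("DFT", "DZ", "TZ", "QZ", "haDZ", "haTZ", "haQZ", "ha5Z",
                    "CBS(DTQ)", "CBS(haDTQ)")

#' Declared vocabulary of electronic-energy level labels
#'
#' Labels follow the correlation-consistent basis-set ladder: \code{DZ},
#' \code{TZ}, \code{QZ} (cc-pVNZ), their heavy-augmented counterparts
#' \code{haDZ}...\code{ha5Z} (haug-cc-pVNZ), the DFT reference level used for
#' window filtering, and the two extrapolated complete-basis-set labels.
#'
#' @return Character vector of recognized level labels.
#' @export
energy_levels <- function() .energy_levels
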