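#' Scale harmonic frequencies
#'
#' Uniform multiplicative scaling of harmonic wavenumbers, the standard way
#' to fold average anharmonicity into rigid-rotor/harmonic-oscillator free
#' energies. The default elsewhere in the package is 0.971, appropriate for
#' wB97X-D/6-31++G** harmonic frequencies.
#'
#' @param freqs numeric vector of wavenumbers, cm^-1, all positive.
#' @param factor positive scale factor.
#' @return Scaled wavenumbers, order preserved.
#' @export
scale_frequencies <- function(freqs, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("scale factor must be positive")
  if (any(freqs <= 0))
    stop("imaginary/non-positive mode(s) present: ",
         paste(format(freqs[freqs <= 0]), collapse = ", "),
         " cm^-1; exclude saddle points before scaling")
  freqs * factor
}

#' Ideal-gas RRHO thermodynamic corrections
#'
#' Standard rigid-rotor/harmonic-oscillator corrections for an ideal gas at
#' temperature \code{T} and pressure \code{P}: translational entropy from the
#' Sackur-Tetrode expression, classical rotational contributions from the
#' principal moments of inertia with symmetry number \code{sigma}, and
#' vibrational contributions from the quantum harmonic oscillator over the
#' scaled modes (the zero-point energy is scaled along with the thermal
#' terms and included in the enthalpy and free-energy corrections).
#' Electronic degeneracy is fixed at 1 (closed-shell species).
#'
#' The enthalpy correction is \eqn{H_{corr} = ZPE + E_{trans} + E_{rot} +
#' E_{vib}(T) + RT} and the Gibbs correction is
#' \eqn{G_{corr} = H_{corr} - T S_{corr}}.
#'
#' @param c a \code{\link{conformer}}.
#' @param freqs a \code{\link{frequency_set}} for the same conformer
#'   (unscaled wavenumbers; ignored for single atoms).
#' @param T temperature in K (default physiological, 310.15).
#' @param P pressure in bar (default 1).
#' @param sigma rotational symmetry number (default 1; asymmetric
#'   conformers).
#' @param scale frequency scale factor (default 0.971).
#' @return Object of class \code{thermo_corrections}: \code{zpe},
#'   \code{h_corr}, \code{g_corr} in kcal/mol, \code{s_corr} in
#'   cal/(mol K), plus the temperature, pressure and scale factor used.
#' @export
thermo_corrections <- function(c, freqs = NULL, T = 310.15, P = 1,
                               sigma = 1, scale = 0.971) {
  pc <- physical_constants()
  n <- n_atoms(c)
  R <- pc$R_kcal            # kcal/(mol K)
  mass_amu <- sum(atomic_masses(c$elements))

  # translational: Sackur-Tetrode
  m_kg <- mass_amu * pc$amu
  q_trans <- (2 * pi * m_kg * pc$kB * T / pc$h^2)^1.5 *
    (pc$kB * T / (P * pc$bar_Pa))
  s_trans <- R * (log(q_trans) + 2.5)        # kcal/(mol K)
  e_trans <- 1.5 * R * T

  if (n == 1L) {
    if (!is.null(freqs) && length(freqs$frequencies) > 0L &&
        any(freqs$frequencies != 0))
      stop("a single atom has no vibrational modes")
    zpe <- 0; e_vib <- 0; s_vib <- 0; e_rot <- 0; s_rot <- 0
  } else {
    if (is.null(freqs)) stop("frequencies required for polyatomic species")
    linear <- isTRUE(freqs$linear_flag)
    rc <- rotational_constants(c)
    if (rc$degenerate_flag && !linear)
      stop("geometry is linear but linear_flag is not set")
    if (!rc$degenerate_flag && linear)
      stop("linear_flag set but geometry is not linear")
    nmode <- expected_mode_count(n, linear)
    if (length(freqs$frequencies) != nmode)
      stop("expected ", nmode, " modes for ", n, " atoms, got ",
           length(freqs$frequencies))
    nu <- scale_frequencies(freqs$frequencies, scale)

    # rotational (classical): theta = h^2/(8 pi^2 I kB) via B = h/(8 pi^2 I)
    # so theta = h B / kB with B in Hz
    theta <- function(B_GHz) pc$h * B_GHz * 1e9 / pc$kB
    if (linear) {
      q_rot <- T / (sigma * theta(rc$B))
      s_rot <- R * (log(q_rot) + 1)
      e_rot <- R * T
    } else {
      q_rot <- sqrt(pi) / sigma *
        sqrt(T^3 / (theta(rc$A) * theta(rc$B) * theta(rc$C)))
      s_rot <- R * (log(q_rot) + 1.5)
      e_rot <- 1.5 * R * T
    }

    # vibrational: x = h c nu / kB T per mode
    x <- pc$h * pc$c * nu / (pc$kB * T)
    zpe <- sum(R * (pc$h * pc$c * nu / pc$kB) / 2)   # R*theta_v/2 per mode
    e_vib <- sum(R * (pc$h * pc$c * nu / pc$kB) / (exp(x) - 1))
    s_vib <- R * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  }

  s_corr <- s_trans + s_rot + s_vib                  # kcal/(mol K)
  h_corr <- zpe + e_trans + e_rot + e_vib + R * T    # + RT for PV (H = E + PV)
  g_corr <- h_corr - T * s_corr
  structure(list(zpe = zpe, h_corr = h_corr,
                 s_corr = s_corr * 1000,             # cal/(mol K)
                 g_corr = g_corr,
                 temperature = T, pressure = P, scale_factor = scale,
                 sigma = sigma),
            class = "thermo_corrections")
}

#' @export
print.thermo_corrections <- function(x, ...) {
  cat(sprintf(paste0("<thermo @ %.2f K, %g bar (scale %.3f): ZPE %.3f, ",
                     "Hcorr %.3f, Gcorr %.3f kcal/mol, Scorr %.3f cal/(mol K)>\n"),
              x$temperature, x$pressure, x$scale_factor,
              x$zpe, x$h_corr, x$g_corr, x$s_corr))
  invisible(x)
}

#' Gas-to-solution standard-state offset
#'
#' The free-energy change of moving from the 1 bar ideal-gas standard state
#' to the 1 mol/L solution standard state, \eqn{RT \ln(c^\circ R T /
#' p^\circ)}. It is about 2 kcal/mol at 310 K and is constant across
#' conformers of one molecule, so it cancels in relative conformer free
#' energies; the pipeline reports it but never silently adds it.
#'
#' @param T temperature in K.
#' @return Offset in kcal/mol.
#' @export
standard_state_offset <- function(T) {
  if (T <= 0) stop("temperature must be positive")
  pc <- physical_constants()
  # RT * c0 / p0 with c0 = 1 mol/L = 1000 mol/m^3, p0 = 1 bar
  ratio <- pc$R_J * T * 1000 / pc$bar_Pa
  pc$R_kcal * T * log(ratio)
}
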