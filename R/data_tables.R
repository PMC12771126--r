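#' Published pharmacology of fentanyl and 33 analogs
#'
#' Experimental hMOR binding affinities (Ki) and potencies (EC50), in nM,
#' for fentanyl (analog 1) and 33 derivatives, as compiled in the published
#' pharmacology literature for this analog series. Censored entries are
#' kept as character strings (\code{">500"}, \code{">1000"}, \code{">2000"})
#' so downstream correlation code can treat them explicitly.
#'
#' @return data.frame with columns \code{analog_id}, \code{name},
#'   \code{ki_nM} (numeric) and \code{ec50_nM} (character; may be censored).
#' @export
fentanyl_pharmacology <- function() {
  data.frame(
    analog_id = as.character(1:34),
    name = c("fentanyl", "cyclopropyl", "p-methyl cyclopropyl", "cyclobutyl",
             "cyclopentyl", "furanyl", "tetrahydrofuran", "acetyl",
             "o-methyl acetyl", "alpha-methyl acetyl", "acryl",
             "o-fluoro acryl", "p-fluoro acryl", "isobutyryl",
             "o-fluoro isobutyryl", "m-fluoro isobutyryl",
             "p-fluoro isobutyryl", "p-chloro isobutyryl", "pivaloyl",
             "butyryl", "o-fluoro butyryl", "methoxyacetyl", "o-fluoro",
             "m-fluoro", "p-fluoro", "o-methyl", "m-methyl", "p-methyl",
             "p-chloro", "cis-3-methyl", "trans-3-methyl", "furanylethyl",
             "beta-hydroxy", "beta-methyl"),
    ki_nM = c(1.6, 2.4, 7.2, 5, 6.6, 1.3, 31, 64, 43, 19, 2.1, 1.1, 4.3,
              6.6, 1.3, 4.5, 24, 82, 4.5, 3.5, 0.7, 17, 0.4, 10, 4.2, 3.4,
              5.5, 4.2, 45, 0.32, 1.1, 8, 6.2, 14),
    ec50_nM = c("32", "55", ">1000", "160", "600", "9.3", "360", ">2000",
                ">1000", ">500", "68", "14", "84", "137", "42", ">500",
                ">1000", ">2000", "531", "80", "60", ">500", "15", "164",
                "79", "58", "450", ">1000", ">1000", "4.2", "25", "350",
                "138", ">500"),
    stringsAsFactors = FALSE)
}

#' Published funnel survivor counts and stabilization energies per analog
#'
#' Per-analog summary of the published computational funnel over the
#' fentanyl analog series: the number of unique conformers surviving each
#' stage (conformational sampling; DFT re-optimization; the coupled-cluster
#' cc-pVNZ stage, i.e. the 8 kcal/mol electronic-energy window; and the
#' heavy-augmented refinement of conformers with Boltzmann population above
#' 5\%) together with the ensemble stabilization free energy
#' \eqn{\Delta G^\circ_{\{A\}}} in kcal/mol at 310.15 K.
#'
#' These are reference values for comparison and correlation studies; the
#' package does not recompute them (doing so requires the underlying
#' quantum-chemistry data set).
#'
#' @return data.frame with columns \code{analog_id}, \code{n_sampling},
#'   \code{n_dft}, \code{n_ccsdt}, \code{n_haug}, \code{dg_stab_kcal}.
#' @export
analog_funnel_summary <- function() {
  data.frame(
    analog_id = as.character(1:34),
    n_sampling = c(229, 259, 177, 145, 253, 157, 485, 126, 213, 162, 172,
                   292, 228, 226, 288, 320, 246, 261, 167, 428, 655, 393,
                   315, 397, 235, 405, 450, 382, 295, 409, 427, 309, 503,
                   536),
    n_dft = c(82, 89, 50, 61, 100, 70, 206, 40, 52, 65, 71, 136, 83, 83,
              85, 127, 79, 71, 52, 170, 284, 168, 129, 173, 87, 143, 133,
              95, 93, 114, 130, 137, 296, 238),
    n_ccsdt = c(60, 69, 37, 49, 77, 55, 146, 32, 49, 51, 51, 101, 60, 59,
                61, 127, 53, 51, 52, 133, 210, 118, 91, 117, 62, 124, 102,
                69, 71, 99, 83, 102, 246, 214),
    n_haug = c(3, 7, 3, 4, 5, 6, 5, 3, 5, 3, 4, 4, 3, 4, 5, 6, 4, 4, 6, 3,
               4, 5, 5, 5, 2, 3, 3, 7, 6, 5, 3, 5, 5, 4),
    dg_stab_kcal = c(-0.34, -0.97, -0.57, -0.58, -0.81, -0.71, -0.98,
                     -0.17, -0.52, -0.36, -0.33, -0.52, -0.66, -0.52,
                     -0.83, -0.81, -0.62, -0.71, -0.76, -0.32, -1.27,
                     -0.39, -0.80, -0.90, -0.31, -0.65, -0.66, -1.03,
                     -0.95, -0.65, -0.67, -0.81, -0.94, -0.42),
    stringsAsFactors = FALSE)
}

#' Published zeta-level relative free energies for trans-3-methyl fentanyl
#'
#' Relative Gibbs free energies (kcal/mol, 310.15 K) of the seven
#' high-population conformers of trans-3-methyl fentanyl (analog 31 of the
#' series) computed with DLPNO-CCSD(T)/haug-cc-pVNZ/SMD model chemistries at
#' the double- through quintuple-zeta levels, together with the published
#' three-point CBS extrapolation of the D/T/Q columns. All values as
#' printed, i.e. rounded to three decimals. Used to validate
#' \code{\link{cbs_extrapolate}} and
#' \code{\link{basis_convergence_report}} against published numbers.
#'
#' @return data.frame with columns \code{conformer_id}, \code{haDZ},
#'   \code{haTZ}, \code{haQZ}, \code{ha5Z}, \code{cbs_published},
#'   \code{ddg_QZ_TZ_published}, \code{ddg_5Z_QZ_published}.
#' @export
analog31_zeta_energies <- function() {
  data.frame(
    conformer_id = c("265", "151", "161", "128", "207", "261", "250"),
    haDZ = c(0.000, 1.920, 1.564, 1.826, 2.255, 1.809, 2.360),
    haTZ = c(0.000, 2.207, 1.870, 2.078, 2.320, 1.658, 2.397),
    haQZ = c(0.000, 2.330, 2.067, 2.363, 2.408, 1.617, 2.429),
    ha5Z = c(0.000, 2.321, 2.101, 2.431, 2.449, 1.611, 2.448),
    cbs_published = c(0.000, 2.445, 2.280, 2.707, 2.518, 1.588, 2.464),
    ddg_QZ_TZ_published = c(0.000, 0.123, 0.197, 0.285, 0.089, -0.041,
                            0.031),
    ddg_5Z_QZ_published = c(0.000, -0.009, 0.033, 0.068, 0.041, -0.006,
                            0.020),
    stringsAsFactors = FALSE)
}
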