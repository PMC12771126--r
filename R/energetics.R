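#' Three-point 4-5 inverse-polynomial CBS extrapolation
#'
#' Extrapolates energies computed in a systematic double/triple/quadruple-
#' zeta basis-set sequence to the complete-basis-set limit:
#' \deqn{E_{CBS} = (243 E_{DZ} - 2048 E_{TZ} + 3125 E_{QZ}) / 1320}
#' With the zeta levels D, T, Q mapped to N = 3, 4, 5, these coefficients
#' (\eqn{3^5}, \eqn{2 \cdot 4^5}, \eqn{5^5}) annihilate both terms of an
#' \eqn{E_N = E_\infty + a N^{-4} + b N^{-5}} convergence form exactly. The
#' scheme is linear, so it applies equally to absolute electronic energies
#' and to relative or free energies whose thermal part is level-independent.
#'
#' @param e_dz,e_tz,e_qz energies at the double-, triple- and quadruple-zeta
#'   levels, in any single consistent unit; vectors extrapolate elementwise.
#' @return Extrapolated CBS-limit energy in the same unit.
#' @export
cbs_extrapolate <- function(e_dz, e_tz, e_qz) {
  if (!all(is.finite(e_dz), is.finite(e_tz), is.finite(e_qz)))
    stop("non-finite energy passed to CBS extrapolation")
  (243 * e_dz - 2048 * e_tz + 3125 * e_qz) / 1320
}

#' Composite Gibbs free energy of one conformer
#'
#' Combines the electronic energy at a named level (hartree) with the RRHO
#' Gibbs correction (kcal/mol) into a composite free energy in hartree. The
#' level label, temperature and frequency scale factor are stamped on the
#' result so ensembles of mixed provenance are rejected downstream.
#'
#' @param e an \code{\link{energy_record}}.
#' @param t a \code{\link{thermo_corrections}}.
#' @param level electronic-energy level label to use.
#' @return Object of class \code{composite_gibbs}: \code{conformer_id},
#'   \code{e_elec} and \code{g_total} (hartree), \code{g_corr} (kcal/mol),
#'   \code{level_label}, \code{temperature}, \code{scale_factor}.
#' @export
composite_gibbs <- function(e, t, level) {
  pc <- physical_constants()
  e_elec <- energy_at(e, level)
  g_total <- e_elec + t$g_corr / pc$hartree_kcal
  structure(list(conformer_id = e$conformer_id,
                 e_elec = e_elec, g_corr = t$g_corr, g_total = g_total,
                 level_label = level,
                 temperature = t$temperature,
                 scale_factor = t$scale_factor),
            class = "composite_gibbs")
}

#' Relative Gibbs free energies of an ensemble
#'
#' Subtracts the ensemble minimum, yielding per-conformer relative free
#' energies in kcal/mol with the global-minimum conformer as reference
#' (ties broken by lexicographically smallest id). Mixing level labels is an
#' error: relative energies across inconsistent model chemistries are
#' meaningless.
#'
#' @param ensemble list of \code{\link{composite_gibbs}} objects.
#' @return Object of class \code{relative_energy_table}: data.frame
#'   \code{table} with columns \code{conformer_id}, \code{dg_kcal};
#'   \code{reference_id}; \code{level_label}; \code{temperature}.
#' @export
relative_gibbs <- function(ensemble) {
  if (length(ensemble) < 1L) stop("empty ensemble")
  levels <- unique(vapply(ensemble, function(x) x$level_label, character(1)))
  if (length(levels) != 1L)
    stop("mixed level labels in ensemble: ", paste(levels, collapse = ", "),
         "; relative energies require one consistent level")
  pc <- physical_constants()
  ids <- vapply(ensemble, function(x) x$conformer_id, character(1))
  g <- vapply(ensemble, function(x) x$g_total, numeric(1))
  gmin <- min(g)
  ref <- min(ids[g == gmin])
  dg <- (g - g[ids == ref][1]) * pc$hartree_kcal
  structure(list(
    table = data.frame(conformer_id = ids, dg_kcal = dg,
                       stringsAsFactors = FALSE),
    reference_id = ref,
    level_label = levels,
    temperature = ensemble[[1]]$temperature),
    class = "relative_energy_table")
}

#' Construct a relative-energy table from plain values
#'
#' Convenience constructor for workflows that already hold relative free
#' energies in kcal/mol (e.g. published tables). Values are re-referenced to
#' their minimum.
#'
#' @param ids conformer ids.
#' @param dg_kcal relative free energies, kcal/mol.
#' @param level_label level label stamp.
#' @param temperature Kelvin.
#' @return A \code{relative_energy_table}.
#' @export
relative_energy_table <- function(ids, dg_kcal, level_label = "CBS(DTQ)",
                                  temperature = 310.15) {
  if (length(ids) != length(dg_kcal) || length(ids) == 0L)
    stop("ids and dg_kcal must have equal, positive length")
  dg <- dg_kcal - min(dg_kcal)
  ref <- min(as.character(ids)[dg == 0])
  structure(list(
    table = data.frame(conformer_id = as.character(ids), dg_kcal = dg,
                       stringsAsFactors = FALSE),
    reference_id = ref, level_label = level_label,
    temperature = temperature),
    class = "relative_energy_table")
}

#' @export
print.relative_energy_table <- function(x, ...) {
  cat(sprintf("<relative energies (%s, %.2f K): %d conformers, ref %s>\n",
              x$level_label, x$temperature, nrow(x$table), x$reference_id))
  invisible(x)
}

#' Keep conformers within an energy window of the minimum
#'
#' The funnel step that limits expensive follow-up calculations to
#' low-energy structures: entries with relative energy less than or equal to
#' the window survive (inclusive boundary). Applied to relative DFT
#' electronic energies in the default pipeline, window 8 kcal/mol.
#'
#' @param rel a \code{relative_energy_table} (free or electronic relative
#'   energies in kcal/mol).
#' @param window window width in kcal/mol, >= 0.
#' @return Character vector of surviving conformer ids, in table order.
#' @export
energy_window_filter <- function(rel, window) {
  if (window < 0) stop("window must be non-negative")
  rel$table$conformer_id[rel$table$dg_kcal <= window]
}
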