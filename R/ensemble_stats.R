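#' Boltzmann population percentages of an ensemble
#'
#' Equilibrium population share of each conformer at temperature T:
#' \deqn{BP_i = 100 \exp(-\Delta G^\circ_i / RT) / \sum_j \exp(-\Delta
#' G^\circ_j / RT)}
#' with R = 1.987204259e-3 kcal/(mol K). The relative-energy table must
#' cover the \emph{complete} surviving ensemble at one level: percentages
#' computed from a partial subset (e.g. only the conformers refined with
#' augmented basis sets) have an incomplete denominator and are refused
#' unless \code{complete} is asserted.
#'
#' @param rel a \code{relative_energy_table}.
#' @param T temperature in K (default: the table's own temperature).
#' @param complete assertion that the table covers the whole surviving
#'   ensemble at this level (default TRUE; pass FALSE to get an error
#'   explaining the refusal rather than silently biased percentages).
#' @return Object of class \code{population_table}: data.frame \code{table}
#'   with \code{conformer_id}, \code{dg_kcal}, \code{bp_percent} sorted by
#'   descending population, plus \code{temperature} and \code{level_label}.
#' @export
boltzmann_percentages <- function(rel, T = rel$temperature, complete = TRUE) {
  if (!isTRUE(complete))
    stop("refusing to compute Boltzmann percentages from an incomplete ",
         "ensemble: the denominator must sum over every surviving ",
         "conformer at this level")
  R <- physical_constants()$R_kcal
  dg <- rel$table$dg_kcal
  w <- exp(-dg / (R * T))
  bp <- 100 * w / sum(w)
  ord <- order(-bp, rel$table$conformer_id)
  structure(list(
    table = data.frame(conformer_id = rel$table$conformer_id[ord],
                       dg_kcal = dg[ord], bp_percent = bp[ord],
                       stringsAsFactors = FALSE),
    temperature = T, level_label = rel$level_label,
    complete_flag = TRUE),
    class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<Boltzmann populations (%s, %.2f K): %d conformers, max %.2f%%>\n",
              x$level_label, x$temperature, nrow(x$table),
              max(x$table$bp_percent)))
  invisible(x)
}

#' Ensemble stabilization correction to the Gibbs free energy
#'
#' The free-energy lowering of an analog's conformer ensemble relative to
#' its single global minimum, from the entropic benefit of multiple
#' thermally accessible conformers:
#' \deqn{\Delta G^\circ_{\{A\}} = -RT \ln \sum_{i \in \{A\}}
#' \exp(-\Delta G^\circ_i / RT)}
#' Always non-positive; zero only for a single conformer at the reference.
#'
#' @param rel a \code{relative_energy_table} (reference at 0 present).
#' @param T temperature in K.
#' @return Object of class \code{stabilization_result}: \code{dg_stab}
#'   (kcal/mol), \code{n_conformers}, \code{temperature}.
#' @export
stabilization_correction <- function(rel, T = rel$temperature) {
  dg <- rel$table$dg_kcal
  if (length(dg) == 0L) stop("empty ensemble")
  R <- physical_constants()$R_kcal
  dg_stab <- -R * T * log(sum(exp(-dg / (R * T))))
  structure(list(dg_stab = dg_stab, n_conformers = length(dg),
                 temperature = T),
            class = "stabilization_result")
}

#' @export
print.stabilization_result <- function(x, ...) {
  cat(sprintf("<stabilization dG{A} = %.3f kcal/mol over %d conformers at %.2f K>\n",
              x$dg_stab, x$n_conformers, x$temperature))
  invisible(x)
}

#' Conformers above a population cutoff
#'
#' Selects conformers whose Boltzmann percentage is strictly greater than
#' the cutoff ("above X percent"), returned in descending population order.
#'
#' @param pop a \code{population_table}.
#' @param cutoff percent, in [0, 100).
#' @return Character vector of conformer ids.
#' @export
population_subset <- function(pop, cutoff) {
  if (cutoff < 0 || cutoff >= 100) stop("cutoff must lie in [0, 100)")
  pop$table$conformer_id[pop$table$bp_percent > cutoff]
}

#' Census of conformation classes above a population cutoff
#'
#' Counts cis, trans and gauche conformers among those with Boltzmann
#' percentage above the cutoff.
#'
#' @param labels named character vector (or list of
#'   \code{conformation_label}s) keyed by conformer id.
#' @param pop a \code{population_table} over the same conformer ids.
#' @param cutoff population cutoff, percent (strict inequality).
#' @return Object of class \code{census}: named integer vector \code{counts}
#'   (cis, trans, gauche), \code{bp_cutoff}, \code{n_total}.
#' @export
conformer_type_census <- function(labels, pop, cutoff = 0.5) {
  if (is.list(labels))
    labels <- vapply(labels, function(l) l$label, character(1))
  sel <- population_subset(pop, cutoff)
  miss <- setdiff(sel, names(labels))
  if (length(miss) > 0L)
    stop("no conformation label for conformer(s): ",
         paste(miss, collapse = ", "))
  lab <- labels[sel]
  counts <- c(cis = sum(lab == "cis"), trans = sum(lab == "trans"),
              gauche = sum(lab == "gauche"))
  structure(list(counts = counts, bp_cutoff = cutoff,
                 n_total = length(sel)),
            class = "census")
}

#' @export
print.census <- function(x, ...) {
  cat(sprintf("<census (BP > %g%%): %d cis, %d trans, %d gauche>\n",
              x$bp_cutoff, x$counts["cis"], x$counts["trans"],
              x$counts["gauche"]))
  invisible(x)
}

#' Correlation of a per-analog conformational summary with pharmacology
#'
#' Descriptive rank (Spearman) and linear (Pearson, on log10 nM)
#' correlations between a per-analog summary statistic (e.g. the ensemble
#' stabilization free energy) and experimental binding affinity (Ki) and
#' potency (EC50). Censored potency entries (strings like \code{">1000"})
#' are included as tied maxima in the rank correlation and excluded from the
#' log-linear correlation; both treatments are reported. No significance
#' claim is made.
#'
#' @param per_analog named numeric vector, analog id -> summary value.
#' @param pharm data.frame with columns \code{analog_id}, \code{ki_nM},
#'   \code{ec50_nM}; potency columns may be character with censored
#'   \code{">x"} entries (see \code{\link{fentanyl_pharmacology}}).
#' @return Object of class \code{correlation_report}: one row per
#'   (endpoint, method) combination with the coefficient and the number of
#'   analogs used.
#' @export
pharmacology_correlation <- function(per_analog, pharm) {
  shared <- intersect(names(per_analog), as.character(pharm$analog_id))
  if (length(shared) < 3L)
    stop("need at least 3 shared analogs, have ", length(shared))
  pharm <- pharm[match(shared, as.character(pharm$analog_id)), , drop = FALSE]
  x <- unname(per_analog[shared])

  parse_censored <- function(v) {
    v <- as.character(v)
    censored <- grepl("^>", v)
    value <- suppressWarnings(as.numeric(sub("^>", "", v)))
    list(value = value, censored = censored)
  }
  one_endpoint <- function(v, endpoint) {
    p <- parse_censored(v)
    ok <- !is.na(p$value)
    # Spearman: censored entries enter as tied maxima (rank handles ties);
    # push them just past the largest observed value so they tie together
    rank_val <- p$value
    if (any(p$censored & ok))
      rank_val[p$censored] <- max(p$value[ok]) * 10
    sp <- stats::cor(x[ok], rank(rank_val[ok]), method = "spearman")
    # Pearson on log10 nM over uncensored entries only
    unc <- ok & !p$censored
    pe <- if (sum(unc) >= 3L)
      stats::cor(x[unc], log10(p$value[unc]), method = "pearson")
    else NA_real_
    data.frame(endpoint = endpoint,
               method = c("spearman", "pearson_log10"),
               coefficient = c(sp, pe),
               n = c(sum(ok), sum(unc)),
               stringsAsFactors = FALSE)
  }
  report <- rbind(one_endpoint(pharm$ki_nM, "ki"),
                  one_endpoint(pharm$ec50_nM, "ec50"))
  structure(list(report = report, analogs = shared),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<pharmacology correlation over %d analogs>\n",
              length(x$analogs)))
  print(x$report, row.names = FALSE)
  invisible(x)
}
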