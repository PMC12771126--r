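#' Pipeline configuration
#'
#' Collects every tunable constant of the conformer funnel in one place;
#' the defaults are the physiological-temperature protocol: 310.15 K, 1 bar,
#' frequency scale 0.971, duplicate tolerances 1\% / 0.1 kcal/mol, an
#' 8 kcal/mol electronic-energy window, population cutoffs 0.5\% and 5\%,
#' and cis/gauche/trans boundaries at 60 and 135 degrees. The full
#' configuration is embedded in every report.
#'
#' @param temperature K.
#' @param pressure bar.
#' @param scale_factor harmonic-frequency scale factor.
#' @param rot_tol relative rotational-constant tolerance for deduplication.
#' @param e_tol dedup energy tolerance, kcal/mol.
#' @param window electronic-energy window, kcal/mol.
#' @param bp_cutoffs population cutoffs, percent (census uses the first).
#' @param cis_max,trans_min conformation class boundaries, degrees.
#' @param bp_level electronic-energy level for composite free energies and
#'   Boltzmann percentages.
#' @param dedup_level level used for the dedup energy comparison.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(temperature = 310.15, pressure = 1,
                            scale_factor = 0.971, rot_tol = 0.01,
                            e_tol = 0.1, window = 8,
                            bp_cutoffs = c(0.5, 5),
                            cis_max = 60, trans_min = 135,
                            bp_level = "CBS(DTQ)", dedup_level = "DFT") {
  stopifnot(temperature > 0, pressure > 0, scale_factor > 0,
            rot_tol > 0, e_tol > 0, window >= 0)
  structure(list(temperature = temperature, pressure = pressure,
                 scale_factor = scale_factor, rot_tol = rot_tol,
                 e_tol = e_tol, window = window, bp_cutoffs = bp_cutoffs,
                 cis_max = cis_max, trans_min = trans_min,
                 bp_level = bp_level, dedup_level = dedup_level),
            class = "pipeline_config")
}

# run one analog through the funnel; internal worker for run_pipeline
.run_analog <- function(ens, config, pharm = NULL) {
  pc <- physical_constants()
  ids <- vapply(ens$conformers, function(c) c$conformer_id, character(1))
  names(ens$conformers) <- ids
  names(ens$energies) <- vapply(ens$energies, function(e) e$conformer_id,
                                character(1))
  names(ens$frequencies) <- vapply(ens$frequencies, function(f)
    f$conformer_id, character(1))
  stages <- c(input = length(ids))

  # 1. duplicate removal on the sampling-level energies
  e_dedup <- vapply(ids, function(id)
    energy_at(ens$energies[[id]], config$dedup_level) * pc$hartree_kcal,
    numeric(1))
  dec <- deduplicate(ens$conformers, e_dedup, rot_tol = config$rot_tol,
                     e_tol = config$e_tol)
  ids <- dec$kept_ids
  stages["dedup"] <- length(ids)

  # 2. electronic-energy window about the minimum
  rel_elec <- relative_energy_table(
    ids, e_dedup[ids], level_label = config$dedup_level,
    temperature = config$temperature)
  ids <- energy_window_filter(rel_elec, config$window)
  stages["window"] <- length(ids)

  # 3. RRHO corrections and composite free energies at the BP level
  level <- config$bp_level
  composites <- lapply(ids, function(id) {
    tc <- thermo_corrections(ens$conformers[[id]], ens$frequencies[[id]],
                             T = config$temperature, P = config$pressure,
                             scale = config$scale_factor)
    rec <- ens$energies[[id]]
    if (!level %in% names(rec$energies) &&
        all(c("DZ", "TZ", "QZ") %in% names(rec$energies)) &&
        level == "CBS(DTQ)") {
      rec <- energy_record(id, c(rec$energies,
        "CBS(DTQ)" = cbs_extrapolate(rec$energies[["DZ"]],
                                     rec$energies[["TZ"]],
                                     rec$energies[["QZ"]])))
    }
    composite_gibbs(rec, tc, level)
  })
  rel <- relative_gibbs(composites)
  stages["thermo"] <- length(ids)

  # 4. populations, stabilization, classes, census
  pop <- boltzmann_percentages(rel, T = config$temperature)
  stab <- stabilization_correction(rel, T = config$temperature)
  labels <- vapply(ids, function(id)
    classify_conformation(ens$conformers[[id]],
                          cis_max = config$cis_max,
                          trans_min = config$trans_min)$label,
    character(1))
  census <- conformer_type_census(labels, pop, cutoff = config$bp_cutoffs[1])

  entries <- merge(pop$table,
                   data.frame(conformer_id = ids, class = unname(labels),
                              stringsAsFactors = FALSE),
                   by = "conformer_id")
  entries <- entries[order(-entries$bp_percent, entries$conformer_id), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(analog_id = ens$analog_id, stages = stages,
                 entries = entries, reference_id = rel$reference_id,
                 dg_stab = stab$dg_stab, census = census,
                 population_subsets = lapply(config$bp_cutoffs, function(ct)
                   population_subset(pop, ct)),
                 dedup = dec, config = config),
            class = "analog_report")
}

#' @export
print.analog_report <- function(x, ...) {
  cat(sprintf("<analog %s: %s; dG{A} = %.3f kcal/mol>\n", x$analog_id,
              paste(sprintf("%s %d", names(x$stages), x$stages),
                    collapse = " -> "), x$dg_stab))
  invisible(x)
}

#' Run the conformer funnel over analog ensembles
#'
#' Executes the full post-processing funnel per analog: duplicate removal
#' (rotational constants within 1\% and energies within 0.1 kcal/mol),
#' electronic-energy window filtering, RRHO thermochemistry with scaled
#' frequencies, composite CBS-extrapolated free energies, Boltzmann
#' populations, ensemble stabilization, cis/trans/gauche classification and
#' census, and optionally a pharmacology correlation over all analogs. A
#' failing analog is reported as an error entry without affecting the
#' others; identical inputs and configuration give identical reports.
#'
#' @param manifests character vector of manifest paths, or a list of
#'   in-memory ensembles (as produced by \code{\link{generate_ensemble}} or
#'   \code{\link{read_ensemble}}).
#' @param config a \code{\link{pipeline_config}}.
#' @param pharm optional pharmacology table (see
#'   \code{\link{fentanyl_pharmacology}}) correlated against the per-analog
#'   stabilization energies.
#' @return List of class \code{funnel_report}: \code{analogs} (one
#'   \code{analog_report} or error record per input), \code{summary}
#'   data.frame of per-stage survivor counts and stabilization energies,
#'   \code{correlation} (or NULL), \code{config}.
#' @export
run_pipeline <- function(manifests, config = pipeline_config(),
                         pharm = NULL) {
  ensembles <- lapply(manifests, function(m)
    if (is.character(m)) read_ensemble(m) else m)
  reports <- lapply(ensembles, function(ens) {
    tryCatch(.run_analog(ens, config),
             error = function(e)
               structure(list(analog_id = ens$analog_id,
                              error = conditionMessage(e)),
                         class = "analog_error"))
  })
  ok <- !vapply(reports, inherits, logical(1), "analog_error")
  summary <- if (any(ok)) {
    do.call(rbind, lapply(reports[ok], function(r)
      data.frame(analog_id = r$analog_id,
                 n_input = r$stages[["input"]],
                 n_dedup = r$stages[["dedup"]],
                 n_window = r$stages[["window"]],
                 n_cis = unname(r$census$counts["cis"]),
                 n_trans = unname(r$census$counts["trans"]),
                 n_gauche = unname(r$census$counts["gauche"]),
                 dg_stab_kcal = r$dg_stab,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame()
  }
  correlation <- NULL
  if (!is.null(pharm) && sum(ok) >= 3L) {
    per_analog <- stats::setNames(summary$dg_stab_kcal, summary$analog_id)
    correlation <- pharmacology_correlation(per_analog, pharm)
  }
  structure(list(analogs = reports, summary = summary,
                 correlation = correlation, config = config),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("<funnel report: %d analogs (%d failed)>\n",
              length(x$analogs),
              sum(vapply(x$analogs, inherits, logical(1), "analog_error"))))
  if (nrow(x$summary) > 0) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Basis-set convergence report for relative free energies
#'
#' Given per-conformer relative free energies at the heavy-augmented
#' double/triple/quadruple-zeta levels (and optionally quintuple-zeta),
#' appends the three-point CBS extrapolation and the consecutive-zeta
#' difference columns that quantify basis-set convergence:
#' \code{ddg_QZ_TZ = haQZ - haTZ} and \code{ddg_5Z_QZ = ha5Z - haQZ}.
#' A missing optional level drops its column with a warning; nothing is
#' fabricated.
#'
#' @param df data.frame with a conformer id column plus columns
#'   \code{haDZ}, \code{haTZ}, \code{haQZ} and optionally \code{ha5Z}
#'   (kcal/mol). Plain \code{DZ}/\code{TZ}/\code{QZ} column names are
#'   accepted too.
#' @return data.frame with the input levels, \code{cbs} and the
#'   consecutive-zeta difference columns.
#' @export
basis_convergence_report <- function(df) {
  lv <- function(base) {
    if (paste0("ha", base) %in% names(df)) paste0("ha", base)
    else if (base %in% names(df)) base
    else NA_character_
  }
  dz <- lv("DZ"); tz <- lv("TZ"); qz <- lv("QZ"); z5 <- lv("5Z")
  if (anyNA(c(dz, tz, qz)))
    stop("need DZ, TZ and QZ (or haDZ/haTZ/haQZ) columns")
  if (nrow(df) < 1L) stop("empty table")
  out <- df
  out$cbs <- cbs_extrapolate(df[[dz]], df[[tz]], df[[qz]])
  out$ddg_QZ_TZ <- df[[qz]] - df[[tz]]
  if (!is.na(z5)) {
    out$ddg_5Z_QZ <- df[[z5]] - df[[qz]]
  } else {
    warning("no quintuple-zeta column; ddg_5Z_QZ omitted")
  }
  out
}
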