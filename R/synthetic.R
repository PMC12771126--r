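# Run code under a temporary RNG state seeded from `seed`, restoring any
# pre-existing global state afterwards (no global side effects).
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random proper rotation matrix (uniform via QR of Gaussian matrix)
.random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a two-ring probe structure at a controlled ring separation angle
#'
#' Builds a chemically plausible toy scaffold mimicking the ring topology
#' that the conformation classifier relies on: a chair-form saturated
#' six-ring containing one nitrogen (the protonated-piperidine surrogate and
#' anchor atom, placed at the origin before the random reorientation), and
#' two planar six-carbon rings whose centroid directions seen from the
#' anchor are separated by exactly \code{angle_deg}. Idealized bond lengths
#' are used (aromatic C-C 1.39, ring C-C 1.53 Angstrom); classification
#' depends only on ring placement, so further chemical realism is not
#' needed.
#'
#' @param angle_deg ring-centroid separation angle, 0..180 degrees.
#' @param seed integer seed controlling the random rigid reorientation and
#'   optional coordinate jitter.
#' @param jitter_sd Gaussian coordinate noise, Angstrom (default 0).
#' @param conformer_id,analog_id identity metadata.
#' @return A \code{\link{conformer}} of 18 atoms (charge +1).
#' @export
generate_two_ring_probe <- function(angle_deg, seed = 1L, jitter_sd = 0,
                                    conformer_id = "probe",
                                    analog_id = "synthetic") {
  if (angle_deg < 0 || angle_deg > 180)
    stop("angle_deg must lie in [0, 180]")
  .with_seed(seed, {
    # chair saturated ring (5 C + 1 N), vertex 0 = N at origin
    d <- 0.25
    r <- sqrt(1.53^2 - 4 * d^2)  # vertex radius giving ring bonds of 1.53
    th <- (0:5) * pi / 3
    sat <- cbind(r * cos(th), r * sin(th), d * (-1)^(0:5))
    sat <- sweep(sat, 2L, sat[1, ])            # anchor N at the origin
    elements <- c("N", rep("C", 5))
    coords <- sat

    # two planar phenyl rings: centroid directions +/- angle/2 about +x in
    # the xz-plane; unequal anchor distances keep the rings separated even
    # at angle 0 (parallel-stacked, the cis exemplar)
    half <- angle_deg / 2 * pi / 180
    u1 <- c(cos(half), 0, sin(half))
    u2 <- c(cos(half), 0, -sin(half))
    place_ring <- function(u, L, phase) {
      cen <- L * u
      # in-plane basis perpendicular to u
      ref <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
      e1 <- ref - sum(ref * u) * u
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      ang <- (0:5) * pi / 3 + phase
      t(vapply(ang, function(a) cen + 1.39 * (cos(a) * e1 + sin(a) * e2),
               numeric(3)))
    }
    coords <- rbind(coords, place_ring(u1, 3.5, 0), place_ring(u2, 6.9, 0.3))
    elements <- c(elements, rep("C", 12))

    if (jitter_sd > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), sd = jitter_sd),
                                ncol = 3)
    # random rigid reorientation: classification must not depend on frame
    R <- .random_rotation()
    tvec <- stats::runif(3, -5, 5)
    coords <- sweep(coords %*% t(R), 2L, tvec, `+`)
    conformer(conformer_id, analog_id, elements, coords, charge = 1L,
              comment = sprintf("%s %s", analog_id, conformer_id))
  })
}

#' Specification of one synthetic analog ensemble
#'
#' Defines the statistical shape of a generated ensemble: the number of
#' conformers, the target cis/trans/gauche mixture (defaults follow the
#' roughly 57/12/31 split typical of fentanyl-family ensembles), the spread
#' of planted relative free energies, the planted complete-basis-set limit
#' and the \eqn{a N^{-4} + b N^{-5}} basis-convergence coefficients used to
#' synthesize the DZ/TZ/QZ energies, and the harmonic-frequency profile
#' (many low-frequency modes, as floppy drug-like molecules have).
#'
#' @param analog_id ensemble identifier.
#' @param n_conformers number of conformers (>= 1).
#' @param class_mix named fractions (cis, trans, gauche) summing to 1.
#' @param dg_spread_kcal maximum planted relative free energy, kcal/mol.
#' @param e_base planted CBS electronic energy of the reference conformer,
#'   hartree.
#' @param convergence_coeffs numeric length-2 (a, b), hartree.
#' @param n_low_modes number of low-frequency modes per conformer.
#' @param low_range,high_range wavenumber ranges (cm^-1) for low/high modes.
#' @param noise_sd Gaussian noise added to each synthesized electronic
#'   energy, hartree (0 = exact planted convergence form).
#' @param seed integer seed; all draws derive from it.
#' @return List of class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(analog_id = "synthetic", n_conformers = 40L,
                          class_mix = c(cis = 0.57, trans = 0.12,
                                        gauche = 0.31),
                          dg_spread_kcal = 8, e_base = -1000.0,
                          convergence_coeffs = c(15, -10),
                          n_low_modes = 12L,
                          low_range = c(30, 300),
                          high_range = c(400, 3200),
                          noise_sd = 0, seed = 1L) {
  if (n_conformers < 1L) stop("n_conformers must be >= 1")
  if (dg_spread_kcal < 0) stop("dg_spread_kcal must be >= 0")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix fractions must be non-negative")
  if (!all(c("cis", "trans", "gauche") %in% names(class_mix)))
    stop("class_mix needs named fractions cis, trans, gauche")
  if (sum(class_mix > 0) > n_conformers)
    stop("infeasible spec: more nonzero class fractions than conformers")
  structure(list(analog_id = analog_id,
                 n_conformers = as.integer(n_conformers),
                 class_mix = class_mix[c("cis", "trans", "gauche")],
                 dg_spread_kcal = dg_spread_kcal, e_base = e_base,
                 convergence_coeffs = convergence_coeffs,
                 n_low_modes = as.integer(n_low_modes),
                 low_range = low_range, high_range = high_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# largest-remainder apportionment of n into the class fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Generate a complete synthetic analog ensemble with planted ground truth
#'
#' Produces conformer geometries (two-ring probes at class-controlled ring
#' angles), electronic-energy records at the DFT, DZ, TZ and QZ levels,
#' harmonic frequency sets, and a ground-truth table recording what was
#' planted. Each conformer's DZ/TZ/QZ energies follow
#' \eqn{E_N = E_\infty + a N^{-4} + b N^{-5}} at N = 3, 4, 5, so with zero
#' noise the three-point extrapolation recovers the planted CBS limit
#' exactly. The planted CBS limits are constructed so that the composite
#' relative Gibbs free energies (CBS electronic energy plus each conformer's
#' own RRHO correction at 310.15 K) equal the planted relative free
#' energies. The DFT level is the planted CBS limit plus a constant 0.5
#' hartree shift, so relative DFT electronic energies differ from relative
#' free energies by the conformer-to-conformer variation of the thermal
#' correction, as in real ensembles.
#'
#' Deterministic for a fixed spec (the seed lives in the spec); the ground
#' truth table is test-only and never consumed by the pipeline.
#'
#' @param spec an \code{\link{ensemble_spec}}.
#' @return List: \code{conformers}, \code{energies} (energy records),
#'   \code{frequencies} (frequency sets), \code{truth} (data.frame:
#'   conformer_id, class, angle_deg, dg_planted_kcal, rank, cbs_hartree,
#'   g_corr_kcal), \code{analog_id}, \code{temperature}.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_conformers
  counts <- .apportion(n, spec$class_mix)
  classes <- rep(c("cis", "trans", "gauche"), counts)
  pc <- physical_constants()

  .with_seed(spec$seed, {
    classes <- sample(classes)
    angle_for <- function(cl) switch(cl,
      cis    = stats::runif(1, 5, 50),
      gauche = stats::runif(1, 65, 130),
      trans  = stats::runif(1, 140, 178))
    angles <- vapply(classes, angle_for, numeric(1))
    dg <- c(0, sort(stats::runif(n - 1L, 0, spec$dg_spread_kcal)))
    sub_seeds <- sample.int(.Machine$integer.max, n)
    # one base mode set per analog: conformers of a molecule share bonding,
    # so their frequency spectra differ only slightly (this keeps the
    # conformer-to-conformer spread of G_corr at realistic tenths of
    # kcal/mol rather than tens)
    nm0 <- expected_mode_count(18L)
    nlow0 <- min(spec$n_low_modes, nm0)
    base_modes <- c(stats::runif(nlow0, spec$low_range[1],
                                 spec$low_range[2]),
                    stats::runif(nm0 - nlow0, spec$high_range[1],
                                 spec$high_range[2]))

    conformers <- vector("list", n)
    freq_sets <- vector("list", n)
    energies <- vector("list", n)
    g_corr <- numeric(n)
    cbs <- numeric(n)
    ids <- sprintf("%s_c%03d", spec$analog_id, seq_len(n))
    for (i in seq_len(n)) {
      conformers[[i]] <- generate_two_ring_probe(
        angles[i], seed = sub_seeds[i], jitter_sd = 0.02,
        conformer_id = ids[i], analog_id = spec$analog_id)
      fr <- base_modes * (1 + stats::rnorm(length(base_modes), sd = 0.02))
      fr <- pmax(fr, 10)
      freq_sets[[i]] <- frequency_set(ids[i], fr)
      tc <- thermo_corrections(conformers[[i]], freq_sets[[i]],
                               T = 310.15, P = 1, scale = 0.971)
      g_corr[i] <- tc$g_corr
      # plant the CBS limit so composite relative dG equals dg[i]
      cbs[i] <- spec$e_base + (dg[i] - g_corr[i]) / pc$hartree_kcal
      a <- spec$convergence_coeffs[1]; b <- spec$convergence_coeffs[2]
      N <- c(DZ = 3, TZ = 4, QZ = 5)
      e_ladder <- cbs[i] + a * N^-4 + b * N^-5
      if (spec$noise_sd > 0)
        e_ladder <- e_ladder + stats::rnorm(3, sd = spec$noise_sd)
      e_dft <- cbs[i] + 0.5
      energies[[i]] <- energy_record(ids[i], c(e_ladder, DFT = e_dft))
    }
    truth <- data.frame(conformer_id = ids, class = classes,
                        angle_deg = angles, dg_planted_kcal = dg,
                        rank = seq_len(n), cbs_hartree = cbs,
                        g_corr_kcal = g_corr, stringsAsFactors = FALSE,
                        row.names = NULL)
    list(conformers = conformers, energies = energies,
         frequencies = freq_sets, truth = truth,
         analog_id = spec$analog_id, temperature = 310.15)
  })
}

#' Write a generated ensemble to disk in the pipeline's input formats
#'
#' Writes the XYZ ensemble, energy CSV, frequency CSV and JSON manifest that
#' \code{\link{read_ensemble}} consumes, plus the ground-truth CSV as a
#' separate test-only file the pipeline never reads.
#'
#' @param ens result of \code{\link{generate_ensemble}}.
#' @param dir output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aid <- ens$analog_id
  xyz <- file.path(dir, paste0(aid, ".xyz"))
  ecsv <- file.path(dir, paste0(aid, "_energies.csv"))
  fcsv <- file.path(dir, paste0(aid, "_frequencies.csv"))
  man <- file.path(dir, paste0(aid, "_manifest.json"))
  write_xyz_ensemble(ens$conformers, xyz)
  write_energy_table(ens$energies, ecsv)
  write_frequency_table(ens$frequencies, fcsv)
  utils::write.csv(ens$truth, file.path(dir, paste0(aid, "_truth.csv")),
                   row.names = FALSE)
  write_manifest(aid, basename(xyz), basename(ecsv), basename(fcsv), man,
                 charge = 1L, temperature = ens$temperature)
  invisible(man)
}
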