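#' Construct a conformer object
#'
#' A conformer is one 3D structure of a molecule: element symbols plus
#' Cartesian coordinates in Angstrom, tagged with the analog it belongs to.
#'
#' @param conformer_id character scalar, unique within an ensemble.
#' @param analog_id character scalar identifying the parent molecule.
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param charge integer total charge (protonated opioids are +1).
#' @param comment free-text comment (XYZ comment line on write).
#' @return Object of class \code{conformer}.
#' @export
conformer <- function(conformer_id, analog_id, elements, coords,
                      charge = 0L, comment = "") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be an n x 3 numeric matrix")
  if (length(elements) != nrow(coords) || length(elements) == 0L)
    stop("elements and coords must have equal, positive length")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  validate_elements(elements)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(conformer_id = as.character(conformer_id),
         analog_id = as.character(analog_id),
         elements = as.character(elements),
         coords = coords,
         charge = as.integer(charge),
         comment = as.character(comment)),
    class = "conformer"
  )
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s (analog %s): %d atoms, charge %+d>\n",
              x$conformer_id, x$analog_id, length(x$elements), x$charge))
  invisible(x)
}

n_atoms <- function(c) length(c$elements)

#' Construct an electronic-energy record
#'
#' Holds the electronic energies of one conformer at one or more levels of
#' theory, keyed by basis-set level label. Units are hartree.
#'
#' @param conformer_id character scalar.
#' @param energies named numeric vector; names drawn from
#'   \code{\link{energy_levels}}.
#' @return Object of class \code{energy_record}.
#' @export
energy_record <- function(conformer_id, energies) {
  energies <- unlist(energies)
  if (is.null(names(energies)) || any(!nzchar(names(energies))))
    stop("energies must be a named vector of level -> hartree")
  bad <- setdiff(names(energies), energy_levels())
  if (length(bad) > 0L)
    stop("unknown energy level label(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(energies)))
    stop("all energies must be finite")
  structure(
    list(conformer_id = as.character(conformer_id),
         energies = energies),
    class = "energy_record"
  )
}

#' Look up one level of an energy record
#'
#' @param rec energy_record.
#' @param level level label.
#' @return Energy in hartree; errors if the level is absent.
#' @export
energy_at <- function(rec, level) {
  if (!level %in% names(rec$energies))
    stop("conformer ", rec$conformer_id, " has no energy at level ", level)
  unname(rec$energies[[level]])
}

#' Construct a harmonic-frequency set
#'
#' Unscaled harmonic wavenumbers for one conformer, stored ascending.
#' Negative entries denote imaginary modes (saddle points) and are preserved
#' with a warning flag rather than dropped; downstream thermochemistry
#' refuses them explicitly.
#'
#' @param conformer_id character scalar.
#' @param frequencies numeric vector of wavenumbers in cm^-1.
#' @param linear_flag TRUE for linear molecules (3N-5 modes expected).
#' @return Object of class \code{frequency_set} with a \code{saddle_flag}
#'   element set when imaginary modes are present.
#' @export
frequency_set <- function(conformer_id, frequencies, linear_flag = FALSE) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0L)
    stop("empty frequency list for conformer ", conformer_id)
  if (!all(is.finite(frequencies)))
    stop("frequencies must be finite")
  frequencies <- sort(frequencies)
  saddle <- any(frequencies <= 0)
  if (saddle)
    warning("conformer ", conformer_id,
            " has non-positive frequencies (saddle point?)")
  structure(
    list(conformer_id = as.character(conformer_id),
         frequencies = frequencies,
         linear_flag = isTRUE(linear_flag),
         saddle_flag = saddle),
    class = "frequency_set"
  )
}

#' Expected vibrational mode count for a conformer
#'
#' 3N-6 for nonlinear, 3N-5 for linear, 0 for a single atom.
#'
#' @param n_atoms number of atoms.
#' @param linear_flag TRUE for linear molecules.
#' @return Integer mode count.
#' @export
expected_mode_count <- function(n_atoms, linear_flag = FALSE) {
  if (n_atoms == 1L) return(0L)
  if (linear_flag) 3L * n_atoms - 5L else 3L * n_atoms - 6L
}
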