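#' Read a multi-frame XYZ ensemble
#'
#' Parses standard multi-frame XYZ: a count line, a comment line, then N atom
#' lines per frame, repeated. Frame order is preserved. If the comment line
#' holds two whitespace-separated tokens they are taken as
#' \code{analog_id conformer_id} (the convention \code{\link{write_xyz_ensemble}}
#' uses); otherwise ids default to \code{analog_id} and \code{"<analog>_<frame>"}.
#'
#' @param path XYZ file path.
#' @param analog_id fallback analog id when the comment line does not carry one.
#' @param charge integer charge assigned to every conformer.
#' @return List of \code{\link{conformer}} objects, in file order.
#' @export
read_xyz_ensemble <- function(path, analog_id = "unknown", charge = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop("frame ", frame, ": malformed atom-count line: '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("frame ", frame, ": file truncated, expected ", nat, " atom lines")
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    nfield <- vapply(toks, length, integer(1))
    if (any(nfield < 4L))
      stop("frame ", frame, ": atom line with fewer than 4 fields: '",
           atom_lines[which(nfield < 4L)[1]], "'")
    elements <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) stop("frame ", frame, ": unparseable coordinate in '",
                         paste(tk, collapse = " "), "'")
      v
    }, numeric(3)))
    bad <- setdiff(elements, names(.atomic_masses))
    if (length(bad) > 0L)
      stop("frame ", frame, ": invalid element symbol(s): ",
           paste(unique(bad), collapse = ", "))
    ctoks <- strsplit(trimws(comment), "\\s+")[[1]]
    if (length(ctoks) == 2L) {
      aid <- ctoks[1]; cid <- ctoks[2]
    } else {
      aid <- analog_id; cid <- sprintf("%s_%d", analog_id, frame)
    }
    out[[frame]] <- conformer(cid, aid, elements, xyz,
                              charge = charge, comment = comment)
    i <- i + 2L + nat
  }
  out
}

#' Write conformers as a multi-frame XYZ file
#'
#' Coordinates are written with 10 decimal places; the comment line carries
#' \code{analog_id conformer_id} so a round trip preserves identity.
#'
#' @param conformers list of \code{\link{conformer}} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_xyz_ensemble <- function(conformers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (c in conformers) {
    writeLines(as.character(n_atoms(c)), con)
    writeLines(paste(c$analog_id, c$conformer_id), con)
    writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                       c$elements, c$coords[, 1], c$coords[, 2],
                       c$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a per-conformer electronic-energy table
#'
#' Comma-delimited with a header row: a \code{conformer_id} column plus one
#' column per level label (see \code{\link{energy_levels}}), energies in
#' hartree. Empty cells become absent levels, never zeros — the
#' heavy-augmented levels are typically computed only for a high-population
#' subset of an ensemble.
#'
#' @param path CSV path.
#' @return List of \code{\link{energy_record}} objects, in row order.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (!"conformer_id" %in% names(df))
    stop("energy table lacks a conformer_id column")
  lev_cols <- setdiff(names(df), "conformer_id")
  bad <- setdiff(lev_cols, energy_levels())
  if (length(bad) > 0L)
    stop("unknown energy level column(s): ", paste(bad, collapse = ", "))
  ids <- df$conformer_id
  if (anyDuplicated(ids))
    stop("duplicate conformer_id in energy table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    vals <- numeric(0)
    for (lv in lev_cols) {
      cell <- df[[lv]][i]
      if (is.na(cell) || !nzchar(cell)) next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        stop("non-numeric energy in row ", i, " (", ids[i], "), column ",
             lv, ": '", cell, "'")
      vals[lv] <- v
    }
    energy_record(ids[i], vals)
  })
}

#' Write an electronic-energy table
#'
#' @param records list of \code{\link{energy_record}} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_energy_table <- function(records, path) {
  levs <- energy_levels()
  used <- levs[levs %in% unique(unlist(lapply(records, function(r)
    names(r$energies))))]
  df <- data.frame(conformer_id = vapply(records, function(r)
    r$conformer_id, character(1)), stringsAsFactors = FALSE)
  for (lv in used) {
    df[[lv]] <- vapply(records, function(r) {
      if (lv %in% names(r$energies))
        sprintf("%.12f", r$energies[[lv]]) else ""
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-conformer harmonic-frequency table
#'
#' Long-format CSV with columns \code{conformer_id}, \code{wavenumber_cm1}
#' and optionally \code{linear_flag}. Frequencies are sorted ascending per
#' conformer on read; negative (imaginary) values are preserved and flagged,
#' never dropped.
#'
#' @param path CSV path.
#' @return List of \code{\link{frequency_set}} objects, in order of first
#'   appearance of each conformer id.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  need <- c("conformer_id", "wavenumber_cm1")
  if (!all(need %in% names(df)))
    stop("frequency table needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$wavenumber_cm1))
    stop("non-numeric wavenumber entries present")
  ids <- unique(df$conformer_id)
  lapply(ids, function(id) {
    sub <- df[df$conformer_id == id, , drop = FALSE]
    lin <- if ("linear_flag" %in% names(sub)) isTRUE(as.logical(sub$linear_flag[1])) else FALSE
    frequency_set(id, sub$wavenumber_cm1, linear_flag = lin)
  })
}

#' Write a harmonic-frequency table
#'
#' @param freq_sets list of \code{\link{frequency_set}} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_frequency_table <- function(freq_sets, path) {
  rows <- do.call(rbind, lapply(freq_sets, function(f)
    data.frame(conformer_id = f$conformer_id,
               wavenumber_cm1 = f$frequencies,
               linear_flag = f$linear_flag,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analog ensemble manifest
#'
#' A manifest is a small JSON object naming the three data files of one
#' analog ensemble (\code{xyz}, \code{energies}, \code{frequencies}) plus
#' \code{analog_id}, \code{charge} and \code{temperature}. Relative paths
#' resolve against the manifest's directory.
#'
#' @param path JSON manifest path.
#' @return List with the manifest fields and resolved absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("analog_id", "xyz", "energies", "frequencies")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L)
    stop("manifest missing field(s): ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (startsWith(p, "/")) p else file.path(base, p)
  m$xyz <- resolve(m$xyz)
  m$energies <- resolve(m$energies)
  m$frequencies <- resolve(m$frequencies)
  if (is.null(m$charge)) m$charge <- 0L
  if (is.null(m$temperature)) m$temperature <- 310.15
  m
}

#' Write an analog ensemble manifest
#'
#' @param analog_id analog identifier.
#' @param xyz,energies,frequencies file paths (stored as given).
#' @param path output JSON path.
#' @param charge integer molecular charge.
#' @param temperature Kelvin.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(analog_id, xyz, energies, frequencies, path,
                           charge = 1L, temperature = 310.15) {
  jsonlite::write_json(
    list(analog_id = analog_id, xyz = xyz, energies = energies,
         frequencies = frequencies, charge = charge,
         temperature = temperature),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a full ensemble from a manifest
#'
#' @param manifest path to a manifest JSON, or the list returned by
#'   \code{\link{read_manifest}}.
#' @return List with \code{analog_id}, \code{conformers}, \code{energies}
#'   (energy records), \code{frequencies} (frequency sets), \code{charge},
#'   \code{temperature}.
#' @export
read_ensemble <- function(manifest) {
  m <- if (is.character(manifest)) read_manifest(manifest) else manifest
  list(
    analog_id = m$analog_id,
    conformers = read_xyz_ensemble(m$xyz, analog_id = m$analog_id,
                                   charge = m$charge),
    energies = read_energy_table(m$energies),
    frequencies = read_frequency_table(m$frequencies),
    charge = m$charge,
    temperature = m$temperature
  )
}
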