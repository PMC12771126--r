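#' Remove duplicate conformers by the rotational-constant/energy rule
#'
#' Two conformers are duplicates when all three rotational constants agree
#' within a relative tolerance (default 1\%) and their energies agree within
#' an absolute tolerance (default 0.1 kcal/mol). Conformers are sorted by
#' ascending energy (ties broken by conformer id) and scanned greedily: a
#' candidate is deleted when it duplicates an already-kept conformer, and is
#' mapped to its lowest-energy twin. Sorting first makes the result
#' independent of input file order, and keeping the lower-energy member is
#' the conservative choice for downstream minima.
#'
#' @param conformers list of \code{\link{conformer}} objects.
#' @param energies_kcal named numeric vector, conformer id -> energy in
#'   kcal/mol at the comparison level (absolute or relative; only
#'   differences matter).
#' @param rot_tol relative rotational-constant tolerance (default 0.01).
#' @param e_tol energy tolerance in kcal/mol (default 0.1).
#' @param all_constants require all of A, B, C within tolerance (default
#'   TRUE, the strict reading of "rotational constants within 1\%"); FALSE
#'   accepts agreement of any one constant.
#' @param rot_constants optional precomputed list of
#'   \code{\link{rotational_constants}} named by conformer id (computed from
#'   the geometries when NULL).
#' @return Object of class \code{dedup_decision}: \code{kept_ids} (ordered by
#'   ascending energy), \code{removed} (named character vector,
#'   removed id -> surviving twin id), and the tolerances used.
#' @export
deduplicate <- function(conformers, energies_kcal, rot_tol = 0.01,
                        e_tol = 0.1, all_constants = TRUE,
                        rot_constants = NULL) {
  ids <- vapply(conformers, function(c) c$conformer_id, character(1))
  miss <- setdiff(ids, names(energies_kcal))
  if (length(miss) > 0L)
    stop("missing energy for conformer(s): ", paste(miss, collapse = ", "))
  if (is.null(rot_constants)) {
    rot_constants <- lapply(conformers, rotational_constants)
    names(rot_constants) <- ids
  }
  e <- unname(energies_kcal[ids])
  ord <- order(e, ids)
  kept <- character(0)
  removed <- character(0)
  for (k in ord) {
    id <- ids[k]
    twin <- NA_character_
    for (kid in kept) {
      if (abs(e[k] - energies_kcal[[kid]]) >= e_tol) next
      rc_k <- rot_constants[[id]]
      rc_j <- rot_constants[[kid]]
      rel <- abs(c(rc_k$A - rc_j$A, rc_k$B - rc_j$B, rc_k$C - rc_j$C)) /
        abs(c(rc_j$A, rc_j$B, rc_j$C))
      hit <- if (all_constants) all(rel < rot_tol) else any(rel < rot_tol)
      if (hit) { twin <- kid; break }
    }
    if (is.na(twin)) kept <- c(kept, id) else removed[id] <- twin
  }
  structure(list(kept_ids = kept, removed = removed,
                 rot_tol = rot_tol, e_tol = e_tol,
                 all_constants = all_constants),
            class = "dedup_decision")
}

#' @export
print.dedup_decision <- function(x, ...) {
  cat(sprintf("<dedup: %d kept, %d removed (rot_tol=%g, e_tol=%g kcal/mol)>\n",
              length(x$kept_ids), length(x$removed), x$rot_tol, x$e_tol))
  invisible(x)
}
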