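#' Rotational constants from atomic coordinates
#'
#' Diagonalizes the mass-weighted inertia tensor about the center of mass
#' (most-abundant-isotope masses) and converts the principal moments to
#' rotational constants in GHz via \eqn{B = h / (8 \pi^2 I)}. These are the
#' quantities the duplicate-conformer rule compares.
#'
#' @param c a \code{\link{conformer}}.
#' @return Object of class \code{rotational_constants}: \code{A >= B >= C}
#'   in GHz and \code{degenerate_flag} (TRUE for collinear geometries, where
#'   the moment about the axis vanishes, \code{A = Inf} and \code{B == C}).
#' @export
rotational_constants <- function(c) {
  n <- n_atoms(c)
  if (n < 2L) stop("rotational constants undefined for a single atom")
  m <- atomic_masses(c$elements)
  x <- c$coords
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2L, com)
  # inertia tensor, amu A^2
  Ixx <- sum(m * (x[, 2]^2 + x[, 3]^2))
  Iyy <- sum(m * (x[, 1]^2 + x[, 3]^2))
  Izz <- sum(m * (x[, 1]^2 + x[, 2]^2))
  Ixy <- -sum(m * x[, 1] * x[, 2])
  Ixz <- -sum(m * x[, 1] * x[, 3])
  Iyz <- -sum(m * x[, 2] * x[, 3])
  Iten <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3L, 3L)
  mom <- sort(eigen(Iten, symmetric = TRUE, only.values = TRUE)$values)
  pc <- physical_constants()
  to_ghz <- function(I_amuA2) {
    I_SI <- I_amuA2 * pc$amu * 1e-20
    pc$h / (8 * pi^2 * I_SI) / 1e9
  }
  degenerate <- mom[1] <= max(mom) * 1e-10
  if (degenerate) {
    B <- to_ghz(mom[2])
    consts <- c(A = Inf, B = B, C = to_ghz(mom[3]))
  } else {
    consts <- c(A = to_ghz(mom[1]), B = to_ghz(mom[2]), C = to_ghz(mom[3]))
  }
  structure(list(A = unname(consts[1]), B = unname(consts[2]),
                 C = unname(consts[3]), degenerate_flag = degenerate,
                 moments_amuA2 = mom),
            class = "rotational_constants")
}

#' @export
print.rotational_constants <- function(x, ...) {
  cat(sprintf("<rotational constants A=%.6g B=%.6g C=%.6g GHz%s>\n",
              x$A, x$B, x$C,
              if (x$degenerate_flag) " (linear)" else ""))
  invisible(x)
}

#' Perceive bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of their
#' covalent radii plus a tolerance (default 0.45 Angstrom).
#'
#' @param c a \code{\link{conformer}}.
#' @param tol additive distance tolerance in Angstrom.
#' @return Two-column integer matrix of bonded atom index pairs (i < j).
#' @export
detect_bonds <- function(c, tol = 0.45) {
  n <- n_atoms(c)
  r <- .covalent_radii[c$elements]
  if (anyNA(r)) stop("no covalent radius for element(s): ",
                     paste(unique(c$elements[is.na(r)]), collapse = ", "))
  d <- as.matrix(stats::dist(c$coords))
  cutoff <- outer(r, r, `+`) + tol
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  colnames(hit) <- c("i", "j")
  hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
}

# All simple 6-cycles in an adjacency list restricted to `allowed` vertices.
# Cycles are canonicalized (sorted vertex sets) and deduplicated.
.six_cycles <- function(adj, allowed) {
  cycles <- list()
  seen <- character(0)
  for (start in allowed) {
    # DFS paths of exactly 6 vertices beginning at `start`, vertices >= start
    stack <- list(c(start))
    while (length(stack) > 0L) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      if (length(path) == 6L) {
        if (start %in% adj[[last]]) {
          key <- paste(sort(path), collapse = ",")
          if (!key %in% seen) {
            seen <- c(seen, key)
            cycles[[length(cycles) + 1L]] <- sort(path)
          }
        }
        next
      }
      for (nb in adj[[last]]) {
        if (nb %in% allowed && nb > start && !nb %in% path)
          stack[[length(stack) + 1L]] <- c(path, nb)
      }
    }
  }
  cycles
}

.adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Mean absolute out-of-plane deviation of points from their best-fit plane.
.planarity_deviation <- function(xyz) {
  centered <- sweep(xyz, 2L, colMeans(xyz))
  sv <- svd(centered)
  normal <- sv$v[, 3]
  mean(abs(centered %*% normal))
}

#' Detect planar all-carbon six-membered rings
#'
#' Finds every 6-cycle of carbon atoms in the perceived bond graph whose mean
#' out-of-plane deviation from its best-fit plane is within a planarity
#' tolerance. Saturated rings (chair cyclohexane, piperidine) fail the
#' planarity filter; heteroaromatic rings fail the all-carbon filter and must
#' be supplied explicitly where needed.
#'
#' @param c a \code{\link{conformer}}.
#' @param planarity_tol mean out-of-plane tolerance, Angstrom (default 0.1).
#' @param bond_tol bond-perception tolerance passed to
#'   \code{\link{detect_bonds}}.
#' @return List of sorted integer vectors of ring atom indices (possibly
#'   empty).
#' @export
detect_aromatic_six_rings <- function(c, planarity_tol = 0.1,
                                      bond_tol = 0.45) {
  carbons <- which(c$elements == "C")
  if (length(carbons) < 6L) return(list())
  bonds <- detect_bonds(c, tol = bond_tol)
  adj <- .adjacency_list(bonds, n_atoms(c))
  rings <- .six_cycles(adj, carbons)
  Filter(function(r) .planarity_deviation(c$coords[r, , drop = FALSE]) <=
           planarity_tol, rings)
}

# Saturated six-ring nitrogen: a nitrogen atom lying on some 6-cycle of the
# full bond graph that is not one of the planar all-carbon rings. This is
# the piperidine nitrogen in fentanyl-like scaffolds (protonated in water).
.find_anchor_nitrogen <- function(c, aromatic_rings) {
  nitrogens <- which(c$elements == "N")
  if (length(nitrogens) == 0L)
    stop("no nitrogen atom found for anchor auto-detection")
  bonds <- detect_bonds(c)
  adj <- .adjacency_list(bonds, n_atoms(c))
  all6 <- .six_cycles(adj, seq_len(n_atoms(c)))
  arom_keys <- vapply(aromatic_rings, paste, character(1), collapse = ",")
  for (ring in all6) {
    key <- paste(ring, collapse = ",")
    if (key %in% arom_keys) next
    inn <- intersect(ring, nitrogens)
    if (length(inn) >= 1L) return(inn[1])
  }
  nitrogens[1]
}

#' Classify a conformer as cis, trans or gauche
#'
#' Phenyl-ring orientation taxonomy for fentanyl-like scaffolds: the angle
#' between the two unit vectors pointing from an anchor atom (the protonated
#' piperidine nitrogen) to the centroids of the two aromatic rings. Rings
#' approximately parallel (small separation angle) are \emph{cis}, rings
#' roughly opposite (~180 degrees) are \emph{trans}, and intermediate
#' (~90 degrees) arrangements are \emph{gauche}. The class boundaries are
#' configurable midpoints, defaulting to 60 and 135 degrees.
#'
#' @param c a \code{\link{conformer}}.
#' @param rings optional list of two integer vectors of ring atom indices;
#'   auto-detected via \code{\link{detect_aromatic_six_rings}} when NULL.
#' @param anchor optional anchor atom index; auto-detected as the nitrogen in
#'   a saturated six-ring when NULL.
#' @param cis_max upper angle bound for cis, degrees.
#' @param trans_min lower angle bound for trans, degrees.
#' @param metric \code{"centroid"} (anchor-to-centroid vectors, default) or
#'   \code{"normal"} (angle between ring-plane normals, folded to
#'   0--90 degrees by sign choice).
#' @return Object of class \code{conformation_label}: \code{label},
#'   \code{separation_angle} (degrees), \code{ring_atom_indices},
#'   \code{anchor_index}.
#' @export
classify_conformation <- function(c, rings = NULL, anchor = NULL,
                                  cis_max = 60, trans_min = 135,
                                  metric = c("centroid", "normal")) {
  metric <- match.arg(metric)
  if (is.null(rings)) {
    rings <- detect_aromatic_six_rings(c)
    if (length(rings) != 2L)
      stop("expected exactly 2 qualifying aromatic rings, found ",
           length(rings), "; supply ring index sets explicitly")
  }
  if (length(rings) != 2L)
    stop("rings must list exactly 2 atom index sets")
  if (is.null(anchor)) anchor <- .find_anchor_nitrogen(c, rings)
  cen1 <- colMeans(c$coords[rings[[1]], , drop = FALSE])
  cen2 <- colMeans(c$coords[rings[[2]], , drop = FALSE])
  if (metric == "centroid") {
    v1 <- cen1 - c$coords[anchor, ]
    v2 <- cen2 - c$coords[anchor, ]
  } else {
    pl <- function(idx) {
      xyz <- c$coords[idx, , drop = FALSE]
      sv <- svd(sweep(xyz, 2L, colMeans(xyz)))
      sv$v[, 3]
    }
    v1 <- pl(rings[[1]])
    v2 <- pl(rings[[2]])
    if (sum(v1 * v2) < 0) v2 <- -v2
  }
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  angle <- acos(min(1, max(-1, cosang))) * 180 / pi
  label <- if (angle < cis_max) "cis" else if (angle < trans_min) "gauche" else "trans"
  structure(list(label = label, separation_angle = angle,
                 ring_atom_indices = rings, anchor_index = anchor),
            class = "conformation_label")
}

#' @export
print.conformation_label <- function(x, ...) {
  cat(sprintf("<conformation %s (%.1f deg)>\n", x$label, x$separation_angle))
  invisible(x)
}

# Kabsch: optimal proper rotation R with R p_i ~ q_i for centered point sets
# P, Q (n x 3). Returns list(R, rmsd).
.kabsch <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- P %*% t(R) - Q
  list(R = R, rmsd = sqrt(mean(rowSums(resid^2))))
}

# O(n^3) shortest-augmenting-path solver for the square assignment problem.
# Returns assign[i] = column matched to row i, minimizing total cost.
.solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  u <- numeric(n)
  v <- numeric(n + 1L)      # column potentials; index 1 is the virtual column
  p <- integer(n + 1L)      # p[j]: row matched to column j (cols 2..n+1 real)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    way <- integer(n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used)
      cur <- cost[i0, free_j - 1L] - u[i0] - v[free_j]
      upd <- cur < minv[free_j]
      minv[free_j[upd]] <- cur[upd]
      way[free_j[upd]] <- j0
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      u[p[used & p > 0L]] <- u[p[used & p > 0L]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

# Hungarian matching of b's atoms to a's, per element class, given b already
# rotated into a's frame. Returns permutation map with b[map, ] ~ a.
.match_atoms <- function(elements, A, B) {
  map <- integer(nrow(A))
  for (el in unique(elements)) {
    ia <- which(elements == el)
    # squared-distance cost between a's atoms of this element and b's
    Asub <- A[ia, , drop = FALSE]
    Bsub <- B[ia, , drop = FALSE]
    cost <- as.matrix(stats::dist(rbind(Asub, Bsub)))[seq_along(ia),
             length(ia) + seq_along(ia), drop = FALSE]^2
    map[ia] <- ia[.solve_assignment(cost)]
  }
  map
}

# 24 proper rotations of the octahedral group (signed permutation matrices
# with determinant +1); deterministic multi-start set for atom matching.
.octahedral_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (pm in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      M <- matrix(0, 3, 3)
      M[1, pm[1]] <- s1; M[2, pm[2]] <- s2; M[3, pm[3]] <- s3
      if (abs(det(M) - 1) < 1e-12) out[[length(out) + 1L]] <- M
    }
  }
  out
}

#' Atom-matched RMSD by Kabsch superposition
#'
#' Optimal rigid-body superposition of conformer \code{b} onto conformer
#' \code{a} using the Kabsch algorithm (proper rotations only). With
#' \code{match_atoms = TRUE} the atom correspondence within each element
#' class is chosen by minimum-cost (Hungarian) assignment, and the
#' assign-then-superpose cycle is iterated to convergence from a
#' deterministic set of starting orientations (sorted-distance
#' initialization plus principal-axis/octahedral multi-starts), keeping the
#' best result. The RMSD is mass-unweighted over all atoms, or heavy atoms
#' only when requested.
#'
#' @param a,b \code{\link{conformer}} objects with identical element
#'   multisets.
#' @param match_atoms permute atoms within element classes to minimize RMSD.
#' @param heavy_only drop hydrogens before alignment.
#' @param max_iter cap on assign/superpose iterations per start.
#' @return Object of class \code{alignment_result}: \code{rmsd} (Angstrom),
#'   \code{rotation} (3x3, det +1), \code{translation} (length-3, applied as
#'   \code{R x + t} to b's coordinates), \code{atom_mapping} (b's atom index
#'   matched to each atom of a).
#' @export
rmsd_aligned <- function(a, b, match_atoms = FALSE, heavy_only = FALSE,
                         max_iter = 50L) {
  ea <- a$elements; eb <- b$elements
  xa <- a$coords; xb <- b$coords
  if (heavy_only) {
    ka <- ea != "H"; kb <- eb != "H"
    ea <- ea[ka]; xa <- xa[ka, , drop = FALSE]
    eb <- eb[kb]; xb <- xb[kb, , drop = FALSE]
  }
  ta <- table(ea); tb <- table(eb)
  if (length(ta) != length(tb) || !all(names(ta) %in% names(tb)) ||
      !all(ta == tb[names(ta)])) {
    imbalance <- paste(capture_imbalance(ta, tb), collapse = "; ")
    stop("element multisets differ: ", imbalance)
  }
  cen_a <- colMeans(xa); cen_b <- colMeans(xb)
  A <- sweep(xa, 2L, cen_a)
  B <- sweep(xb, 2L, cen_b)
  # align b's atoms into a's element order so index i refers to same element
  ord_a <- order(ea, seq_along(ea))
  ord_b <- order(eb, seq_along(eb))
  inv_a <- integer(length(ord_a)); inv_a[ord_a] <- seq_along(ord_a)
  els <- ea[ord_a]
  A2 <- A[ord_a, , drop = FALSE]
  B2 <- B[ord_b, , drop = FALSE]

  if (!match_atoms) {
    if (!identical(ea, eb))
      stop("without atom matching, element sequences must be identical")
    fit <- .kabsch(B, A)
    return(structure(list(
      rmsd = fit$rmsd, rotation = fit$R,
      translation = as.numeric(cen_a - fit$R %*% cen_b),
      atom_mapping = seq_along(ea)), class = "alignment_result"))
  }

  evaluate_from_map <- function(map) {
    # iterate assignment <-> superposition until the mapping is stable
    best <- NULL
    for (it in seq_len(max_iter)) {
      fit <- .kabsch(B2[map, , drop = FALSE], A2)
      best <- list(map = map, fit = fit)
      Brot <- B2 %*% t(fit$R)
      new_map <- .match_atoms(els, A2, Brot)
      if (identical(new_map, map)) break
      map <- new_map
    }
    best
  }

  starts <- list(seq_along(els))
  # sorted-distance-from-centroid initialization within each element class
  dmapA <- sqrt(rowSums(A2^2)); dmapB <- sqrt(rowSums(B2^2))
  sd_map <- integer(length(els))
  for (el in unique(els)) {
    idx <- which(els == el)
    sd_map[idx[order(dmapA[idx])]] <- idx[order(dmapB[idx])]
  }
  starts[[2]] <- sd_map
  # multi-start: rotate B by octahedral orientations (after principal-axis
  # alignment) and take the nearest-neighbour assignment as the seed mapping
  pax <- function(X) svd(X)$v
  Va <- pax(A2); Vb <- pax(B2)
  if (det(Va) < 0) Va[, 3] <- -Va[, 3]
  if (det(Vb) < 0) Vb[, 3] <- -Vb[, 3]
  rot_maps <- lapply(.octahedral_rotations(), function(M) {
    Brot <- B2 %*% t(Va %*% M %*% t(Vb))
    .match_atoms(els, A2, Brot)
  })
  starts <- c(starts, rot_maps)

  best <- NULL
  for (map in unique(starts)) {
    res <- evaluate_from_map(map)
    if (is.null(best) || res$fit$rmsd < best$fit$rmsd) best <- res
  }
  fit <- best$fit
  # express mapping in the original atom indexing: for atom i of a, the
  # matched atom of b
  mapping <- integer(length(ea))
  mapping[ord_a] <- ord_b[best$map]
  structure(list(
    rmsd = fit$rmsd, rotation = fit$R,
    translation = as.numeric(cen_a - fit$R %*% cen_b),
    atom_mapping = mapping), class = "alignment_result")
}

capture_imbalance <- function(ta, tb) {
  all_el <- union(names(ta), names(tb))
  unlist(lapply(all_el, function(el) {
    na <- if (el %in% names(ta)) ta[[el]] else 0L
    nb <- if (el %in% names(tb)) tb[[el]] else 0L
    if (na != nb) sprintf("%s: %d vs %d", el, na, nb) else character(0)
  }))
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment rmsd = %.6f A>\n", x$rmsd))
  invisible(x)
}
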