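# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: plain formulas and brute-force enumeration.

# --- brute-force Kabsch (own svd-based implementation) -----------------------
oracle_kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

# all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# exhaustive minimum RMSD over all within-element permutations of b's atoms
oracle_matched_rmsd <- function(elements, xa, xb) {
  classes <- split(seq_along(elements), elements)
  perm_sets <- lapply(classes, function(idx) {
    lapply(all_perms(length(idx)), function(p) idx[p])
  })
  best <- Inf
  grids <- expand.grid(lapply(perm_sets, seq_along))
  for (r in seq_len(nrow(grids))) {
    map <- integer(length(elements))
    for (ci in seq_along(classes)) {
      map[classes[[ci]]] <- perm_sets[[ci]][[grids[r, ci]]]
    }
    best <- min(best, oracle_kabsch_rmsd(xb[map, , drop = FALSE], xa))
  }
  best
}

# --- closed-form statistical mechanics --------------------------------------
ORACLE <- list(h = 6.62607015e-34, kB = 1.380649e-23, c = 2.99792458e10,
               amu = 1.66053906660e-27, R = 1.987204259e-3)

oracle_sackur_tetrode <- function(mass_amu, T, P_bar) {
  m <- mass_amu * ORACLE$amu
  q <- (2 * pi * m * ORACLE$kB * T / ORACLE$h^2)^1.5 *
    (ORACLE$kB * T / (P_bar * 1e5))
  ORACLE$R * (log(q) + 2.5)   # kcal/(mol K)
}

oracle_vib <- function(nu_cm1, T) {
  theta <- ORACLE$h * ORACLE$c * nu_cm1 / ORACLE$kB
  x <- theta / T
  list(zpe = ORACLE$R * theta / 2,
       e_thermal = ORACLE$R * theta / (exp(x) - 1),
       s = ORACLE$R * (x / (exp(x) - 1) - log(1 - exp(-x))))
}

oracle_diatomic_B_GHz <- function(m1_amu, m2_amu, r_angstrom) {
  mu <- m1_amu * m2_amu / (m1_amu + m2_amu) * ORACLE$amu
  I <- mu * (r_angstrom * 1e-10)^2
  ORACLE$h / (8 * pi^2 * I) / 1e9
}

# --- dedup connected-component oracle ----------------------------------------
# duplicate relation: all three constants within rot_tol relative to the
# lower-energy member, and |dE| < e_tol. Keep the lowest-energy conformer of
# every connected component of the duplicate graph.
oracle_dedup_components <- function(ids, consts, energies, rot_tol, e_tol) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    lo <- if (energies[i] <= energies[j]) i else j
    hi <- if (lo == i) j else i
    rel <- abs(consts[[hi]] - consts[[lo]]) / abs(consts[[lo]])
    if (all(rel < rot_tol) && abs(energies[i] - energies[j]) < e_tol)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  kept <- vapply(split(seq_len(n), comp), function(members) {
    members[order(energies[members], ids[members])][1]
  }, integer(1))
  sort(ids[kept])
}

# --- small random structures --------------------------------------------------
random_small_structure <- function(n_max = 8L) {
  pool <- c("C", "C", "H", "H", "H", "O", "N")
  n <- sample(3:n_max, 1L)
  elements <- sort(sample(pool, n, replace = TRUE))
  coords <- matrix(stats::runif(3 * n, -2, 2), ncol = 3)
  list(elements = elements, coords = coords)
}

random_rotation_matrix <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
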