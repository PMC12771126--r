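test_that("rotational constants are frame-invariant and scale as 1/s^2", {
  set.seed(7)
  c1 <- generate_two_ring_probe(75, seed = 9)
  rc1 <- rotational_constants(c1)
  expect_true(rc1$A >= rc1$B && rc1$B >= rc1$C && rc1$C > 0)

  R <- random_rotation_matrix()
  c2 <- c1
  c2$coords <- sweep(c1$coords %*% t(R), 2, c(3, -1, 7), `+`)
  rc2 <- rotational_constants(c2)
  expect_equal(c(rc2$A, rc2$B, rc2$C), c(rc1$A, rc1$B, rc1$C),
               tolerance = 1e-9)

  c3 <- c1
  c3$coords <- c1$coords * 2
  rc3 <- rotational_constants(c3)
  expect_equal(c(rc3$A, rc3$B, rc3$C) * 4, c(rc1$A, rc1$B, rc1$C),
               tolerance = 1e-9)
})

test_that("diatomic rotational constant matches the reduced-mass closed form", {
  r <- 1.27
  hcl <- conformer("hcl", "x", c("H", "Cl"),
                   matrix(c(0, 0, 0, 0, 0, r), 2, 3, byrow = TRUE))
  rc <- rotational_constants(hcl)
  expect_true(rc$degenerate_flag)
  B_oracle <- oracle_diatomic_B_GHz(atomic_masses("H"),
                                    atomic_masses("Cl"), r)
  expect_equal(rc$B, B_oracle, tolerance = 1e-10)
  expect_equal(rc$C, B_oracle, tolerance = 1e-10)
  expect_error(rotational_constants(
    conformer("a", "x", "Ar", matrix(0, 1, 3))), "single atom")
})

test_that("bent triatomic constants match brute-force inertia diagonalization", {
  # water-like geometry
  xyz <- matrix(c(0, 0, 0.1173,
                  0, 0.7572, -0.4692,
                  0, -0.7572, -0.4692), 3, 3, byrow = TRUE)
  w <- conformer("w", "x", c("O", "H", "H"), xyz)
  rc <- rotational_constants(w)
  # oracle: independent inertia tensor diagonalization
  m <- c(15.9949146196, 1.00782503207, 1.00782503207)
  com <- colSums(xyz * m) / sum(m)
  x <- sweep(xyz, 2, com)
  Iten <- matrix(0, 3, 3)
  for (i in 1:3) {
    ri <- x[i, ]
    Iten <- Iten + m[i] * (sum(ri^2) * diag(3) - outer(ri, ri))
  }
  mom <- sort(eigen(Iten, symmetric = TRUE)$values)
  B <- ORACLE$h / (8 * pi^2 * (mom * ORACLE$amu * 1e-20)) / 1e9
  expect_equal(c(rc$A, rc$B, rc$C), sort(B, decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("aromatic ring detection finds planar carbon six-rings only", {
  # idealized benzene
  th <- (0:5) * pi / 3
  benz <- conformer("b", "x", rep("C", 6),
                    cbind(1.39 * cos(th), 1.39 * sin(th), 0))
  rings <- detect_aromatic_six_rings(benz)
  expect_length(rings, 1L)
  expect_equal(rings[[1]], 1:6)

  # chair cyclohexane fails the planarity filter
  r <- sqrt(1.53^2 - 4 * 0.25^2)
  chair <- conformer("ch", "x", rep("C", 6),
                     cbind(r * cos(th), r * sin(th), 0.25 * (-1)^(0:5)))
  expect_length(detect_aromatic_six_rings(chair), 0L)

  # fentanyl-like probe: exactly two rings, excluding the saturated ring
  p <- generate_two_ring_probe(100, seed = 2)
  rings <- detect_aromatic_six_rings(p)
  expect_length(rings, 2L)
  sat_atoms <- 1:6  # probe layout: saturated ring first
  for (ring in rings) expect_length(intersect(ring, sat_atoms), 0L)
})

test_that("classification is invariant under rigid motion and reindexing", {
  set.seed(31)
  for (ang in c(20, 100, 160)) {
    p <- generate_two_ring_probe(ang, seed = ang)
    lab <- classify_conformation(p)
    expect_equal(lab$separation_angle, ang, tolerance = 0.5)

    q <- p
    R <- random_rotation_matrix()
    q$coords <- sweep(p$coords %*% t(R), 2, rnorm(3), `+`)
    expect_identical(classify_conformation(q)$label, lab$label)
    expect_equal(classify_conformation(q)$separation_angle,
                 lab$separation_angle, tolerance = 1e-8)

    # atom reindexing
    perm <- sample(seq_along(p$elements))
    q2 <- conformer(p$conformer_id, p$analog_id, p$elements[perm],
                    p$coords[perm, ], charge = p$charge)
    expect_identical(classify_conformation(q2)$label, lab$label)
  }
})

test_that("classification errors when the two rings cannot be located", {
  th <- (0:5) * pi / 3
  benz <- conformer("b", "x", rep("C", 6),
                    cbind(1.39 * cos(th), 1.39 * sin(th), 0))
  expect_error(classify_conformation(benz), "1")
})

test_that("Kabsch RMSD is zero for identity and transformed copies", {
  p <- generate_two_ring_probe(45, seed = 5)
  expect_lt(rmsd_aligned(p, p)$rmsd, 1e-12)
  set.seed(8)
  q <- p
  q$coords <- sweep(p$coords %*% t(random_rotation_matrix()), 2,
                    runif(3, -10, 10), `+`)
  res <- rmsd_aligned(p, q)
  expect_lt(res$rmsd, 1e-8)
  expect_equal(det(res$rotation), 1, tolerance = 1e-10)
})

test_that("atom matching undoes within-element relabeling", {
  p <- generate_two_ring_probe(120, seed = 6)
  q <- p
  # swap two carbons and rotate
  q$coords[c(7, 10), ] <- q$coords[c(10, 7), ]
  set.seed(9)
  q$coords <- sweep(q$coords %*% t(random_rotation_matrix()), 2, 1:3, `+`)
  expect_gt(rmsd_aligned(p, q)$rmsd, 0.1)
  expect_lt(rmsd_aligned(p, q, match_atoms = TRUE)$rmsd, 1e-8)
})

test_that("RMSD is symmetric and matching never hurts", {
  set.seed(12)
  for (k in 1:5) {
    s <- random_small_structure()
    a <- conformer("a", "x", s$elements, s$coords)
    b <- conformer("b", "x", s$elements,
                   s$coords + matrix(rnorm(length(s$coords), sd = 0.3),
                                     ncol = 3))
    r_ab <- rmsd_aligned(a, b, match_atoms = TRUE)$rmsd
    r_ba <- rmsd_aligned(b, a, match_atoms = TRUE)$rmsd
    expect_equal(r_ab, r_ba, tolerance = 1e-10)
    expect_lte(r_ab, rmsd_aligned(a, b)$rmsd + 1e-12)
  }
})

test_that("element multiset mismatch is reported with the imbalance", {
  a <- conformer("a", "x", c("C", "H"), matrix(rnorm(6), 2, 3))
  b <- conformer("b", "x", c("C", "O"), matrix(rnorm(6), 2, 3))
  expect_error(rmsd_aligned(a, b), "H: 1 vs 0")
})
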