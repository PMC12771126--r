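# minimal conformer stubs + injected rotational constants, so the rule
# logic is exercised independent of geometry
stub_conformers <- function(ids) {
  lapply(ids, function(id)
    conformer(id, "stub", c("C", "O"),
              matrix(c(0, 0, 0, 0, 0, 1.2), 2, 3, byrow = TRUE)))
}

rc_stub <- function(A, B, C) {
  structure(list(A = A, B = B, C = C, degenerate_flag = FALSE),
            class = "rotational_constants")
}

test_that("bit-identical conformers collapse to one survivor", {
  ids <- c("c1", "c2")
  rc <- list(c1 = rc_stub(1, 0.5, 0.3), c2 = rc_stub(1, 0.5, 0.3))
  dec <- deduplicate(stub_conformers(ids), c(c1 = 0, c2 = 0),
                     rot_constants = rc)
  expect_identical(dec$kept_ids, "c1")
  expect_identical(unname(dec$removed["c2"]), "c1")
})

test_that("the rule requires both the constants and the energy to agree", {
  ids <- c("c1", "c2")
  conf <- stub_conformers(ids)
  # constants 2% apart, equal energies -> both kept
  rc <- list(c1 = rc_stub(1, 0.5, 0.3), c2 = rc_stub(1.02, 0.51, 0.306))
  dec <- deduplicate(conf, c(c1 = 0, c2 = 0), rot_constants = rc)
  expect_length(dec$kept_ids, 2L)

  # constants within 0.5%, dE = 0.05 -> duplicate
  rc <- list(c1 = rc_stub(1, 0.5, 0.3), c2 = rc_stub(1.004, 0.502, 0.3012))
  dec <- deduplicate(conf, c(c1 = 0, c2 = 0.05), rot_constants = rc)
  expect_identical(dec$kept_ids, "c1")

  # same constants, dE = 0.2 -> both kept
  dec <- deduplicate(conf, c(c1 = 0, c2 = 0.2), rot_constants = rc)
  expect_length(dec$kept_ids, 2L)
})

test_that("the kept set does not depend on input order", {
  set.seed(5)
  ids <- sprintf("c%02d", 1:12)
  rc <- lapply(1:12, function(i) {
    base <- c(2, 1, 0.6) * (1 + 0.005 * (i %% 4))
    rc_stub(base[1], base[2], base[3])
  })
  names(rc) <- ids
  e <- setNames(runif(12, 0, 0.5), ids)
  d1 <- deduplicate(stub_conformers(ids), e, rot_constants = rc)
  perm <- sample(12)
  d2 <- deduplicate(stub_conformers(ids[perm]), e, rot_constants = rc)
  expect_identical(d1$kept_ids, d2$kept_ids)
  expect_identical(d1$removed[order(names(d1$removed))],
                   d2$removed[order(names(d2$removed))])
})

test_that("duplicates map to their lowest-energy twin and missing energy errors", {
  ids <- c("x", "y", "z")
  rc <- setNames(rep(list(rc_stub(1, 0.5, 0.3)), 3), ids)
  dec <- deduplicate(stub_conformers(ids), c(x = 0.02, y = 0.0, z = 0.05),
                     rot_constants = rc)
  expect_identical(dec$kept_ids, "y")
  expect_identical(unname(dec$removed[c("x", "z")]), c("y", "y"))

  expect_error(deduplicate(stub_conformers(ids), c(x = 0, y = 0)),
               "missing energy.*z")
})

test_that("greedy dedup equals the component oracle on tight, separated clusters", {
  # when duplicate clusters are tight (well inside the tolerances) and
  # clusters are widely separated, the duplicate relation is transitive and
  # the greedy scan must reproduce the connected-component oracle exactly
  set.seed(2024)
  for (trial in 1:50) {
    n <- sample(4:20, 1)
    k <- sample(2:5, 1)
    centers <- lapply(1:k, function(i)
      sort(runif(3, 0.2, 3), decreasing = TRUE) * (1 + 0.2 * i))
    e_centers <- runif(k, 0, 4)
    assign_to <- sample(k, n, replace = TRUE)
    ids <- sprintf("t%02d", 1:n)
    consts <- lapply(1:n, function(i)
      centers[[assign_to[i]]] * (1 + runif(3, -0.003, 0.003)))
    energies <- setNames(e_centers[assign_to] + runif(n, 0, 0.06), ids)
    rc <- setNames(lapply(consts, function(v) rc_stub(v[1], v[2], v[3])),
                   ids)
    dec <- deduplicate(stub_conformers(ids), energies, rot_constants = rc)
    oracle_kept <- oracle_dedup_components(ids, consts,
                                           unname(energies[ids]),
                                           rot_tol = 0.01, e_tol = 0.1)
    expect_identical(sort(dec$kept_ids), oracle_kept)
  }
})

test_that("non-transitive tolerance chains are resolved consistently, never silently", {
  # clusters whose spread straddles the tolerances create chains a-b-c
  # where a~b and b~c but not a~c; the greedy result may then differ from
  # the component oracle, but every decision must remain locally valid:
  # survivors pairwise distinct under the rule, removals mapped to a true
  # duplicate twin
  set.seed(2025)
  n_discrepant <- 0L
  for (trial in 1:50) {
    n <- sample(4:20, 1)
    k <- sample(2:5, 1)
    centers <- lapply(1:k, function(i) sort(runif(3, 0.2, 3),
                                            decreasing = TRUE))
    e_centers <- runif(k, 0, 4)
    assign_to <- sample(k, n, replace = TRUE)
    ids <- sprintf("t%02d", 1:n)
    consts <- lapply(1:n, function(i)
      centers[[assign_to[i]]] * (1 + runif(3, -0.012, 0.012)))
    energies <- setNames(e_centers[assign_to] + runif(n, 0, 0.15), ids)
    rc <- setNames(lapply(consts, function(v) rc_stub(v[1], v[2], v[3])),
                   ids)
    dec <- deduplicate(stub_conformers(ids), energies, rot_constants = rc)
    oracle_kept <- oracle_dedup_components(ids, consts,
                                           unname(energies[ids]),
                                           rot_tol = 0.01, e_tol = 0.1)
    if (!identical(sort(dec$kept_ids), oracle_kept))
      n_discrepant <- n_discrepant + 1L
    kept <- dec$kept_ids
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i >= j) next
      lo <- kept[[i]]; hi <- kept[[j]]  # kept_ids ordered by energy
      rel <- abs(c(rc[[hi]]$A - rc[[lo]]$A, rc[[hi]]$B - rc[[lo]]$B,
                   rc[[hi]]$C - rc[[lo]]$C)) /
        abs(c(rc[[lo]]$A, rc[[lo]]$B, rc[[lo]]$C))
      dup <- all(rel < 0.01) && abs(energies[hi] - energies[lo]) < 0.1
      expect_false(dup)
    }
    for (rm in names(dec$removed)) {
      tw <- dec$removed[[rm]]
      rel <- abs(c(rc[[rm]]$A - rc[[tw]]$A, rc[[rm]]$B - rc[[tw]]$B,
                   rc[[rm]]$C - rc[[tw]]$C)) /
        abs(c(rc[[tw]]$A, rc[[tw]]$B, rc[[tw]]$C))
      expect_true(all(rel < 0.01) &&
                    abs(energies[rm] - energies[tw]) < 0.1)
    }
  }
})
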