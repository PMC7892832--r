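test_that("Kabsch RMSD is a proper superposition metric", {
  set.seed(5)
  x <- matrix(rnorm(36), 12, 3)
  expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-12)
  # invariance to proper rigid motion of either argument
  for (i in 1:5) {
    r <- random_rotation()
    shift <- matrix(rnorm(3, 0, 10), 12, 3, byrow = TRUE)
    expect_lt(kabsch_rmsd(x, x %*% r + shift), 1e-10)
    expect_lt(kabsch_rmsd(x %*% r + shift, x), 1e-10)
  }
  # symmetry
  y <- x + matrix(rnorm(36, 0, 0.4), 12, 3)
  expect_equal(kabsch_rmsd(x, y), kabsch_rmsd(y, x), tolerance = 1e-12)
  expect_error(kabsch_rmsd(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("Kabsch agrees with brute-force superposition on small sets", {
  set.seed(6)
  for (i in 1:3) {
    a <- matrix(rnorm(18), 6, 3)
    b <- a %*% random_rotation() + matrix(rnorm(18, 0, 0.3), 6, 3)
    expect_equal(kabsch_rmsd(a, b), brute_superpose_rmsd(a, b),
                 tolerance = 1e-3)
  }
  # displaced-vertex triangle: optimal superposition can only reduce the
  # naive (unfitted) RMSD
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0.5, sqrt(3) / 2, 0), 3, 3,
                byrow = TRUE)
  tri2 <- tri
  tri2[3, 1] <- tri2[3, 1] + 0.3
  naive <- sqrt(mean(rowSums((tri - tri2)^2)))
  expect_equal(naive, 0.3 / sqrt(3), tolerance = 1e-12)
  k <- kabsch_rmsd(tri, tri2)
  expect_lte(k, naive + 1e-12)
  expect_equal(k, brute_superpose_rmsd(tri, tri2), tolerance = 1e-3)
})

test_that("ensembles of identical models have zero pairwise RMSD", {
  spec <- synth_spec(seed = 2, ensemble = list(sigma_backbone = 0,
                                               sigma_sidechain = 0))
  e <- gen_toy_ensemble(spec)$ensemble
  expect_equal(ensemble_pairwise_rmsd(e, "backbone")$rmsd_mean, 0,
               tolerance = 1e-10)
  expect_equal(cross_structure_rmsd(e, e)$rmsd, 0, tolerance = 1e-10)
})

test_that("pairwise ensemble RMSD matches a direct pair average and the
           backbone is tighter than heavy atoms", {
  spec <- synth_spec(seed = 3, ensemble = list(n_models = 4L))
  e <- gen_toy_ensemble(spec)$ensemble
  bb <- ensemble_pairwise_rmsd(e, "backbone")
  hv <- ensemble_pairwise_rmsd(e, "heavy")
  # side-chain dummies carry larger displacements
  expect_lt(bb$rmsd_mean, hv$rmsd_mean)
  expect_equal(bb$n_pairs, 6)
  # direct (independent) computation of the same mean over pairs
  sel <- which(e$atoms$elety %in% c("N", "CA", "C"))
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    vals <- c(vals, brute_superpose_rmsd(e$coords[[i]][sel, ],
                                         e$coords[[j]][sel, ],
                                         n_starts = 40))
  }
  expect_equal(bb$rmsd_mean, mean(vals), tolerance = 1e-3)
})

test_that("a rigid hinge rotation is recovered by global superposition", {
  spec <- synth_spec(seed = 4, ensemble = list(n_models = 1L,
                                               sigma_backbone = 0,
                                               sigma_sidechain = 0))
  e <- gen_toy_ensemble(spec)$ensemble
  # rotate the last quarter of the chain about the z axis (a hinge)
  co <- e$coords[[1]]
  hinge <- e$atoms$resno > 30
  th <- 0.35
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  co2 <- co
  co2[hinge, ] <- co[hinge, ] %*% rz
  e2 <- structure_ensemble(e$atoms, list(co2))
  got <- cross_structure_rmsd(e, e2, selection = "backbone")$rmsd
  sel <- which(e$atoms$elety %in% c("N", "CA", "C"))
  expect_equal(got, brute_superpose_rmsd(co[sel, ], co2[sel, ]),
               tolerance = 1e-3)
  expect_gt(got, 0.1)
})

test_that("PDB ensembles round-trip and malformed files are rejected", {
  spec <- synth_spec(seed = 8, ensemble = list(n_models = 3L,
                                               n_residues = 10L))
  e <- gen_toy_ensemble(spec)$ensemble
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(e, f)
  e2 <- read_pdb_ensemble(f)
  expect_equal(e2$n_models, 3)
  expect_equal(nrow(e2$atoms), 50)
  expect_equal(e2$coords[[2]], e$coords[[2]], tolerance = 1e-3,
               ignore_attr = TRUE)
  # hydrogens would be excluded from both selections
  expect_false(any(e2$atoms$element[ensemble_selection(e2, "heavy")] == "H"))

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), bad)
  expect_error(read_pdb_ensemble(bad), "inconsistent|failed")
})
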