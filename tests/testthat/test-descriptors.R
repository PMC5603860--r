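test_that("RDF closed forms: single atom, single pair, three collinear atoms", {
  lone <- molecule("C", matrix(0, 1, 3))
  expect_equal(unname(rdf_code(lone, c(1, 2, 3))), c(0, 0, 0))

  pair <- toy_molecule("pair", distance = 2)
  radii <- c(1.5, 2, 2.5)
  got <- rdf_code(pair, radii, f = 1, B = 100)
  expect_equal(unname(got), exp(-100 * (radii - 2)^2), tolerance = 1e-12)
  expect_equal(unname(got[2]), 1)

  tri <- molecule(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  for (B in c(1, 25, 100)) {
    # pairs at distances 1, 1, 2
    expect_equal(unname(rdf_code(tri, 1, B = B)),
                 2 + exp(-B), tolerance = 1e-12)
  }
})

test_that("RDF agrees with a brute-force double loop on random molecules", {
  set.seed(11)
  for (rep in 1:10) {
    mol <- random_molecule(sample(4:8, 1))
    w <- atomic_weights(mol, "mass")
    radii <- c(1, 2.5, 4)
    got <- rdf_code(mol, radii, weights = "mass", B = 10)
    want <- vapply(radii, function(r)
      oracle_rdf(mol$coordinates, w, r, B = 10), numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("RDF is invariant under rigid motion and atom permutation", {
  set.seed(21)
  radii <- seq(0.5, 5, by = 0.5)
  for (rep in 1:10) {
    mol <- random_molecule(sample(5:8, 1))
    ref <- rdf_code(mol, radii, weights = "electronegativity")
    moved <- mol
    moved$coordinates <- rigid_motion(mol$coordinates)
    expect_equal(rdf_code(moved, radii, weights = "electronegativity"),
                 ref, tolerance = 1e-10)
    perm <- sample(length(mol$elements))
    shuffled <- molecule(mol$elements[perm], mol$coordinates[perm, ],
                         data.frame(i = match(mol$bonds$i, perm),
                                    j = match(mol$bonds$j, perm)))
    expect_equal(rdf_code(shuffled, radii, weights = "electronegativity"),
                 ref, tolerance = 1e-10)
  }
})

test_that("Moran and Geary reproduce the hand-computed 3-atom path values", {
  p3 <- toy_molecule("path3", weights = c(1, 2, 3))
  expect_equal(moran_autocorrelation(p3, 1, "custom"), 0)
  expect_equal(moran_autocorrelation(p3, 2, "custom"), -1.5)
  expect_equal(geary_autocorrelation(p3, 1, "custom"), 0.5)
  expect_equal(geary_autocorrelation(p3, 2, "custom"), 2.0)
})

test_that("autocorrelations agree with the double-loop oracle on random graphs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    mol <- random_molecule(n)
    w <- stats::runif(n, 0.5, 3)
    d <- oracle_topo_dist(n, mol$bonds)
    for (lag in 1:4) {
      expect_equal(moran_autocorrelation(mol, lag, w),
                   oracle_moran(d, w, lag), tolerance = 1e-12)
      expect_equal(geary_autocorrelation(mol, lag, w),
                   oracle_geary(d, w, lag), tolerance = 1e-12)
    }
  }
})

test_that("degenerate autocorrelations return exactly zero", {
  p3 <- toy_molecule("path3")
  # equal weights: zero variance
  expect_identical(moran_autocorrelation(p3, 1, rep(2, 3)), 0)
  expect_identical(geary_autocorrelation(p3, 1, rep(2, 3)), 0)
  # lag beyond the graph diameter: no pairs
  expect_identical(moran_autocorrelation(p3, 5, "custom"), 0)
  expect_identical(geary_autocorrelation(p3, 5, "custom"), 0)
})

test_that("C-005 counts methyls on electronegative atoms only", {
  expect_equal(c005_count(toy_molecule("methyl_probe", name = "methane")), 0L)
  expect_equal(c005_count(toy_molecule("methyl_probe",
                                       name = "dimethyl ether")), 2L)
  expect_equal(c005_count(toy_molecule("methyl_probe", name = "anisole")), 1L)
  # explicit hydrogens: ethanol CH3-CH2-OH -> methyl is on carbon, count 0
  ethanol <- molecule(
    c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    matrix(stats::rnorm(27), 9, 3),
    data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3),
               j = c(2, 3, 4, 5, 6, 7, 8, 9)))
  expect_equal(c005_count(ethanol), 0L)
  # explicit-H methylamine CH3-NH2 -> 1
  mam <- molecule(c("C", "N", "H", "H", "H", "H", "H"),
                  matrix(stats::rnorm(21), 7, 3),
                  data.frame(i = c(1, 1, 1, 1, 2, 2),
                             j = c(2, 3, 4, 5, 6, 7)))
  expect_equal(c005_count(mam), 1L)
})

test_that("descriptor tables follow the name grammar and match single ops", {
  pair <- toy_molecule("pair", distance = 10.5)
  tab <- compute_descriptors(list(pair), "RDF105u")
  expect_equal(tab$RDF105u, 1.0)

  expect_equal(nrow(compute_descriptors(list(), c("RDF020u", "C-005"))), 0)

  # heteroatom path C-O-C: weights differ under mass weighting
  ether <- toy_molecule("methyl_probe", name = "dimethyl ether")
  requested <- c("MATS1m", "GATS2v", "C-005", "RDF028m")
  tab <- compute_descriptors(list(ether, ether), requested)
  expect_equal(names(tab), c("compound_id", requested))
  expect_equal(tab$MATS1m[1], moran_autocorrelation(ether, 1, "mass"))
  expect_equal(tab$GATS2v[1], geary_autocorrelation(ether, 2, "vdw_volume"))
  expect_equal(tab$`C-005`[1], 2)
  expect_equal(tab$RDF028m[1],
               unname(rdf_code(ether, 2.8, weights = "mass")))

  expect_error(compute_descriptors(list(pair), "RDFxyz"),
               class = "qsar_config_error")
  expect_error(compute_descriptors(list(pair), "MATS4q"),
               class = "qsar_config_error")
})

test_that("SDF (V2000) files round-trip into molecule geometries", {
  skip_if_not_installed("ChemmineR")
  sdf <- c(
    "dimethyl ether", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "   -1.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  mols <- suppressWarnings(read_sdf_molecules(path))
  expect_length(mols, 1)
  m <- mols[[1]]
  expect_equal(m$elements, c("C", "O", "C"))
  expect_equal(nrow(m$bonds), 2)
  expect_equal(c005_count(m), 2L)
  expect_equal(unname(rdf_code(m, 1.4)), 2, tolerance = 1e-9)
})
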