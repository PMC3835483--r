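test_that("the cholesterol fixture has the sterol composition", {
  g <- cholesterol_graph()
  expect_equal(n_atoms(g), 74L)                        # C27 H46 O
  expect_equal(sum(g$elements == "C"), 27L)
  expect_equal(sum(g$elements == "H"), 46L)
  expect_equal(sum(g$elements == "O"), 1L)
  expect_equal(nrow(g$bonds), 77L)
  expect_equal(graph_cycles(g), 4L)                    # tetracyclic
  # sterol valences: all carbons 3 or 4 neighbours, O has 2
  deg <- graph_degrees(g)
  expect_true(all(deg[g$elements == "C"] %in% 3:4))
  expect_equal(deg[g$elements == "O"], 2L)
})

test_that("the shipped model-built geometry matches the fixture graph", {
  g <- cholesterol_graph()
  s <- cholesterol_structure()
  expect_identical(s$elements, g$elements)
  ens <- ensemble(list(s$xyz), s$elements)
  bl <- measure_features(ens, enumerate_bonds(g))$values
  expect_true(all(bl > 0.9 & bl < 1.7))  # every listed bond is bond-length
})

test_that("matrix generation is seed-deterministic with hot/cold structure", {
  a <- generate_feature_matrix(n_frames = 100, n_features = 20,
                               hot = c(3, 7), kind = "bond", seed = 42)
  b <- generate_feature_matrix(n_frames = 100, n_features = 20,
                               hot = c(3, 7), kind = "bond", seed = 42)
  expect_identical(a$values, b$values)
  v <- apply(a$values, 2, var)
  expect_true(all(v[c(3, 7)] > 50 * median(v[-c(3, 7)])))
  expect_error(generate_feature_matrix(hot = 1, kind = "bond"),
               "seed")
  expect_error(generate_feature_matrix(hot = 99, n_features = 10, seed = 1),
               "range")
})

test_that("hot features near the branch cut are still recovered", {
  fm <- generate_feature_matrix(n_frames = 250, n_features = 40,
                                hot = c(5, 21), sd_hot = 20, sd_cold = 1,
                                kind = "dihedral", hot_near_cut = TRUE,
                                seed = 13)
  # raw values straddle +/-180: naive variance would explode
  expect_true(any(fm$values[, 5] > 170) && any(fm$values[, 5] < -170))
  rk <- pca_rank(fm)
  expect_true(all(c(5, 21) %in% rk$top))
})

test_that("null matrices (sd_hot = sd_cold) have a flat spectrum", {
  fm <- generate_feature_matrix(n_frames = 200, n_features = 15,
                                hot = 1:3, sd_hot = 2, sd_cold = 2,
                                kind = "bond", seed = 7)
  dec <- ic_pca(ic_preprocess(fm)$centered)
  expect_lt(max(dec$eigenvalues) / min(dec$eigenvalues), 5)
})

test_that("chain ensembles round-trip their torsions through Cartesians", {
  chain <- generate_chain_ensemble(n_atoms = 6, n_frames = 50,
                                   hot_torsion = 2, amplitude = 60,
                                   jitter = 2, seed = 3)
  fd <- enumerate_dihedrals(chain$graph)
  meas <- measure_features(chain$ensemble, fd)$values
  expect_lt(max(abs(meas - chain$torsions)), 1e-6)
  # bonds untouched by construction
  fb <- enumerate_bonds(chain$graph)
  bl <- measure_features(chain$ensemble, fb)$values
  expect_lt(max(abs(bl - 1.53)), 1e-6)
  # determinism
  again <- generate_chain_ensemble(n_atoms = 6, n_frames = 50,
                                   hot_torsion = 2, amplitude = 60,
                                   jitter = 2, seed = 3)
  expect_identical(chain$torsions, again$torsions)
})

test_that("a frozen chain (no amplitude, no jitter) fails PCA on purpose", {
  chain <- generate_chain_ensemble(n_atoms = 6, n_frames = 10,
                                   hot_torsion = 1, amplitude = 0,
                                   jitter = 0, seed = 1)
  d <- vapply(chain$ensemble$frames, function(f) max(abs(f -
    chain$ensemble$frames[[1]])), numeric(1))
  expect_lt(max(d), 1e-12)
  fm <- measure_features(chain$ensemble, enumerate_dihedrals(chain$graph))
  prep <- ic_preprocess(fm)
  dec <- ic_pca(prep$centered)
  expect_error(select_pcs(dec$eigenvalues), "no variance")
})

test_that("charge patterns have the stated structure", {
  g <- cholesterol_graph()
  expect_true(all(generate_charges(g, "neutral")$charge == 0))
  dp <- generate_charges(g, "dipole", dipole_atoms = c(1, 74), q = 0.3)
  expect_equal(sum(dp$charge), 0)
  expect_equal(sort(unique(dp$charge)), c(-0.3, 0, 0.3))
  fx <- generate_charges(g, "fixture-like")
  expect_equal(sum(fx$charge), 0)
  o <- which(g$elements == "O")
  expect_lt(fx$charge[o], 0)
  expect_equal(sum(fx$charge != 0), 3L)  # O, its H, anchor carbon
})

test_that("energy tables are seeded and hit their means", {
  t0 <- generate_energy_table(n_frames = 5,
                              means = c(kinetic = 100, potential = 100),
                              noise = 0, seed = 1)
  eb <- summarize_energy(t0)
  expect_equal(eb$kinetic_fraction, 0.5)
  t1 <- generate_energy_table(n_frames = 50,
                              means = c(kinetic = 100, potential = 300,
                                        bond = 5, angle = 10, dihedral = 5),
                              noise = 2, seed = 9)
  t2 <- generate_energy_table(n_frames = 50,
                              means = c(kinetic = 100, potential = 300,
                                        bond = 5, angle = 10, dihedral = 5),
                              noise = 2, seed = 9)
  expect_identical(t1, t2)
  expect_equal(colMeans(as.matrix(t1)),
               c(kinetic = 100, potential = 300, bond = 5, angle = 10,
                 dihedral = 5), tolerance = 0.05)
})
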