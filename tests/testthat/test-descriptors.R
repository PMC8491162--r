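test_that("srw05 counts closed 5-walks and matches brute-force enumeration", {
  expect_equal(srw05(parse_smiles("c1ccccc1")), 0)   # bipartite: no odd walks
  expect_equal(srw05(parse_smiles("C1CCCC1")), 10)
  expect_gt(srw05(parse_smiles(fixture_registry("Tofacitinib"))), 0)

  for (smi in c("C", "CC", "CCC", "CC(C)C", "C1CC1", "C1CCC1", "C1CCCC1",
                "C1CCCCC1", "CC1CCC1", "C1CC1C", "c1ccncc1", "C1CC1CC")) {
    g <- parse_smiles(smi)
    expect_lte(g$n_heavy, 8)
    expect_equal(srw05(g), closed_walks_oracle(g$adjacency, 5), info = smi)
  }
  # log-transform variant
  expect_equal(srw05(parse_smiles("C1CCCC1"), log_transform = TRUE), log1p(10))
})

test_that("information content indices follow the entropy formula", {
  # methane, order 0: classes {C}, {H x 4}
  ic0 <- information_content(parse_smiles("C"), k = 0)
  expect_equal(ic0$ic, -(0.2 * log2(0.2) + 0.8 * log2(0.8)))
  expect_equal(ic0$cic, log2(5) - ic0$ic)

  # maximal symmetry: all atoms in one class -> IC = 0, CIC = log2 n
  h2 <- information_content(parse_smiles("[H][H]"), k = 2)
  expect_equal(h2$ic, 0)
  expect_equal(h2$cic, 1)

  # single atom convention
  expect_equal(information_content(parse_smiles("[He]"), k = 2),
               list(ic = 0, cic = 0))

  # IC_k non-decreasing in k, CIC_k = log2(n) - IC_k >= 0
  for (smi in c("CCO", "c1ccccc1", "CC(C)CC", "c1cc[nH]c1",
                fixture_registry("Ruxolitinib"))) {
    g <- parse_smiles(smi)
    n <- hydrogen_filled(g)$n_heavy
    ics <- vapply(0:4, function(k) information_content(g, k)$ic, 0)
    expect_true(all(diff(ics) >= -1e-12), info = smi)
    cics <- vapply(0:4, function(k) information_content(g, k)$cic, 0)
    expect_true(all(cics >= -1e-12), info = smi)
    expect_equal(ics + cics, rep(log2(n), 5), info = smi)
  }
})

test_that("CIC2 of Tofacitinib reproduces the calibration anchor", {
  g <- parse_smiles(fixture_registry("Tofacitinib"))
  expect_equal(round(information_content(g, 2)$cic, 3), 0.500)
})

test_that("Geary autocorrelation matches its closed forms and conventions", {
  expect_equal(geary_autocorrelation(parse_smiles("CO"), 1, "mass"), 1)
  # homonuclear skeleton: zero variance convention
  expect_equal(geary_autocorrelation(parse_smiles("CCC"), 3, "mass"), 0)
  expect_equal(geary_autocorrelation(parse_smiles("CCC"), 1, "mass"), 0)
  # empty lag convention (diameter < 6)
  expect_equal(geary_autocorrelation(parse_smiles("CCO"), 6, "mass"), 0)
})

test_that("Moran autocorrelation matches its closed forms and conventions", {
  expect_equal(moran_autocorrelation(parse_smiles("CO"), 1, "mass"), -1)
  expect_equal(moran_autocorrelation(parse_smiles("CCC"), 1, "mass"), 0)
  expect_equal(moran_autocorrelation(parse_smiles("CCO"), 6, "mass"), 0)
})

test_that("Geary and Moran match the literal-formula oracle everywhere", {
  for (smi in oracle_smiles()) {
    g <- parse_smiles(smi)
    for (prop in c("mass", "sanderson_en", "ionization")) {
      w <- atom_weights(g, prop)
      for (lag in c(1, 2, 4, 6, 8)) {
        expect_equal(geary_autocorrelation(g, lag, prop),
                     geary_oracle(g$topo_dist, w, lag),
                     info = paste(smi, prop, lag))
        expect_equal(moran_autocorrelation(g, lag, prop),
                     moran_oracle(g$topo_dist, w, lag),
                     info = paste(smi, prop, lag))
      }
    }
  }
})

test_that("Galvez charge index follows the charge-transfer matrix definition", {
  expect_equal(charge_index(parse_smiles("CC"), 1), 0)  # M is the identity
  expect_equal(charge_index(parse_smiles("CCO"), 8), 0) # no pairs at 8
  # linear 3-path, hand evaluation of M = A Q:
  # CT(1,2) = -0.25, CT(2,3) = 0.25, both pairs at distance 1
  # G1 = 0.5, JGI1 = 0.5 / (n - 1) = 0.25
  expect_equal(charge_index(parse_smiles("CCC"), 1), 0.25)
  expect_equal(charge_index(parse_smiles("C"), 1), 0)   # single atom
})

test_that("augmented edge adjacency eigenvalue has its closed-form values", {
  expect_equal(eig05_aea_dm(parse_smiles("CC")), 0)  # fewer than 5 bonds
  # cyclopentane: edge graph of C5 is C5; eigenvalues 2cos(2 pi k / 5),
  # C-C dipole weight 0 on the diagonal; 5th largest = 2cos(4 pi / 5)
  expect_equal(eig05_aea_dm(parse_smiles("C1CCCC1")), 2 * cos(4 * pi / 5),
               tolerance = 1e-10)
})

test_that("P_VSA log P bins partition the total heavy-atom surface", {
  for (smi in c("CCO", "c1ccncc1", fixture_registry("Baricitinib"))) {
    g <- parse_smiles(smi)
    total <- sum(atom_weights(g, "vdw_surface", scaled = FALSE))
    bins <- vapply(1:10, function(b) pvsa_logp(g, b), 0)
    expect_equal(sum(bins), total, info = smi)
  }
  expect_error(pvsa_logp(parse_smiles("C"), 11), "between 1 and 10")
  expect_error(pvsa_logp(parse_smiles("C"), 0), "between 1 and 10")
  # aliphatic carbon contribution 0.144 lies in bin 5 (0.1, 0.15]
  g <- parse_smiles("C")
  expect_equal(pvsa_logp(g, 5),
               sum(atom_weights(g, "vdw_surface", scaled = FALSE)))
  expect_equal(sum(vapply(c(1:4, 6:10), function(b) pvsa_logp(g, b), 0)), 0)
})

test_that("PCD is zero for saturated acyclic hydrocarbons and counts bond-order excess", {
  for (smi in c("CC", "CCC", "CC(C)C", "CCCCCC", "CC(C)(C)C"))
    expect_equal(pcd(parse_smiles(smi)), 0, info = smi)
  expect_equal(pcd(parse_smiles("C=C")), 1)   # weight 2 vs count 1
  expect_equal(pcd(parse_smiles("C#N")), 2)   # weight 3 vs count 1
  # ethene + one single bond: paths C=C (1), C-C (0), C=C-C (weight 2)
  expect_equal(pcd(parse_smiles("C=CC")), (2 - 1) + (2 - 1))
})

test_that("descriptor_vector composes the registry deterministically", {
  d <- descriptor_vector(parse_smiles("C1CCCC1"))
  expect_equal(d[["SRW05"]], 10)
  expect_equal(d[["PCD"]], 0)
  expect_equal(d[["GATS6m"]], 0)
  expect_equal(descriptor_vector(parse_smiles("c1ccccc1"))[["SRW05"]], 0)
  expect_true(all(is.finite(d)))
  # deterministic
  expect_identical(d, descriptor_vector(parse_smiles("C1CCCC1")))
})

test_that("every descriptor is invariant under atom relabeling", {
  set.seed(23)
  mols <- c("CC1CCN(C)C1", "c1ccc2[nH]ccc2c1", "CC(=O)NCC#N",
            "c1cnc(nc1)N(C)C", "OCC1CCCO1")
  for (smi in mols) {
    g <- parse_smiles(smi)
    ref <- descriptor_vector(g)
    for (r in 1:3) {
      gp <- permute_molgraph(g, sample(g$n_heavy))
      expect_equal(descriptor_vector(gp), ref, tolerance = 1e-9, info = smi)
    }
  }
})

test_that("calc_descriptors returns a tidy table and validates names", {
  lib <- tibble::tibble(id = c("cp", "bz"),
                        smiles = c("C1CCCC1", "c1ccccc1"))
  out <- calc_descriptors(lib, descriptors = c("SRW05", "CIC2", "JGI8"))
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("id", "SRW05", "CIC2", "JGI8"))
  expect_equal(out$SRW05, c(10, 0))
  expect_error(calc_descriptors(lib, descriptors = "NOPE"), "unknown")
  expect_true(all(retraining_descriptors() %in%
                    names(calc_descriptors(lib))))
})
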