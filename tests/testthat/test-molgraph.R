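test_that("parse_smiles builds correct graphs for canonical small molecules", {
  cp <- parse_smiles("C1CCCC1")
  expect_equal(cp$n_heavy, 5)
  expect_equal(nrow(cp$bonds), 5)
  expect_equal(max(cp$topo_dist), 2)

  bz <- parse_smiles("c1ccccc1")
  expect_equal(bz$n_heavy, 6)
  expect_true(all(bz$atoms$aromatic))
  expect_equal(nrow(bz$bonds), 6)
  expect_true(all(bz$bonds$order == "ar"))

  pr <- parse_smiles("CCC")
  expect_equal(pr$topo_dist[1, 3], 2)

  # implicit hydrogens by standard valence
  expect_equal(parse_smiles("C")$atoms$n_h, 4L)
  expect_equal(parse_smiles("c1ccccc1")$atoms$n_h, rep(1L, 6))
  expect_equal(parse_smiles("c1cc[nH]c1")$atoms$n_h[4], 1L)
  expect_equal(sum(parse_smiles("O=S(=O)(C)C")$atoms$n_h), 6L)
})

test_that("parse errors are informative, empty input rejected", {
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(C"), "unclosed branch")
  expect_error(parse_smiles("CQ"), "position 2")
  expect_error(parse_smiles(""), "empty")
  expect_error(parse_smiles("   "), "empty")
})

test_that("multi-fragment inputs reduce to the largest fragment", {
  salt <- parse_smiles("CCN.Cl")
  expect_equal(salt$n_heavy, 3)
  expect_equal(sort(salt$atoms$element), c("C", "C", "N"))
})

test_that("adjacency and distance matrices satisfy the graph invariants", {
  for (smi in oracle_smiles()) {
    g <- parse_smiles(smi)
    A <- g$adjacency
    expect_true(isSymmetric(A), info = smi)
    expect_true(all(diag(A) == 0), info = smi)
    D <- g$topo_dist
    expect_equal(D, bfs_dist_oracle(A), info = smi)
    expect_true(all((D == 1) == (A == 1)), info = smi)
    expect_true(all(diag(D) == 0), info = smi)
  }
})

test_that("hydrogen_filled expands implicit hydrogens to explicit vertices", {
  me <- hydrogen_filled(parse_smiles("C"))
  expect_equal(me$n_heavy, 5)       # 5 vertices total
  expect_equal(nrow(me$bonds), 4)
  et <- hydrogen_filled(parse_smiles("CC"))
  expect_equal(et$n_heavy, 8)
  expect_equal(nrow(et$bonds), 7)
  bz <- hydrogen_filled(parse_smiles("c1ccccc1"))
  expect_equal(bz$n_heavy, 12)
  expect_equal(nrow(bz$bonds), 12)
  expect_true(all(bz$atoms$n_h == 0))
})

test_that("atom_weights returns per-atom property values, carbon-scaled on request", {
  expect_equal(atom_weights(parse_smiles("CCC"), "mass"), c(1, 1, 1))
  expect_equal(atom_weights(parse_smiles("CO"), "mass", scaled = FALSE),
               c(12.011, 15.999))
  ep <- element_properties()
  expect_equal(atom_weights(parse_smiles("CO"), "sanderson_en"),
               c(1, ep$sanderson_en[ep$symbol == "O"] /
                   ep$sanderson_en[ep$symbol == "C"]))
  expect_error(atom_weights(parse_smiles("[Se]C"), "mass"), "Se")
})

test_that("graphs from rewritten SMILES of the same molecule are isomorphic", {
  pairs <- list(
    c("CC1CCCC1", "C1CCCC1C"),
    c("c1ccccc1C", "Cc1ccccc1"),
    c("OC(=O)CC", "CCC(O)=O"),
    c("c1cc2[nH]ccc2cc1", "c1ccc2c(c1)cc[nH]2")
  )
  for (p in pairs) {
    g1 <- parse_smiles(p[1]); g2 <- parse_smiles(p[2])
    expect_equal(sort(rowSums(g1$adjacency)), sort(rowSums(g2$adjacency)),
                 info = p[1])
    expect_equal(sort(as.vector(g1$topo_dist)), sort(as.vector(g2$topo_dist)),
                 info = p[1])
    expect_equal(sort(g1$atoms$element), sort(g2$atoms$element), info = p[1])
  }
})

test_that("atom relabeling leaves distance-matrix multisets unchanged", {
  set.seed(11)
  for (smi in c("CC1CCN(C)C1", "c1ccc2[nH]ccc2c1", "CC(=O)NCC#N")) {
    g <- parse_smiles(smi)
    for (r in 1:5) {
      gp <- permute_molgraph(g, sample(g$n_heavy))
      expect_equal(sort(as.vector(gp$topo_dist)),
                   sort(as.vector(g$topo_dist)), info = smi)
    }
  }
})

test_that("parser agrees with an independent cheminformatics toolkit on composition", {
  # ChemmineR/OpenBabel as external oracle for heavy-atom and bond counts
  suppressMessages(suppressWarnings({
    for (nm in c("Tofacitinib", "Ruxolitinib", "Baricitinib")) {
      smi <- fixture_registry(nm)
      g <- parse_smiles(smi)
      sdf <- ChemmineR::smiles2sdf(smi)[[1]]
      el <- gsub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
      expect_equal(g$n_heavy, sum(el != "H"), info = nm)
      expect_equal(nrow(g$bonds), nrow(ChemmineR::bondblock(sdf)), info = nm)
      expect_equal(sort(table(g$atoms$element)),
                   sort(table(el[el != "H"])), info = nm)
    }
  }))
})

test_that("SMILES library files round-trip", {
  lib <- tibble::tibble(id = c("a", "b"), smiles = c("CCO", "c1ccccc1"))
  path <- withr::local_tempfile(fileext = ".smi")
  write_smi(lib, path)
  back <- read_smi(path)
  expect_equal(back$id, lib$id)
  expect_equal(back$smiles, lib$smiles)
})

test_that("graph_summary reports composition and five-ring flags", {
  gs <- graph_summary(tibble::tibble(
    id = c("cp", "bz", "tofa"),
    smiles = c("C1CCCC1", "c1ccccc1", fixture_registry("Tofacitinib"))))
  expect_equal(gs$has_five_ring, c(TRUE, FALSE, TRUE))
  expect_equal(gs$n_rings, c(1, 1, 3))
  expect_equal(gs$mw[3], 312.377, tolerance = 1e-6)
})
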