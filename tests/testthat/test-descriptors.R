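# fake conformer builder for closed-form 3D checks
fake_conformer <- function(coords, elem = rep("C", nrow(coords)),
                           charges = rep(0, nrow(coords))) {
  structure(list(smiles = NA, elem = elem, coords = coords,
                 charges = charges,
                 masses = faahscreen:::.elem_lookup(faahscreen:::.MASS, elem, 12.011),
                 n_h = rep(0L, nrow(coords)),
                 degree = rep(1L, nrow(coords)), minimized = TRUE),
            class = "conformer")
}

test_that("3D embedding is deterministic and geometrically sane", {
  c1 <- embed_3d("CC(=O)Oc1ccccc1C(=O)O", seed = 1)
  c2 <- embed_3d("CC(=O)Oc1ccccc1C(=O)O", seed = 1)
  expect_identical(c1$coords, c2$coords)
  expect_identical(c1$charges, c2$charges)
  expect_true(all(is.finite(c1$coords)))
  expect_length(c1$charges, nrow(c1$coords))
  # ethane bond length after minimization
  eth <- embed_3d("CC", seed = 1)
  expect_gte(stats::dist(eth$coords)[1], 1.45)
  expect_lte(stats::dist(eth$coords)[1], 1.60)
  # single heavy atom sits at the origin after centering
  meth <- embed_3d("C", seed = 1)
  expect_equal(as.numeric(meth$coords), c(0, 0, 0))
})

test_that("spectral MAD of the distance matrix matches hand computation", {
  # ethane: D = [[0,1],[1,0]], eigenvalues {1,-1}, mean 0 -> SpMAD = 1
  expect_equal(spmad_distance("CC"), 1)
  expect_equal(spmad_distance("C"), 0)
  # renumbering invariance: same molecule entered in different atom orders
  expect_equal(spmad_distance("CCO"), spmad_distance("OCC"))
  expect_equal(spmad_distance("c1ccccc1CCN"), spmad_distance("NCCc1ccccc1"))
})

test_that("Crippen logP is additive and near the reference value", {
  lp1 <- crippen_logp("CCO")
  lp2 <- crippen_logp("CCO.CCO")
  expect_equal(lp2, 2 * lp1, tolerance = 1e-6)
  # benzene: independent atomic-contribution implementations agree to 0.1
  expect_equal(crippen_logp("c1ccccc1"), 1.6866, tolerance = 0.1)
})

test_that("Burden matrix eigenvalues match a hand-built matrix", {
  # propane: 3 carbons, both bonds terminal
  B <- matrix(0.001, 3, 3)
  diag(B) <- 1
  B[1, 2] <- B[2, 1] <- B[2, 3] <- B[3, 2] <- 0.11
  expected <- sort(abs(eigen(B, symmetric = TRUE)$values), decreasing = TRUE)
  got <- burden_spmax5("CCC")
  expect_true(attr(got, "degenerate")[1])
  expect_equal(as.numeric(got), expected[3], tolerance = 1e-10)
  # five or more atoms: proper 5th eigenvalue, no degeneracy flag
  got5 <- burden_spmax5("c1ccccc1CCN")
  expect_false(attr(got5, "degenerate")[1])
  # renumbering invariance
  expect_equal(as.numeric(burden_spmax5("c1ccccc1CCN")),
               as.numeric(burden_spmax5("NCCc1ccccc1")), tolerance = 1e-10)
})

test_that("WHIM size index matches closed forms and is motion-invariant", {
  # unit tetrahedron: covariance is the identity -> A = 3
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(whim_size(fake_conformer(tet)), 3, tolerance = 1e-12)
  # planar points: lambda3 = 0 so A = lambda1 * lambda2
  sq <- cbind(c(2, -2, 2, -2), c(1, 1, -1, -1), 0)
  S <- crossprod(sweep(sq, 2, colMeans(sq))) / 4
  ev <- sort(eigen(S)$values, decreasing = TRUE)
  expect_equal(whim_size(fake_conformer(sq)), ev[1] * ev[2], tolerance = 1e-12)
  # rigid rotation + translation leave A unchanged
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  conf <- embed_3d("CC(=O)Oc1ccccc1C(=O)O", seed = 1)
  moved <- fake_conformer(sweep(conf$coords %*% R, 2, c(3, -1, 2), `+`),
                          elem = conf$elem)
  ref <- fake_conformer(conf$coords, elem = conf$elem)
  for (wt in c("unweighted", "sanderson_en", "ionization", "vdw_volume")) {
    expect_equal(whim_size(moved, wt), whim_size(ref, wt), tolerance = 1e-9)
  }
})

test_that("RDF descriptor follows its Gaussian pair formula", {
  one <- fake_conformer(matrix(0, 1, 3))
  expect_equal(rdf_descriptor(one), 0)
  # two carbons exactly 8.5 apart: weights 1, exponent 0 -> g = 1
  two <- fake_conformer(rbind(c(0, 0, 0), c(8.5, 0, 0)))
  expect_equal(rdf_descriptor(two), 1, tolerance = 1e-12)
  # monotone decay moving away from the evaluation radius
  g_at <- function(d) rdf_descriptor(fake_conformer(rbind(0, c(d, 0, 0))))
  expect_true(g_at(8.5) > g_at(8.3))
  expect_true(g_at(8.3) > g_at(8.0))
  expect_true(g_at(8.5) > g_at(8.7))
  # rotation invariance on a real conformer
  conf <- embed_3d("CCCCCCCCCCCC", seed = 1)
  flip <- fake_conformer(sweep(conf$coords[, c(2, 1, 3)], 2, c(1, 1, -1), `*`),
                         elem = conf$elem)
  expect_equal(rdf_descriptor(fake_conformer(conf$coords, elem = conf$elem)),
               rdf_descriptor(flip), tolerance = 1e-9)
})

test_that("charged partial surface areas follow their definitions", {
  toy <- fake_conformer(rbind(c(0, 0, 0), c(3, 0, 0)),
                        charges = c(0.2, -0.2))
  wp <- cpsa_wpsa(toy, sasa = c(10, 20))
  expect_equal(wp$PPSA1, 10)
  expect_equal(wp$TMSA, 30)
  expect_equal(wp$WPSA1, 10 * 30 / 1000)
  expect_equal(wp$WPSA2, (0.2 * 10) * 30 / 1000)
  # no positive atoms -> zero
  wp0 <- cpsa_wpsa(fake_conformer(rbind(c(0, 0, 0), c(3, 0, 0)),
                                  charges = c(-0.1, -0.2)), sasa = c(10, 20))
  expect_equal(wp0$WPSA1, 0)
  expect_equal(wp0$WPSA2, 0)
  # doubling all surface areas quadruples WPSA1
  wp2 <- cpsa_wpsa(toy, sasa = c(20, 40))
  expect_equal(wp2$WPSA1, 4 * wp$WPSA1)
  # an isolated sphere has its full analytic surface
  lone <- fake_conformer(matrix(0, 1, 3), charges = 0.1)
  expect_equal(atom_sasa(lone), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
})

test_that("descriptor panel is reproducible and complete", {
  d1 <- descriptor_panel(c("CC(=O)Oc1ccccc1C(=O)O", "CCN1CCN(CC1)CCO"), seed = 3)
  d2 <- descriptor_panel(c("CC(=O)Oc1ccccc1C(=O)O", "CCN1CCN(CC1)CCO"), seed = 3)
  expect_identical(d1, d2)
  expect_named(d1, c("id", "CrippenLogP", "SpMAD_D", "SpMax5_Bhi", "Au",
                     "Ae", "Ai", "As", "Av", "RDF85m", "WPSA1", "WPSA2"))
  expect_true(all(is.finite(as.matrix(d1[, -1]))))
  expect_true(all(d1$RDF85m >= 0) && all(d1$WPSA1 >= 0))
})
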