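test_that("atom paths enumerate simple element paths from a root atom", {
  methane <- FX$methane$graph
  expect_identical(atom_paths(methane, 1, depth = 2),
                   sort(c("C", "CH", "CH", "CH", "CH")))
  # depth 1 is just the root element; an isolated atom likewise
  expect_identical(atom_paths(methane, 1, depth = 1), "C")
  lone <- mol_graph("O", NULL)
  expect_identical(atom_paths(lone, 1, depth = 5), "O")
  expect_error(atom_paths(methane, 9, depth = 2),
               class = "confstrain_shape_error")
})

test_that("atom paths agree with a brute-force simple-path oracle", {
  # ethanol from C1 at depth 3, plus random graphs at several depths
  eth <- FX$ethanol$graph
  expect_identical(atom_paths(eth, 1, depth = 3), brute_paths(eth, 1, 3))
  for (seed in 1:8) {
    g <- random_molecule_graph(sample(4:9, 1), seed = seed, ring = seed %% 2 == 0)
    at <- sample(length(g$elements), 1)
    d <- sample(2:5, 1)
    expect_identical(atom_paths(g, at, depth = d), brute_paths(g, at, d))
  }
})

test_that("atom paths are invariant under atom relabeling", {
  set.seed(61)
  g <- random_molecule_graph(8, seed = 17, ring = TRUE)
  perm <- sample(8)
  gp <- permute_graph(g, perm)
  # atom i of gp is atom perm[i] of g
  for (i in seq_len(8))
    expect_identical(atom_paths(gp, i, 6), atom_paths(g, perm[i], 6))
})

test_that("randomly permuted molecules match and the mapping is recovered", {
  set.seed(71)
  graphs <- c(lapply(FX, `[[`, "graph"),
              lapply(1:6, function(s) random_molecule_graph(10, seed = s,
                                                            ring = TRUE)))
  for (rep in 1:30) {
    g <- graphs[[sample(length(graphs), 1)]]
    n <- length(g$elements)
    perm <- sample(n)
    gp <- permute_graph(g, perm)
    m <- same_molecule(g, gp)
    expect_true(m$is_match)
    # mapping must send bonds of g onto bonds of gp
    eb <- paste(pmin(gp$bonds[, 1], gp$bonds[, 2]),
                pmax(gp$bonds[, 1], gp$bonds[, 2]))
    mapped <- cbind(m$mapping[g$bonds[, 1]], m$mapping[g$bonds[, 2]])
    ea <- paste(pmin(mapped[, 1], mapped[, 2]), pmax(mapped[, 1], mapped[, 2]))
    expect_setequal(ea, eb)
    # composed with the inverse permutation this is an automorphism of g
    auto <- perm[m$mapping]
    expect_identical(sort(auto), seq_len(n))
    expect_identical(g$elements[auto], g$elements)
  }
})

test_that("constitutional isomers do not match", {
  m <- same_molecule(FX$ethanol$graph, FX$dimethyl_ether$graph)
  expect_false(m$is_match)
  expect_match(m$reason, "signature")
  expect_false(same_molecule(FX$hexane$graph, FX$methylpentane$graph)$is_match)
  # independent confirmation via brute-force permutation search
  expect_false(brute_isomorphic(FX$hexane$graph, FX$methylpentane$graph))
  expect_false(brute_isomorphic(FX$ethanol$graph, FX$dimethyl_ether$graph))
})

test_that("identity decisions agree with a brute-force oracle on small graphs", {
  for (seed in 1:12) {
    n <- sample(4:9, 1)
    a <- random_molecule_graph(n, seed = seed, ring = seed %% 3 == 0)
    b <- if (seed %% 2 == 0) {
      permute_graph(a, sample(n))
    } else {
      random_molecule_graph(n, seed = seed + 100, ring = seed %% 3 == 0)
    }
    expect_identical(same_molecule(a, b)$is_match, brute_isomorphic(a, b))
  }
})

test_that("identity matching is symmetric and detects changed hydrogen counts", {
  set.seed(81)
  pairs <- list(list(FX$ethanol$graph, FX$dimethyl_ether$graph),
                list(FX$hexane$graph, FX$methylpentane$graph),
                list(FX$benzene$graph, FX$chlorobenzene$graph))
  for (p in pairs)
    expect_identical(same_molecule(p[[1]], p[[2]])$is_match,
                     same_molecule(p[[2]], p[[1]])$is_match)
  # an added hydrogen (valence "fixed" by a generator) must break identity
  eth <- FX$ethanol$graph
  eth_h <- mol_graph(c(eth$elements, "H"), rbind(eth$bonds, c(3L, 10L)))
  expect_false(same_molecule(eth, eth_h)$is_match)
})

test_that("pathological symmetry under a tiny node budget raises an ambiguity error", {
  # large even cycle of one element at depth 1: all signatures identical
  n <- 12L
  ring <- mol_graph(rep("C", n), rbind(cbind(1:(n - 1), 2:n), c(n, 1L)))
  expect_error(same_molecule(ring, ring, depth = 1, node_budget = 5),
               class = "confstrain_ambiguity_error")
})

test_that("superposition RMSD is zero under rigid motion and positive otherwise", {
  set.seed(91)
  p <- matrix(rnorm(30), 10)
  expect_lt(kabsch_rmsd(p, p), 1e-12)
  for (seed in 1:10) {
    rot <- random_rigid_rotation(seed)
    q <- p %*% t(rot) + matrix(rnorm(3), 10, 3, byrow = TRUE)
    expect_lt(kabsch_rmsd(p, q), 1e-10)
  }
  # a 37-degree rotation about an arbitrary axis plus translation
  axis <- c(1, 2, 3) / sqrt(14)
  th <- 37 * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  rot37 <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  expect_lt(kabsch_rmsd(p, p %*% t(rot37) + 5), 1e-10)
})

test_that("superposition RMSD agrees with a quaternion oracle and is symmetric", {
  set.seed(101)
  for (rep in 1:20) {
    p <- matrix(rnorm(30), 10)
    q <- matrix(rnorm(30), 10)
    r1 <- kabsch_rmsd(p, q)
    expect_lt(abs(r1 - quaternion_rmsd(p, q)), 1e-10)
    expect_lt(abs(r1 - kabsch_rmsd(q, p)), 1e-10)
    # superposition can only reduce the deviation
    expect_lte(r1, sqrt(mean(rowSums((p - q)^2))) + 1e-12)
  }
  # printed 4-point fixture against the quaternion oracle
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  b <- rbind(c(0, 0, 1), c(2, 0, 0), c(0, 1, 0), c(3, 0, 0))
  expect_equal(kabsch_rmsd(a, b), quaternion_rmsd(a, b), tolerance = 1e-10)
})

test_that("reflections are excluded: enantiomers do not superpose to zero", {
  r <- FX$chlorofluoroethane_R$conformation$coords
  s <- FX$chlorofluoroethane_S$conformation$coords
  expect_gt(kabsch_rmsd(r, s), 0.1)
})

test_that("mapping and heavy-atom filtering are honoured", {
  conf <- FX$ethanol$conformation
  n <- nrow(conf$coords)
  perm <- sample(n)
  shuffled <- conformation(conf$elements[perm], conf$coords[perm, ],
                           net_charge = conf$net_charge)
  # pairing atom i with its new position perm-inverse recovers zero
  mapping <- match(seq_len(n), perm)
  expect_lt(kabsch_rmsd(conf, shuffled, mapping = mapping), 1e-10)
  expect_lt(kabsch_rmsd(conf, conf, heavy_only = TRUE), 1e-10)
  expect_error(kabsch_rmsd(matrix(0, 3, 3), matrix(0, 4, 3)),
               class = "confstrain_shape_error")
})
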