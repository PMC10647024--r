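# Shared fixtures, built in code at test time.

FX <- make_molecule_fixtures()

# apply an atom permutation to a graph: atom i of the result is atom
# perm[i] of the input (so result = input reindexed by perm)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  mol_graph(g$elements[perm],
            matrix(inv[g$bonds], ncol = 2L),
            atom_names = if (is.null(g$atom_names)) NULL else g$atom_names[perm])
}

# random chemistry-flavoured tree graph (plus optional extra ring-closure
# edge) for property tests
random_molecule_graph <- function(n, seed, elements = c("C", "N", "O"),
                                  ring = FALSE) {
  set.seed(seed)
  els <- sample(elements, n, replace = TRUE)
  bonds <- if (n > 1L) cbind(2:n, vapply(2:n, function(i)
    sample.int(i - 1L, 1L), 1L)) else matrix(integer(0), ncol = 2L)
  if (ring && n >= 4L) {
    extra <- sort(sample.int(n, 2L))
    if (!any(bonds[, 1] == extra[2] & bonds[, 2] == extra[1]) &&
        !any(bonds[, 1] == extra[1] & bonds[, 2] == extra[2]))
      bonds <- rbind(bonds, extra)
  }
  mol_graph(els, bonds)
}

# a flexible chiral fixture: 2-chlorobutane (chiral at C2, one rotatable
# C2-C3 bond)
chlorobutane_fixture <- function() {
  g <- mol_graph(c("C", "C", "C", "C", "Cl", rep("H", 9L)),
                 rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(2L, 5L),
                       c(1L, 6L), c(1L, 7L), c(1L, 8L), c(2L, 9L),
                       c(3L, 10L), c(3L, 11L),
                       c(4L, 12L), c(4L, 13L), c(4L, 14L)))
  conf <- conformation(g$elements, confstrain:::embed_graph(g))
  list(graph = g, conformation = conf)
}

random_rigid_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
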