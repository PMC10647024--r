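#' Create a molecular graph
#'
#' A molecular graph is the connectivity view of a molecule: ordered element
#' symbols plus an undirected bond list. Bond orders are deliberately not
#' part of the structure - identity matching in this package is purely
#' element-and-connectivity based. The graph may be disconnected (salts);
#' connected components are tracked.
#'
#' @param elements Character vector of chemical symbols.
#' @param bonds Two-column integer matrix of bonded atom index pairs
#'   (1-based, unordered; may have zero rows).
#' @param atom_names Optional character vector of atom labels.
#' @return An object of class `"mol_graph"`.
#' @examples
#' # water
#' mol_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
#' @export
mol_graph <- function(elements, bonds, atom_names = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) err_shape("a molecular graph needs at least one atom")
  bad <- setdiff(unique(elements), names(ELEMENT_MASSES))
  if (length(bad))
    err_shape(sprintf("not valid chemical symbols: %s", paste(bad, collapse = ", ")))
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2L)
  }
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > n))
      err_shape("bond indices out of range")
    if (any(bonds[, 1L] == bonds[, 2L]))
      err_shape("self-bonds are not allowed")
    # canonical order (i < j), dedup
    bonds <- t(apply(bonds, 1L, sort))
    bonds <- unique(bonds)
    dim(bonds) <- c(length(bonds) %/% 2L, 2L)
  }
  if (!is.null(atom_names)) {
    atom_names <- as.character(atom_names)
    if (length(atom_names) != n) err_shape("atom_names length must match element count")
  }
  g <- structure(list(elements = elements, bonds = bonds, atom_names = atom_names),
                 class = "mol_graph")
  g$components <- graph_components(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds, %d component(s) [%s]\n",
              length(x$elements), nrow(x$bonds), max(x$components),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    sort(table(x$elements), decreasing = TRUE),
                    sep = "", collapse = " ")))
  invisible(x)
}

# adjacency list: integer vector of neighbours per atom
adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1L]; j <- b[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

graph_components <- function(graph) {
  n <- length(graph$elements)
  adj <- adjacency(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

degree_of <- function(graph) {
  n <- length(graph$elements)
  tabulate(c(graph$bonds[, 1L], graph$bonds[, 2L]), nbins = n)
}

# Bonds whose removal disconnects the graph (bridges), via DFS low-link.
bridge_bonds <- function(graph) {
  n <- length(graph$elements)
  adj <- adjacency(graph)
  disc <- integer(n); low <- integer(n); timer <- 0L
  bridges <- matrix(integer(0), ncol = 2L)
  # iterative DFS with parent tracking
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(list(v = root, parent = 0L, i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i <= length(adj[[v]])) {
        u <- adj[[v]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (u == fr$parent) next
        if (disc[u] == 0L) {
          timer <- timer + 1L; disc[u] <- low[u] <- timer
          stack[[length(stack) + 1L]] <- list(v = u, parent = v, i = 1L)
        } else {
          low[v] <- min(low[v], disc[u])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          p <- stack[[length(stack)]]$v
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) bridges <- rbind(bridges, c(p, v))
        }
      }
    }
  }
  bridges
}

#' Rotatable bonds of a molecular graph
#'
#' A bond is rotatable when it is acyclic (a bridge), both end atoms have
#' degree at least two, and neither end carries only hydrogens besides the
#' bond itself (methyl/amine-type rotations are excluded since they do not
#' produce distinguishable heavy-atom conformers).
#'
#' @param graph A [mol_graph()].
#' @return Two-column integer matrix of rotatable bond atom pairs.
#' @export
rotatable_bonds <- function(graph) {
  deg <- degree_of(graph)
  adj <- adjacency(graph)
  br <- bridge_bonds(graph)
  keep <- logical(nrow(br))
  for (k in seq_len(nrow(br))) {
    i <- br[k, 1L]; j <- br[k, 2L]
    if (deg[i] < 2L || deg[j] < 2L) next
    heavy_i <- any(graph$elements[setdiff(adj[[i]], j)] != "H")
    heavy_j <- any(graph$elements[setdiff(adj[[j]], i)] != "H")
    keep[k] <- heavy_i && heavy_j
  }
  out <- br[keep, , drop = FALSE]
  out[order(pmin(out[, 1L], out[, 2L]), pmax(out[, 1L], out[, 2L])), , drop = FALSE]
}

# Atoms on the j-side of bond i-j after removing the bond (for torsion
# rotation). Only valid for bridges.
bond_subtree <- function(graph, i, j) {
  adj <- adjacency(graph)
  seen <- logical(length(graph$elements))
  seen[i] <- TRUE
  stack <- j
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    out <- c(out, v)
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  sort(out)
}

# Signed-volume stereo signature: for every atom with exactly four
# neighbours, the sign of det(n2-n1, n3-n1, n4-n1) with neighbours in atom
# index order. Torsion rotations never change these signs, so comparing
# signatures verifies that generated conformers keep the seed's chirality.
stereo_signature <- function(graph, conf) {
  adj <- adjacency(graph)
  centers <- which(vapply(adj, length, 1L) == 4L)
  sig <- integer(length(centers))
  for (k in seq_along(centers)) {
    nb <- adj[[centers[k]]]
    m <- conf$coords[nb[2:4], , drop = FALSE] -
      matrix(conf$coords[nb[1L], ], 3L, 3L, byrow = TRUE)
    sig[k] <- sign(det(m))
  }
  names(sig) <- as.character(centers)
  sig
}
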