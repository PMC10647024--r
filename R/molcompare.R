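#' Element-labeled atomic paths from one atom
#'
#' Enumerates every simple path (no repeated atom) of up to `depth` atoms
#' starting at `atom`, encoding each as the concatenation of element symbols
#' along the path. The multiset of these strings is an isomorphism
#' invariant of the rooted graph and is the per-atom signature used by
#' [same_molecule()]. Bond orders play no role - paths are element-based
#' only.
#'
#' @param graph A [mol_graph()].
#' @param atom Atom index (1-based).
#' @param depth Maximum number of atoms in a path (>= 1).
#' @return Sorted character vector (a deterministic multiset encoding).
#' @examples
#' methane <- mol_graph(c("C", "H", "H", "H", "H"), cbind(1, 2:5))
#' atom_paths(methane, 1, depth = 2)   # "C" and four "CH"
#' @export
atom_paths <- function(graph, atom, depth = 8L) {
  stopifnot(inherits(graph, "mol_graph"), depth >= 1L)
  n <- length(graph$elements)
  if (atom < 1L || atom > n) err_shape(sprintf("atom index %d out of range 1..%d", atom, n))
  adj <- adjacency(graph)
  el <- graph$elements
  out <- character(0)
  visited <- logical(n)
  recurse <- function(v, prefix, len) {
    out[[length(out) + 1L]] <<- prefix
    if (len == depth) return(invisible())
    visited[v] <<- TRUE
    for (u in adj[[v]]) {
      if (!visited[u]) recurse(u, paste0(prefix, el[u]), len + 1L)
    }
    visited[v] <<- FALSE
  }
  recurse(atom, el[atom], 1L)
  sort(out)
}

# canonical per-atom signature string for all atoms at once
atom_signatures <- function(graph, depth) {
  vapply(seq_along(graph$elements),
         function(i) paste(atom_paths(graph, i, depth), collapse = ""),
         "")
}

#' Decide whether two structures are the same molecule
#'
#' Conformer generators may reorder atoms, rename them, or silently alter
#' the molecule (e.g. fill open valences). This test decides identity from
#' elements and connectivity alone: it first compares element multisets,
#' then partitions atoms by their element-path signature ([atom_paths()])
#' and searches for a signature-consistent bijection, verified against the
#' full bond structure. Hydrogens participate, so a changed H count is
#' detected.
#'
#' @param a,b [mol_graph()] objects.
#' @param depth Path depth for the signatures (bonds-based default 8).
#' @param node_budget Cap on backtracking nodes before an ambiguity error
#'   is raised (pathological symmetry; retry with larger `depth`).
#' @return A `"match_result"`: `is_match`, `mapping` (integer permutation,
#'   atom i of `a` corresponds to atom `mapping[i]` of `b`; only when
#'   matched) and `reason` on mismatch.
#' @examples
#' ethanol <- mol_graph(c("C","C","O","H","H","H","H","H","H"),
#'   rbind(c(1,2), c(2,3), c(1,4), c(1,5), c(1,6), c(2,7), c(2,8), c(3,9)))
#' perm <- rev(seq_len(9))
#' shuffled <- mol_graph(ethanol$elements[perm],
#'   matrix(match(ethanol$bonds, perm), ncol = 2))
#' same_molecule(ethanol, shuffled)$is_match
#' @export
same_molecule <- function(a, b, depth = 8L, node_budget = 200000L) {
  stopifnot(inherits(a, "mol_graph"), inherits(b, "mol_graph"))
  no <- function(reason) structure(list(is_match = FALSE, mapping = NULL,
                                        reason = reason), class = "match_result")
  if (length(a$elements) != length(b$elements))
    return(no(sprintf("atom counts differ (%d vs %d)",
                      length(a$elements), length(b$elements))))
  ta <- sort(a$elements); tb <- sort(b$elements)
  if (!identical(ta, tb)) return(no("element multisets differ"))
  if (nrow(a$bonds) != nrow(b$bonds))
    return(no(sprintf("bond counts differ (%d vs %d)", nrow(a$bonds), nrow(b$bonds))))

  sig_a <- atom_signatures(a, depth)
  sig_b <- atom_signatures(b, depth)
  if (!identical(sort(sig_a), sort(sig_b)))
    return(no("element-path signatures differ"))

  adj_a <- adjacency(a); adj_b <- adjacency(b)
  n <- length(a$elements)
  # order A's atoms: smallest signature class first, then lowest index
  class_size <- table(sig_a)
  ord <- order(as.integer(class_size[sig_a]), seq_len(n))
  cand0 <- lapply(seq_len(n), function(i) which(sig_b == sig_a[i]))

  mapping <- integer(n)      # 0 = unassigned
  used_b <- logical(n)
  nodes <- 0L

  assign_next <- function(pos) {
    if (pos > n) return(TRUE)
    i <- ord[pos]
    for (j in cand0[[i]]) {
      if (used_b[j]) next
      ok <- TRUE
      for (u in adj_a[[i]]) {
        if (mapping[u] != 0L && !(mapping[u] %in% adj_b[[j]])) { ok <- FALSE; break }
      }
      if (ok) {
        # reverse direction: every mapped neighbour of j must be a mapped
        # neighbour image of i
        for (v in adj_b[[j]]) {
          w <- match(v, mapping)
          if (!is.na(w) && !(w %in% adj_a[[i]])) { ok <- FALSE; break }
        }
      }
      nodes <<- nodes + 1L
      if (nodes > node_budget) err_ambiguity(node_budget)
      if (!ok) next
      mapping[i] <<- j; used_b[j] <<- TRUE
      if (assign_next(pos + 1L)) return(TRUE)
      mapping[i] <<- 0L; used_b[j] <<- FALSE
    }
    FALSE
  }

  if (!assign_next(1L))
    return(no("no bond-preserving bijection exists at this path depth"))

  # full verification: every bond of a maps onto a bond of b
  eb <- paste(pmin(b$bonds[, 1L], b$bonds[, 2L]),
              pmax(b$bonds[, 1L], b$bonds[, 2L]))
  ma <- cbind(mapping[a$bonds[, 1L]], mapping[a$bonds[, 2L]])
  ea <- paste(pmin(ma[, 1L], ma[, 2L]), pmax(ma[, 1L], ma[, 2L]))
  if (!setequal(ea, eb) || anyDuplicated(ea))
    return(no("mapping failed full bond verification"))
  structure(list(is_match = TRUE, mapping = mapping, reason = NULL),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$is_match) cat("<match_result> same molecule\n")
  else cat(sprintf("<match_result> NOT the same molecule: %s\n", x$reason))
  invisible(x)
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Minimum root-mean-square deviation between two conformations over all
#' rigid rotations and translations. Reflections are excluded (determinant
#' correction), so enantiomeric geometries do not superpose to zero -
#' chirality is respected.
#'
#' @param a,b [conformation()] objects or plain N x 3 coordinate matrices.
#' @param mapping Optional integer permutation pairing atom i of `a` with
#'   atom `mapping[i]` of `b` (e.g. from [same_molecule()]).
#' @param heavy_only Drop hydrogens before superposing (conformations only).
#' @return RMSD in Angstrom (non-negative scalar).
#' @examples
#' p <- matrix(rnorm(12), 4)
#' kabsch_rmsd(p, p + 1)      # rigid translation: 0
#' @export
kabsch_rmsd <- function(a, b, mapping = NULL, heavy_only = FALSE) {
  ca <- if (inherits(a, "conformation")) a$coords else as.matrix(a)
  cb <- if (inherits(b, "conformation")) b$coords else as.matrix(b)
  if (!is.null(mapping)) {
    if (length(mapping) != nrow(ca)) err_shape("mapping length must match atom count")
    cb <- cb[mapping, , drop = FALSE]
  }
  if (heavy_only) {
    if (!inherits(a, "conformation") || !inherits(b, "conformation"))
      err_shape("heavy_only needs conformations (element information)")
    keep <- a$elements != "H"
    eb <- if (is.null(mapping)) b$elements else b$elements[mapping]
    if (!identical(a$elements[keep], eb[keep]))
      err_shape("element sequences disagree under the given pairing")
    ca <- ca[keep, , drop = FALSE]; cb <- cb[keep, , drop = FALSE]
  }
  if (nrow(ca) != nrow(cb)) err_shape("atom counts differ")
  if (nrow(ca) < 1L) err_shape("no atoms left to superpose")
  p <- sweep(ca, 2L, colMeans(ca))
  q <- sweep(cb, 2L, colMeans(cb))
  s <- svd(crossprod(p, q))
  dsign <- sign(det(s$v %*% t(s$u)))
  if (dsign == 0) dsign <- 1
  rot <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  diffs <- p %*% t(rot) - q
  sqrt(sum(diffs^2) / nrow(p))
}
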