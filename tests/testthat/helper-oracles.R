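# Independent oracles used to check the package's own implementations.
# These deliberately use different algorithms from the code under test.

# central finite-difference gradient of any potential
fd_gradient <- function(potential, x, h = 1e-5) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  g <- x * 0
  for (i in seq_len(nrow(x))) for (d in seq_len(ncol(x))) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    g[i, d] <- (pes_evaluate(potential, xp)$energy -
                  pes_evaluate(potential, xm)$energy) / (2 * h)
  }
  g
}

# Horn's quaternion method for optimal superposition RMSD (no reflections),
# an algorithm independent of the SVD-based Kabsch route.
quaternion_rmsd <- function(p, q) {
  p <- sweep(as.matrix(p), 2L, colMeans(p))
  q <- sweep(as.matrix(q), 2L, colMeans(q))
  m <- crossprod(p, q)   # sum_i p_i q_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4L, 4L, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lambda) / nrow(p)
  sqrt(max(msd, 0))
}

# brute-force simple-path enumeration by explicit recursion over index
# vectors (no string accumulation; compares against atom_paths)
brute_paths <- function(graph, atom, depth) {
  adj <- list()
  n <- length(graph$elements)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds[r, 1]; b <- graph$bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  paths <- list()
  grow <- function(path) {
    paths[[length(paths) + 1L]] <<- path
    if (length(path) == depth) return(invisible())
    for (u in adj[[path[length(path)]]])
      if (!(u %in% path)) grow(c(path, u))
  }
  grow(atom)
  sort(vapply(paths, function(p) paste(graph$elements[p], collapse = ""), ""))
}

# brute-force graph isomorphism: backtracking over element-consistent,
# adjacency-consistent assignments in plain index order (no signatures)
brute_isomorphic <- function(a, b) {
  n <- length(a$elements)
  if (n != length(b$elements)) return(FALSE)
  if (!identical(sort(a$elements), sort(b$elements))) return(FALSE)
  adj_a <- matrix(FALSE, n, n); adj_b <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(a$bonds))) {
    adj_a[a$bonds[r, 1], a$bonds[r, 2]] <- TRUE
    adj_a[a$bonds[r, 2], a$bonds[r, 1]] <- TRUE
  }
  for (r in seq_len(nrow(b$bonds))) {
    adj_b[b$bonds[r, 1], b$bonds[r, 2]] <- TRUE
    adj_b[b$bonds[r, 2], b$bonds[r, 1]] <- TRUE
  }
  if (sum(adj_a) != sum(adj_b)) return(FALSE)
  map <- integer(n); used <- logical(n)
  rec <- function(i) {
    if (i > n) return(TRUE)
    for (j in seq_len(n)) {
      if (used[j] || a$elements[i] != b$elements[j]) next
      ok <- TRUE
      for (prev in seq_len(i - 1L)) {
        if (adj_a[i, prev] != adj_b[j, map[prev]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[i] <<- j; used[j] <<- TRUE
      if (rec(i + 1L)) return(TRUE)
      used[j] <<- FALSE; map[i] <<- 0L
    }
    FALSE
  }
  rec(1L)
}

# signed volumes at 4-coordinate centres - stereo oracle for generated
# conformers (neighbours in atom-index order)
signed_volumes <- function(graph, coords) {
  n <- length(graph$elements)
  adj <- list(); for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds[r, 1]; b <- graph$bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  centers <- which(lengths(adj) == 4L)
  vapply(centers, function(c0) {
    nb <- sort(adj[[c0]])
    m <- coords[nb[2:4], , drop = FALSE] -
      matrix(coords[nb[1], ], 3, 3, byrow = TRUE)
    sign(det(m))
  }, 0)
}
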