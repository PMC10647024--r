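#' Synthetic cohort specification
#'
#' Defines a population of synthetic ligand ensemble records whose
#' strain-energy (delta-E) values are exact draws from a stated
#' distribution, so every downstream statistic has a known ground truth.
#' The defaults mirror the published cohort scale: a Gamma delta-E model
#' whose median is 2.91 kcal/mol and whose 90th percentile is 9.85
#' kcal/mol (shape 0.971512, scale 4.372 kcal/mol), atom counts of mean
#' 48.6 and sd 18.6, up to 200 conformers per ligand with half the ligands
#' saturating the cap, and subset fractions of roughly 12% bound-below-
#' minimum and 22% above the 20 kcal/mol window.
#'
#' @param n_ligands Number of records to draw.
#' @param delta_distribution `"gamma"`, `"exponential"` or `"lognormal"`.
#' @param delta_params Distribution parameters (kcal/mol scale):
#'   gamma `shape`/`scale`, exponential `mean`, lognormal
#'   `meanlog`/`sdlog`.
#' @param max_conformers Ensemble size cap.
#' @param atom_count_mean,atom_count_sd Normal model of molecule size
#'   (truncated below at `atom_count_min`).
#' @param atom_count_min Smallest molecule size emitted.
#' @param frac_below_min Probability a record's bound conformation beats
#'   the ensemble minimum (scenario `below_min`, negative delta-E).
#' @param frac_above_cutoff Probability a record lands above the subset
#'   window (delta-E > `cutoff`, scenario `above_max`).
#' @param frac_single Probability of a single-conformer record (these are
#'   what the multiconformer filter removes).
#' @param frac_charged Probability of a non-zero net charge.
#' @param size_delta_correlation Gaussian-copula rank correlation between
#'   molecule size and delta-E (default 0.5): larger molecules carry more
#'   strain, while the marginal delta-E distribution remains exactly the
#'   stated one.
#' @param member_rel_params Lognormal `meanlog`/`sdlog` of the ensemble
#'   members' relative energies above their global minimum. The defaults
#'   (3.1289, 3.5824) put about 65%, 59% and 51% of conformers more than
#'   6, 10 and 20 kcal/mol above the global minimum - the heavy-tailed
#'   shape real generated ensembles show.
#' @param cutoff Subset window in kcal/mol.
#' @param element_set Element set tag carried by the cohort.
#' @param rng_seed Integer seed; cohorts are bit-reproducible.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_ligands = 1000L,
                        delta_distribution = c("gamma", "exponential", "lognormal"),
                        delta_params = list(shape = 0.971512, scale = 4.372),
                        max_conformers = 200L,
                        atom_count_mean = 48.6, atom_count_sd = 18.6,
                        atom_count_min = 8L,
                        frac_below_min = 0.124, frac_above_cutoff = 0.220,
                        frac_single = 0.02, frac_charged = 0.09,
                        size_delta_correlation = 0.5,
                        member_rel_params = list(meanlog = 3.1289, sdlog = 3.5824),
                        cutoff = 20, element_set = "CHONSFCl",
                        rng_seed = 1L) {
  delta_distribution <- match.arg(delta_distribution)
  stopifnot(n_ligands >= 1L, max_conformers >= 1L,
            frac_below_min >= 0, frac_above_cutoff >= 0, frac_single >= 0,
            frac_below_min + frac_above_cutoff + frac_single < 1,
            abs(size_delta_correlation) < 1,
            atom_count_sd > 0, cutoff > 0,
            all(unlist(delta_params) > 0) || delta_distribution == "lognormal")
  structure(list(n_ligands = as.integer(n_ligands),
                 delta_distribution = delta_distribution,
                 delta_params = delta_params,
                 max_conformers = as.integer(max_conformers),
                 atom_count_mean = atom_count_mean,
                 atom_count_sd = atom_count_sd,
                 atom_count_min = as.integer(atom_count_min),
                 frac_below_min = frac_below_min,
                 frac_above_cutoff = frac_above_cutoff,
                 frac_single = frac_single, frac_charged = frac_charged,
                 size_delta_correlation = size_delta_correlation,
                 member_rel_params = member_rel_params,
                 cutoff = cutoff, element_set = element_set,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

delta_quantile_fun <- function(spec) {
  p <- spec$delta_params
  switch(spec$delta_distribution,
         gamma = function(q) stats::qgamma(q, shape = p$shape, scale = p$scale),
         exponential = function(q) stats::qexp(q, rate = 1 / p$mean),
         lognormal = function(q) stats::qlnorm(q, meanlog = p$meanlog,
                                               sdlog = p$sdlog))
}

delta_draw_fun <- function(spec) {
  p <- spec$delta_params
  switch(spec$delta_distribution,
         gamma = function(n) stats::rgamma(n, shape = p$shape, scale = p$scale),
         exponential = function(n) stats::rexp(n, rate = 1 / p$mean),
         lognormal = function(n) stats::rlnorm(n, meanlog = p$meanlog,
                                               sdlog = p$sdlog))
}

#' Draw a synthetic ligand cohort with known ground truth
#'
#' Emits ensemble records whose delta-E values are exact draws from the
#' spec's distribution. Each record's category is drawn first: with
#' probability `frac_below_min` the bound energy is placed below the
#' ensemble minimum (delta-E is a small negative exponential draw); with
#' probability `frac_above_cutoff` delta-E is the cutoff plus a draw (and
#' the ensemble maximum is kept below the bound energy, scenario
#' `above_max`); with probability `frac_single` the ensemble has a single
#' conformer; otherwise delta-E is an exact draw from the delta
#' distribution and the ensemble range is built to contain the bound
#' energy (scenario `within`). Absolute energies carry an arbitrary
#' per-ligand offset, which no downstream statistic may depend on.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (list of `"ensemble_record"`) and `truth`:
#'   the drawn within-category delta values (`within_draws`), all deltas
#'   (`deltas`), the category labels, and the distribution's theoretical
#'   `q1`/`median`/`q3`/`p90`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  qf <- delta_quantile_fun(spec)
  rf <- delta_draw_fun(spec)
  withr_seed(spec$rng_seed, {
    n <- spec$n_ligands
    u <- stats::runif(n)
    category <- ifelse(u < spec$frac_below_min, "below_min",
                ifelse(u < spec$frac_below_min + spec$frac_above_cutoff, "above_cutoff",
                ifelse(u < spec$frac_below_min + spec$frac_above_cutoff +
                         spec$frac_single, "single", "within")))
    # latent size variable feeds both the atom count and (through a
    # Gaussian copula) the strain draw, so bigger molecules strain more
    z_size <- stats::rnorm(n)
    atom_counts <- pmax(spec$atom_count_min,
                        round(spec$atom_count_mean +
                                spec$atom_count_sd * z_size))
    rho_sz <- spec$size_delta_correlation
    z_delta <- rho_sz * z_size + sqrt(1 - rho_sz^2) * stats::rnorm(n)
    charges <- ifelse(stats::runif(n) < spec$frac_charged,
                      sample(c(-1L, 1L), n, replace = TRUE), 0L)
    records <- vector("list", n)
    deltas <- numeric(n)
    for (i in seq_len(n)) {
      base <- stats::rnorm(1, 0, 50)
      # ensemble size: about half the ligands saturate the cap, the rest
      # spread uniformly (mirrors the reported 50%-at-cap / 95%-at->=5 shape)
      n_conf <- if (category[i] == "single") 1L
                else min(spec$max_conformers,
                         max(2L, ceiling(spec$max_conformers * 2 * stats::runif(1))))
      delta <- switch(category[i],
                      below_min = -stats::rexp(1, rate = 2),
                      above_cutoff = spec$cutoff + rf(1L),
                      single = qf(stats::pnorm(z_delta[i])),
                      within = qf(stats::pnorm(z_delta[i])))
      # store the realized delta (e_active - e_min as representable in
      # floating point) so downstream summaries reproduce it bit-exactly
      deltas[i] <- (base + delta) - base
      mp <- spec$member_rel_params
      rel <- if (n_conf == 1L) 0
             else switch(category[i],
        # scenario above_max needs every member below the bound energy
        above_cutoff = c(0, stats::runif(n_conf - 1L, 0, min(15, 0.8 * delta))),
        c(0, stats::rlnorm(n_conf - 1L, mp$meanlog, mp$sdlog)))
      # scenario `within` needs the ensemble range to contain e_active
      if (category[i] == "within" && max(rel) < delta)
        rel[n_conf] <- delta + abs(stats::rnorm(1, 1, 0.5))
      members <- base + rel
      records[[i]] <- ensemble_record(
        ligand_id = sprintf("SYN%05d", i),
        e_active = base + delta,
        member_energies = members,
        atom_count = atom_counts[i],
        net_charge = charges[i])
    }
    truth <- list(deltas = deltas,
                  within_draws = deltas[category == "within"],
                  category = category,
                  theoretical = list(q1 = qf(0.25), median = qf(0.5),
                                     q3 = qf(0.75), p90 = qf(0.9)),
                  rng_seed = spec$rng_seed)
    list(records = records, truth = truth)
  })
}

#' Perturbed-geometry fixture with a known minimum
#'
#' Builds a starting geometry for optimizer tests by displacing a known
#' minimum of the potential with i.i.d. Gaussian noise (sd `sigma` per
#' Cartesian component). Supported potentials: harmonic wells (matrix
#' center), Lennard-Jones dimers, and mock-ensemble wells (the nominal
#' global well; all well centers are returned too).
#'
#' @param potential A `pes_*` potential.
#' @param sigma Displacement scale in Angstrom.
#' @param rng_seed Integer seed.
#' @param shape For scalar-centered harmonic wells, the coordinate matrix
#'   dimensions as `c(n_atoms, 3)`.
#' @return List with `start`, `minimum` (matrices) and `wells` (list of
#'   all nominal minima).
#' @export
make_perturbed_geometry <- function(potential, sigma, rng_seed = 1L,
                                    shape = NULL) {
  wells <- if (inherits(potential, "pes_harmonic_well")) {
    ctr <- potential$center
    if (!is.matrix(ctr)) {
      if (is.null(shape)) err_shape("scalar-centered harmonic well needs `shape`")
      ctr <- matrix(ctr, shape[1L], shape[2L])
    }
    list(ctr)
  } else if (inherits(potential, "pes_lennard_jones")) {
    r <- 2^(1 / 6) * potential$sigma
    list(rbind(c(0, 0, 0), c(r, 0, 0)))
  } else if (inherits(potential, "pes_mock_ensemble")) {
    potential$centers[order(potential$well_depths)]
  } else err_shape("no constructible minimum for this potential kind")
  minimum <- wells[[1L]]
  start <- withr_seed(rng_seed,
                      minimum + matrix(stats::rnorm(length(minimum), 0, sigma),
                                       nrow(minimum), ncol(minimum)))
  list(start = start, minimum = minimum, wells = wells)
}

# ---- deterministic molecule fixture library ------------------------------

BOND_LENGTHS <- c(CC = 1.54, CH = 1.09, CO = 1.43, OH = 0.96, OC = 1.43,
                  HC = 1.09, HO = 0.96, CCl = 1.79, ClC = 1.79,
                  CF = 1.35, FC = 1.35, CBr = 1.94, BrC = 1.94,
                  CN = 1.47, NC = 1.47, NH = 1.01, HN = 1.01)

bond_length <- function(a, b) {
  key <- paste0(a, b)
  if (!is.na(BOND_LENGTHS[key])) unname(BOND_LENGTHS[key]) else 1.5
}

unit <- function(v) v / sqrt(sum(v * v))

# unit directions completing a tetrahedral centre that already has
# `existing` outgoing unit vectors (matrix, one row each)
tetra_complete <- function(existing, n_needed) {
  th <- 109.471 * pi / 180
  if (nrow(existing) == 0L) {
    dirs <- rbind(c(0, 0, 1),
                  c(2 * sqrt(2) / 3, 0, -1 / 3),
                  c(-sqrt(2) / 3, sqrt(2 / 3), -1 / 3),
                  c(-sqrt(2) / 3, -sqrt(2 / 3), -1 / 3))
    return(dirs[seq_len(n_needed), , drop = FALSE])
  }
  if (nrow(existing) == 1L) {
    u <- unit(existing[1L, ])
    ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit(ref - sum(ref * u) * u)
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    dirs <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
      cos(th) * u + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
    }, numeric(3)))
    return(dirs[seq_len(n_needed), , drop = FALSE])
  }
  if (nrow(existing) == 2L) {
    u <- unit(existing[1L, ]); v <- unit(existing[2L, ])
    b <- unit(-(u + v))
    nrm <- unit(c(u[2] * v[3] - u[3] * v[2],
                  u[3] * v[1] - u[1] * v[3],
                  u[1] * v[2] - u[2] * v[1]))
    half <- (th / 2)
    dirs <- rbind(cos(half) * b + sin(half) * nrm,
                  cos(half) * b - sin(half) * nrm)
    return(dirs[seq_len(n_needed), , drop = FALSE])
  }
  s <- colSums(existing)
  matrix(unit(-s), 1L)[seq_len(n_needed), , drop = FALSE]
}

# Build 3D coordinates for a (acyclic-or-aromatic-free) tetrahedral-ish
# molecule from its graph: heavy atoms are placed by BFS with tetrahedral
# completion, hydrogens last. Good enough for fixtures - geometry sanity,
# not physics.
embed_graph <- function(graph) {
  n <- length(graph$elements)
  adj <- adjacency(graph)
  coords <- matrix(NA_real_, n, 3L)
  placed <- logical(n)
  heavy_first <- order(graph$elements == "H", seq_len(n))
  root <- heavy_first[1L]
  coords[root, ] <- 0
  placed[root] <- TRUE
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    todo <- nb[!placed[nb]]
    todo <- todo[order(graph$elements[todo] == "H")]   # heavy before H
    if (!length(todo)) next
    have <- nb[placed[nb]]
    existing <- if (length(have))
      t(vapply(have, function(u) unit(coords[u, ] - coords[v, ]), numeric(3)))
    else matrix(numeric(0), 0L, 3L)
    dirs <- tetra_complete(existing, length(todo))
    for (k in seq_along(todo)) {
      u <- todo[k]
      coords[u, ] <- coords[v, ] +
        bond_length(graph$elements[v], graph$elements[u]) * dirs[k, ]
      placed[u] <- TRUE
      queue <- c(queue, u)
    }
  }
  coords
}

chain_bonds <- function(idx) cbind(idx[-length(idx)], idx[-1L])

# n-alkane graph: carbons 1..n then hydrogens
alkane_graph <- function(n_c, branches = NULL) {
  elements <- rep("C", n_c)
  bonds <- chain_bonds(seq_len(n_c))
  if (!is.null(branches)) {
    for (at in branches) {
      elements <- c(elements, "C")
      bonds <- rbind(bonds, c(at, length(elements)))
    }
  }
  n_heavy <- length(elements)
  deg <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = n_heavy)
  for (i in seq_len(n_heavy)) {
    for (h in seq_len(4L - deg[i])) {
      elements <- c(elements, "H")
      bonds <- rbind(bonds, c(i, length(elements)))
    }
  }
  mol_graph(elements, bonds)
}

ring6_graph <- function(substituent = NULL) {
  elements <- rep("C", 6L)
  bonds <- rbind(chain_bonds(1:6), c(6L, 1L))
  nH <- 6L
  if (!is.null(substituent)) {
    elements <- c(elements, substituent)
    bonds <- rbind(bonds, c(1L, 7L))
    nH <- 5L
  }
  at <- if (is.null(substituent)) 1:6 else 2:6
  for (i in at) {
    elements <- c(elements, "H")
    bonds <- rbind(bonds, c(i, length(elements)))
  }
  mol_graph(elements, bonds)
}

ring6_coords <- function(graph, sub_len = NULL) {
  n <- length(graph$elements)
  coords <- matrix(0, n, 3L)
  r <- 1.39 / (2 * sin(pi / 6))
  ang <- 2 * pi * (0:5) / 6
  coords[1:6, ] <- cbind(r * cos(ang), r * sin(ang), 0)
  k <- 7L
  if (!is.null(sub_len)) {
    coords[7L, ] <- cbind((r + sub_len) * cos(ang[1L]),
                          (r + sub_len) * sin(ang[1L]), 0)
    k <- 8L
  }
  at <- if (is.null(sub_len)) 1:6 else 2:6
  for (i in at) {
    coords[k, ] <- cbind((r + 1.09) * cos(ang[i]), (r + 1.09) * sin(ang[i]), 0)
    k <- k + 1L
  }
  coords
}

fixture_entry <- function(graph, coords = NULL, net_charge = 0L) {
  if (is.null(coords)) coords <- embed_graph(graph)
  list(graph = graph,
       conformation = conformation(graph$elements, coords,
                                   atom_names = paste0(graph$elements,
                                                       seq_along(graph$elements)),
                                   net_charge = net_charge, role = "bound"))
}

#' Deterministic molecule fixture library
#'
#' A small, fully programmatic library of molecular graphs with seed 3D
#' geometries, spanning the cases the pipeline must distinguish: rigid and
#' flexible molecules, CHON-only and CHONSFCl molecules, an element outside
#' both supported sets (bromobenzene), constitutional-isomer pairs
#' (ethanol / dimethyl ether; n-hexane / 2-methylpentane) and a chiral
#' center with both enantiomeric geometries. Geometries are idealized
#' tetrahedral embeddings - valid, clash-free 3D structures for exercising
#' the machinery, not physical minima.
#'
#' @return Named list; each entry holds `graph` (a [mol_graph()]) and
#'   `conformation` (its seed geometry).
#' @examples
#' fx <- make_molecule_fixtures()
#' names(fx)
#' @export
make_molecule_fixtures <- function() {
  out <- list()
  out$methane <- fixture_entry(alkane_graph(1L))
  out$water <- fixture_entry(
    mol_graph(c("O", "H", "H"), rbind(c(1L, 2L), c(1L, 3L))),
    rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2400, 0.9266, 0)))
  out$butane <- fixture_entry(alkane_graph(4L))
  out$hexane <- fixture_entry(alkane_graph(6L))
  out$methylpentane <- fixture_entry(alkane_graph(5L, branches = 2L))
  out$heptane <- fixture_entry(alkane_graph(7L))
  out$ethanol <- fixture_entry(
    mol_graph(c("C", "C", "O", rep("H", 6L)),
              rbind(c(1L, 2L), c(2L, 3L), c(1L, 4L), c(1L, 5L), c(1L, 6L),
                    c(2L, 7L), c(2L, 8L), c(3L, 9L))))
  out$dimethyl_ether <- fixture_entry(
    mol_graph(c("C", "O", "C", rep("H", 6L)),
              rbind(c(1L, 2L), c(2L, 3L), c(1L, 4L), c(1L, 5L), c(1L, 6L),
                    c(3L, 7L), c(3L, 8L), c(3L, 9L))))
  out$benzene <- fixture_entry(ring6_graph(), ring6_coords(ring6_graph()))
  out$chlorobenzene <- fixture_entry(ring6_graph("Cl"),
                                     ring6_coords(ring6_graph("Cl"), 1.79))
  out$bromobenzene <- fixture_entry(ring6_graph("Br"),
                                    ring6_coords(ring6_graph("Br"), 1.94))
  # 1-chloro-1-fluoroethane: chiral at C1 (H, F, Cl, CH3); both hands
  cfe_graph <- mol_graph(c("C", "C", "F", "Cl", rep("H", 4L)),
                         rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 5L),
                               c(2L, 6L), c(2L, 7L), c(2L, 8L)))
  cfe_coords <- embed_graph(cfe_graph)
  out$chlorofluoroethane_R <- fixture_entry(cfe_graph, cfe_coords)
  mirrored <- cfe_coords
  mirrored[, 3L] <- -mirrored[, 3L]
  out$chlorofluoroethane_S <- fixture_entry(cfe_graph, mirrored)
  out
}
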