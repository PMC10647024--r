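#' Conformer generator specification
#'
#' @param kind `"torsion_sampling"` (seeded random torsions about every
#'   rotatable bond; default), `"torsion_enumeration"` (regular torsion
#'   grid), or `"external_file"` (ingest a multi-record mol2/SDF produced
#'   by an external generator).
#' @param max_conformers Upper bound on ensemble size (default 200).
#' @param rng_seed Integer seed; generation is bit-reproducible for a
#'   fixed seed.
#' @param angle_step Grid step in degrees for `"torsion_enumeration"`.
#' @param path File path for `"external_file"`.
#' @param min_distance Clash cutoff in Angstrom: generated geometries with
#'   a shorter non-bonded contact are rejected.
#' @return A `"generator_spec"` list.
#' @export
generator_spec <- function(kind = c("torsion_sampling", "torsion_enumeration",
                                    "external_file"),
                           max_conformers = 200L, rng_seed = 1L,
                           angle_step = 120, path = NULL,
                           min_distance = 0.7) {
  kind <- match.arg(kind)
  stopifnot(max_conformers >= 1L, angle_step > 0, min_distance >= 0)
  if (kind == "external_file" && is.null(path))
    err_shape("external_file generation needs a path")
  structure(list(kind = kind, max_conformers = as.integer(max_conformers),
                 rng_seed = as.integer(rng_seed), angle_step = angle_step,
                 path = path, min_distance = min_distance,
                 stereo_preserved = TRUE),
            class = "generator_spec")
}

# Rodrigues rotation of points about the axis from `origin` along `axis`.
rotate_about_axis <- function(points, origin, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  p <- sweep(points, 2L, origin)
  kx <- cbind(k[2] * p[, 3] - k[3] * p[, 2],
              k[3] * p[, 1] - k[1] * p[, 3],
              k[1] * p[, 2] - k[2] * p[, 1])
  kdp <- as.numeric(p %*% k)
  rot <- p * cos(th) + kx * sin(th) + outer(kdp, k) * (1 - cos(th))
  sweep(rot, 2L, origin, "+")
}

apply_torsions <- function(graph, coords, rb, angles) {
  for (t in seq_len(nrow(rb))) {
    if (angles[t] == 0) next
    i <- rb[t, 1L]; j <- rb[t, 2L]
    sub <- bond_subtree(graph, i, j)
    sub <- setdiff(sub, j)
    if (!length(sub)) next
    coords[sub, ] <- rotate_about_axis(coords[sub, , drop = FALSE],
                                       coords[j, ], coords[j, ] - coords[i, ],
                                       angles[t])
  }
  coords
}

min_nonbonded_distance <- function(graph, coords) {
  n <- nrow(coords)
  if (n < 3L) return(Inf)
  d <- as.matrix(stats::dist(coords))
  bonded <- matrix(FALSE, n, n)
  bonded[graph$bonds] <- TRUE
  bonded[graph$bonds[, 2:1, drop = FALSE]] <- TRUE
  diag(d) <- Inf
  d[bonded] <- Inf
  min(d)
}

#' Generate a conformer ensemble
#'
#' Builds up to `spec$max_conformers` distinct conformations of one
#' molecule by driving its rotatable-bond torsions (random sampling or a
#' regular grid), starting from a seed geometry. Torsion driving rotates a
#' rigid subtree about the bond axis, which cannot alter connectivity or
#' chirality; stereo preservation is nevertheless verified against the
#' seed's signed-volume signature. Clashing geometries (non-bonded contact
#' below `spec$min_distance`) and exact duplicates are discarded. Rigid
#' molecules yield a single conformer (the seed geometry).
#'
#' @param graph A [mol_graph()].
#' @param seed_conf The seed [conformation()] (atom order must match
#'   `graph`).
#' @param spec A [generator_spec()].
#' @param ligand_id Identifier used in error reports.
#' @return List of [conformation()] objects with role `"generated"`.
#' @export
generate_ensemble <- function(graph, seed_conf, spec = generator_spec(),
                              ligand_id = "ligand") {
  stopifnot(inherits(graph, "mol_graph"), inherits(seed_conf, "conformation"))
  if (length(graph$elements) != n_atoms(seed_conf))
    err_generation(ligand_id, "graph and seed geometry have different atom counts")
  if (spec$kind == "external_file") {
    mols <- read_structure(spec$path)
    out <- lapply(mols, function(m) {
      m$conformation$role <- "generated"; m$conformation
    })
    if (!length(out)) err_generation(ligand_id, "external file holds no structures")
    return(out[seq_len(min(length(out), spec$max_conformers))])
  }
  rb <- rotatable_bonds(graph)
  sig0 <- stereo_signature(graph, seed_conf)
  base <- seed_conf$coords
  keep_conf <- function(coords) {
    cf <- set_coords(seed_conf, coords, role = "generated")
    if (min_nonbonded_distance(graph, coords) < spec$min_distance) return(NULL)
    if (!identical(stereo_signature(graph, cf), sig0)) return(NULL)
    cf
  }
  out <- list(keep_conf(base))
  if (is.null(out[[1L]]))
    out <- list(set_coords(seed_conf, base, role = "generated"))
  if (nrow(rb) == 0L) return(out)

  if (spec$kind == "torsion_enumeration") {
    n_steps <- max(1L, round(360 / spec$angle_step))
    grids <- rep(list(spec$angle_step * (seq_len(n_steps) - 1L)), nrow(rb))
    combos <- as.matrix(expand.grid(grids))
    for (r in seq_len(nrow(combos))) {
      if (length(out) >= spec$max_conformers) break
      if (all(combos[r, ] == 0)) next   # seed already present
      cf <- keep_conf(apply_torsions(graph, base, rb, combos[r, ]))
      if (!is.null(cf)) out[[length(out) + 1L]] <- cf
    }
  } else {
    target <- min(spec$max_conformers, 3L^nrow(rb))
    draws <- withr_seed(spec$rng_seed, {
      n_try <- 8L * target
      matrix(stats::runif(n_try * nrow(rb), 0, 360), ncol = nrow(rb))
    })
    for (r in seq_len(nrow(draws))) {
      if (length(out) >= target) break
      cf <- keep_conf(apply_torsions(graph, base, rb, draws[r, ]))
      if (!is.null(cf)) out[[length(out) + 1L]] <- cf
    }
  }
  # exact-duplicate removal (coordinates identical to 1e-6 A)
  keys <- vapply(out, function(cf) paste(round(cf$coords, 6L), collapse = ","), "")
  out <- out[!duplicated(keys)]
  out[seq_len(min(length(out), spec$max_conformers))]
}

#' Construct an ensemble record
#'
#' Collects the optimized energies of a ligand's bound conformation and its
#' generated ensemble into the bookkeeping record the distribution analysis
#' consumes. The global energy is the minimum optimized member energy (the
#' bound conformation is never a candidate); ties go to the first member in
#' generation order. The scenario classifies where the bound energy sits:
#' `below_min` (E_active < E_min), `within` (E_min <= E_active <= E_max,
#' boundaries inclusive) or `above_max`.
#'
#' @param ligand_id Ligand identifier.
#' @param bound A `"cgbs_fit"` for the bound conformation.
#' @param members List of `"cgbs_fit"` objects for the generated ensemble.
#' @param bound_graph,member_graphs Optional [mol_graph()]s; when both are
#'   given every member is identity-checked against the bound graph and a
#'   mismatch raises a molecule-mismatch error.
#' @param match_depth Path depth for the identity check.
#' @return An `"ensemble_record"`.
#' @export
build_record <- function(ligand_id, bound, members,
                         bound_graph = NULL, member_graphs = NULL,
                         match_depth = 8L) {
  stopifnot(inherits(bound, "cgbs_fit"), length(members) >= 1L)
  if (!is.null(bound_graph) && !is.null(member_graphs)) {
    for (k in seq_along(member_graphs)) {
      m <- same_molecule(bound_graph, member_graphs[[k]], depth = match_depth)
      if (!m$is_match) err_molecule_mismatch(ligand_id, m$reason)
    }
  }
  member_energies <- vapply(members, function(f) f$energy, 0)
  conf <- bound$final
  ensemble_record(
    ligand_id = ligand_id,
    e_active = bound$energy,
    member_energies = member_energies,
    atom_count = if (inherits(conf, "conformation")) n_atoms(conf) else nrow(conf),
    net_charge = if (inherits(conf, "conformation")) conf$net_charge else 0L,
    rmsd_bound = bound$rmsd_start_final,
    rmsd_members = vapply(members, function(f) f$rmsd_start_final, 0))
}

#' @rdname build_record
#' @param e_active Optimized energy of the bound conformation, kcal/mol.
#' @param member_energies Optimized ensemble energies, kcal/mol.
#' @param atom_count,net_charge Molecule size and net charge.
#' @param rmsd_bound,rmsd_members Optional pre/post-optimization RMSDs.
#' @export
ensemble_record <- function(ligand_id, e_active, member_energies,
                            atom_count, net_charge = 0L,
                            rmsd_bound = NA_real_, rmsd_members = NULL) {
  stopifnot(length(member_energies) >= 1L, is.finite(e_active),
            all(is.finite(member_energies)), atom_count >= 1L)
  e_min <- min(member_energies)
  e_max <- max(member_energies)
  scenario <- if (e_active < e_min) "below_min"
              else if (e_active <= e_max) "within"
              else "above_max"
  structure(list(ligand_id = as.character(ligand_id),
                 e_active = e_active,
                 member_energies = member_energies,
                 e_min = e_min, e_global = e_min, e_max = e_max,
                 n_conformers = length(member_energies),
                 scenario = scenario,
                 delta_e = e_active - e_min,
                 atom_count = as.integer(atom_count),
                 net_charge = as.integer(net_charge),
                 rmsd_bound = rmsd_bound,
                 rmsd_members = rmsd_members),
            class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("<ensemble_record> %s: %d conformers, E_active %.3f, E_global %.3f, dE %.3f kcal/mol (%s)\n",
              x$ligand_id, x$n_conformers, x$e_active, x$e_global,
              x$delta_e, x$scenario))
  invisible(x)
}

# flatten a list of records into the analysis data frame
records_df <- function(records) {
  stopifnot(length(records) >= 0L)
  do.call(rbind, lapply(records, function(r) {
    data.frame(ligand_id = r$ligand_id, e_active = r$e_active,
               e_min = r$e_min, e_global = r$e_global, e_max = r$e_max,
               n_conformers = r$n_conformers, scenario = r$scenario,
               delta_e = r$delta_e, atom_count = r$atom_count,
               net_charge = r$net_charge, rmsd_bound = r$rmsd_bound,
               stringsAsFactors = FALSE)
  }))
}
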