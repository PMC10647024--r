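#' Pipeline configuration
#'
#' Bundles everything one end-to-end analysis run needs: the ligand cohort,
#' an optional structure-entry table for best-resolution selection, the
#' potential (a `pes_*` object shared by all ligands, or a factory
#' `function(graph, conformation, seed)` building a per-ligand potential -
#' the default factory anchors a mock committee potential at each ligand's
#' seed geometry, with a second, twisted well for flexible molecules so
#' bound and global conformations can differ), optimizer settings,
#' generator spec, element filter, subset cutoff, pruning-threshold grid,
#' output directory, and the global seed from which all per-ligand seeds
#' are derived.
#'
#' @param ligands List of ligand entries `list(ligand_id=, graph=,
#'   conformation=)` (e.g. assembled from [make_molecule_fixtures()] or
#'   [read_structure()]). An entry may also carry a `reference`
#'   conformation - an idealized geometry that anchors the default mock
#'   potential, so the bound pose itself need not sit at a potential
#'   minimum.
#' @param entries Optional data frame for [select_best_resolution()]; rows
#'   with `ligand_id`s absent from `ligands` are ignored.
#' @param potential A `pes_*` object or factory function; `NULL` for the
#'   default mock-committee factory.
#' @param settings [cgbs_settings()].
#' @param generator [generator_spec()]; its `rng_seed` is re-derived per
#'   ligand from `global_seed`.
#' @param element_set `"CHON"` or `"CHONSFCl"`.
#' @param cutoff Subset window, kcal/mol.
#' @param thresholds Pruning-threshold grid, kcal/mol.
#' @param outdir Output directory (created if missing).
#' @param match_depth Path depth for the identity filter.
#' @param global_seed Integer master seed.
#' @return A `"run_config"` list.
#' @export
run_config <- function(ligands, entries = NULL, potential = NULL,
                       settings = cgbs_settings(),
                       generator = generator_spec(max_conformers = 20L),
                       element_set = "CHONSFCl", cutoff = 20,
                       thresholds = seq(0, 20, by = 0.5),
                       outdir = tempfile("confstrain_run_"),
                       match_depth = 8L, global_seed = 1L) {
  stopifnot(length(ligands) >= 1L, cutoff > 0, length(thresholds) >= 1L)
  structure(list(ligands = ligands, entries = entries, potential = potential,
                 settings = settings, generator = generator,
                 element_set = element_set, cutoff = cutoff,
                 thresholds = thresholds, outdir = outdir,
                 match_depth = as.integer(match_depth),
                 global_seed = as.integer(global_seed)),
            class = "run_config")
}

# Default per-ligand potential: committee of harmonic wells anchored at the
# seed geometry; flexible molecules get a second well at a 120-degree twist
# of their first rotatable bond whose depth is drawn from the ligand seed,
# so the global conformer is sometimes the twisted one.
default_mock_potential <- function(graph, conf, seed) {
  wells <- list(conf$coords)
  depths <- 0
  rb <- rotatable_bonds(graph)
  if (nrow(rb)) {
    twisted <- apply_torsions(graph, conf$coords, rb[1L, , drop = FALSE], 120)
    wells <- c(wells, list(twisted))
    depths <- c(depths, withr_seed(seed, stats::rnorm(1, 0, 2)))
  }
  pes_mock_ensemble(wells, k = 20, tau = 1, n_members = 5,
                    well_depths = depths, member_sd = 0.2, seed = seed)
}

new_stage <- function(name, kept, dropped_ids) {
  list(name = name, kept = kept, dropped = dropped_ids)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (s in x$stages)
    cat(sprintf("  %-18s %5d kept, %4d dropped\n", s$name, s$kept,
                length(s$dropped)))
  cat(sprintf("  subsets: %d / %d / %d (below-min / within window / above window)\n",
              x$subset_counts[["subset1"]], x$subset_counts[["subset2"]],
              x$subset_counts[["subset3"]]))
  invisible(x)
}

#' Run the full strain-energy analysis pipeline
#'
#' Executes the stages of the analysis workflow in order: best-resolution
#' deduplication (when an entry table is supplied), element filtering,
#' conformer-ensemble generation, geometry optimization of the bound
#' conformation and every ensemble member, molecule-identity filtering,
#' multiconformer filtering (single-conformer ligands are unusable for a
#' distribution), record construction, subset clustering, and the
#' distribution summaries. Per-ligand failures are logged and skipped,
#' never aborting the cohort. The run is resumable: ligands already in the
#' output ledger are not re-optimized. All randomness derives from
#' `config$global_seed`, so a rerun is byte-identical.
#'
#' @param config A [run_config()].
#' @return List with `report` (a `"filter_report"`), `records`, `subsets`
#'   (per-record labels), `summary` (subset-2 [summarize_deltas()]),
#'   `tradeoff` (threshold grid data frame), `bins` (atom-count bins),
#'   and the paths of the written artifacts (`ledger`, `report_json`,
#'   `summary_csv`, `cumulative_csv`, `tradeoff_csv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ligands <- config$ligands
  ids <- vapply(ligands, function(l) l$ligand_id, "")
  stages <- list()
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  # stage: dedup / best-resolution selection
  n_input <- length(ligands)
  if (!is.null(config$entries)) {
    sel <- select_best_resolution(config$entries)
    keep <- ids %in% sel$selected$ligand_id
    for (id in ids[!keep]) note("dedup: dropped %s (no X-ray entry selected)", id)
  } else {
    keep <- !duplicated(ids)
    for (id in ids[!keep]) note("dedup: dropped duplicate ligand_id %s", id)
  }
  stages$dedup <- new_stage("after_dedup", sum(keep), ids[!keep])
  ligands <- ligands[keep]; ids <- ids[keep]

  # stage: element filter
  keep <- vapply(ligands, function(l)
    filter_elements(l$graph, config$element_set), TRUE)
  for (id in ids[!keep]) note("element_filter: dropped %s (unsupported element)", id)
  stages$elements <- new_stage("element_supported", sum(keep), ids[!keep])
  ligands <- ligands[keep]; ids <- ids[keep]

  # resumability: records already in the ledger are reused
  ledger_path <- file.path(config$outdir, "ledger.jsonl")
  done <- list()
  if (file.exists(ledger_path)) {
    prev <- read_ledger(ledger_path)
    names(prev) <- vapply(prev, function(r) r$ligand_id, "")
    done <- prev
    note("resume: found %d finished ligands in ledger", length(done))
  }

  records <- list()
  mismatch_ids <- character(0)
  single_ids <- character(0)
  failed_ids <- character(0)
  n_opt <- 0L

  for (k in seq_along(ligands)) {
    lig <- ligands[[k]]
    if (!is.null(done[[lig$ligand_id]])) {
      records[[lig$ligand_id]] <- done[[lig$ligand_id]]
      next
    }
    seed_k <- (config$global_seed + 7919L * k) %% 2147483647L
    res <- tryCatch({
      gen <- config$generator
      gen$rng_seed <- seed_k
      members <- generate_ensemble(lig$graph, lig$conformation, gen,
                                   ligand_id = lig$ligand_id)
      # identity filter: every member must be the same molecule as the bound
      ok <- TRUE
      for (m in members) {
        if (n_atoms(m) != length(lig$graph$elements) ||
            !identical(sort(m$elements), sort(lig$graph$elements))) {
          ok <- FALSE; break
        }
      }
      if (ok && gen$kind == "external_file") {
        for (m in members) {
          mg <- attr(m, "graph")
          if (!is.null(mg) &&
              !same_molecule(lig$graph, mg, depth = config$match_depth)$is_match) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) {
        mismatch_ids <- c(mismatch_ids, lig$ligand_id)
        note("identity_filter: dropped %s", lig$ligand_id)
        NULL
      } else if (length(members) < 2L) {
        single_ids <- c(single_ids, lig$ligand_id)
        note("multiconformer_filter: dropped %s (single conformer)", lig$ligand_id)
        NULL
      } else {
        anchor <- if (!is.null(lig$reference)) lig$reference
                  else lig$conformation
        pot <- config$potential
        if (is.null(pot)) pot <- default_mock_potential(lig$graph, anchor, seed_k)
        else if (is.function(pot)) pot <- pot(lig$graph, anchor, seed_k)
        bound_fit <- cgbs_optimize(pot, lig$conformation, config$settings)
        member_fits <- lapply(members, function(m)
          cgbs_optimize(pot, m, config$settings))
        n_opt <- n_opt + 1L + length(member_fits)
        rec <- build_record(lig$ligand_id, bound_fit, member_fits)
        rec$net_charge <- lig$conformation$net_charge
        rec
      }
    }, confstrain_error = function(e) {
      failed_ids <<- c(failed_ids, lig$ligand_id)
      note("failure: %s skipped (%s)", lig$ligand_id, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) records[[lig$ligand_id]] <- res
  }

  identity_kept <- length(ids) - length(mismatch_ids) - length(failed_ids)
  stages$identity <- new_stage("identity_matched", identity_kept,
                               c(mismatch_ids, failed_ids))
  stages$multi <- new_stage("multiconformer", identity_kept - length(single_ids),
                            single_ids)

  records <- records[order(match(names(records), ids))]
  subsets <- vapply(records, function(r) assign_subset(r, config$cutoff), "")
  subset_counts <- c(subset1 = sum(subsets == "subset1"),
                     subset2 = sum(subsets == "subset2"),
                     subset3 = sum(subsets == "subset3"))
  report <- structure(list(
    n_input = n_input,
    stages = stages,
    subset_counts = subset_counts,
    n_optimizations = n_opt,
    log = log), class = "filter_report")

  # artifacts
  write_ledger(records, ledger_path)
  report_json <- file.path(config$outdir, "filter_report.json")
  stage_counts <- lapply(stages, function(s) s$kept)
  names(stage_counts) <- vapply(stages, function(s) s$name, "")
  stage_dropped <- lapply(stages, function(s) s$dropped)
  names(stage_dropped) <- names(stage_counts)
  jsonlite::write_json(list(n_input = n_input,
                            counts = c(list(input = n_input), stage_counts),
                            dropped = stage_dropped,
                            subset_counts = as.list(subset_counts),
                            log = log),
                       report_json, auto_unbox = TRUE, digits = NA)
  sub2 <- records[subsets == "subset2"]
  summary <- NULL
  tradeoff <- NULL
  bins <- NULL
  summary_csv <- file.path(config$outdir, "summary.csv")
  cumulative_csv <- file.path(config$outdir, "cumulative.csv")
  tradeoff_csv <- file.path(config$outdir, "tradeoff.csv")
  if (length(records) == 0L) err_empty_distribution()
  if (length(sub2)) {
    summary <- summarize_deltas(vapply(sub2, function(r) r$delta_e, 0))
    tradeoff <- threshold_tradeoff(sub2, config$thresholds)
    bins <- bin_by_atom_count(sub2)
    utils::write.csv(bins, summary_csv, row.names = FALSE)
    utils::write.csv(summary$cumulative, cumulative_csv, row.names = FALSE)
    utils::write.csv(tradeoff, tradeoff_csv, row.names = FALSE)
  }
  list(report = report, records = records, subsets = subsets,
       summary = summary, tradeoff = tradeoff, bins = bins,
       ledger = ledger_path, report_json = report_json,
       summary_csv = summary_csv, cumulative_csv = cumulative_csv,
       tradeoff_csv = tradeoff_csv)
}
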