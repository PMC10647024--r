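#' Select the best-resolution structure per ligand
#'
#' Crystallographic resolution is reported in Angstrom and numerically
#' smaller is better, so per ligand the X-ray entry with the smallest
#' resolution value is kept. Ligands seen only in non-X-ray entries (NMR,
#' EM, ...) carry no resolution and are dropped and reported. Resolution
#' ties break to the lexicographically smallest structure id.
#'
#' @param entries Data frame with columns `ligand_id`, `structure_id`,
#'   `resolution` (Angstrom, `NA` for non-X-ray) and `method`
#'   (`"xray"`, `"nmr"`, `"other"`).
#' @return List with `selected` (one row per retained ligand) and
#'   `dropped` (ligand ids with no X-ray entry).
#' @export
select_best_resolution <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("ligand_id", "structure_id", "resolution", "method") %in%
                  names(entries)))
  xr <- entries$method == "xray"
  if (any(xr & !is.finite(entries$resolution)))
    err_shape("X-ray entries must carry a positive resolution")
  if (any(!xr & is.finite(entries$resolution)))
    err_shape("non-X-ray entries must not carry a resolution")
  if (any(entries$resolution[xr] <= 0))
    err_shape("resolutions must be positive")
  x <- entries[xr, , drop = FALSE]
  x <- x[order(x$ligand_id, x$resolution, x$structure_id), , drop = FALSE]
  selected <- x[!duplicated(x$ligand_id), , drop = FALSE]
  rownames(selected) <- NULL
  dropped <- sort(setdiff(unique(entries$ligand_id), selected$ligand_id))
  list(selected = selected, dropped = dropped)
}

#' Element-set filter
#'
#' Whether every element of a molecule belongs to a supported element set:
#' `"CHON"` (the basic organic set) or `"CHONSFCl"` (the extended set that
#' additionally covers S, F and Cl).
#'
#' @param mol A [mol_graph()], [conformation()], or character vector of
#'   element symbols.
#' @param element_set `"CHON"` or `"CHONSFCl"`.
#' @return Logical scalar.
#' @export
filter_elements <- function(mol, element_set = c("CHONSFCl", "CHON")) {
  element_set <- match.arg(element_set)
  els <- if (is.character(mol)) mol else mol$elements
  allowed <- if (element_set == "CHON") c("C", "H", "O", "N")
             else c("C", "H", "O", "N", "S", "F", "Cl")
  all(els %in% allowed)
}

#' Cluster a record into the three strain-energy subsets
#'
#' Subset 1: the bound conformation beats the ensemble's global minimum
#' (delta-E < 0). Subset 2: 0 <= delta-E <= `cutoff` (the window analyzed
#' for the distribution statistics; the cutoff is inclusive). Subset 3:
#' delta-E above the cutoff.
#'
#' @param record An `"ensemble_record"`, or a numeric vector of delta-E
#'   values.
#' @param cutoff Window width in kcal/mol (default 20).
#' @return Character scalar/vector in `c("subset1", "subset2", "subset3")`.
#' @export
assign_subset <- function(record, cutoff = 20) {
  delta <- if (inherits(record, "ensemble_record")) record$delta_e
           else if (is.list(record) && !is.null(record$delta_e)) record$delta_e
           else as.numeric(record)
  ifelse(delta < 0, "subset1",
         ifelse(delta <= cutoff, "subset2", "subset3"))
}

#' Summarize a strain-energy distribution
#'
#' Quartiles and the 90th percentile use linear interpolation between order
#' statistics (R's default quantile type 7); the cumulative curve is the
#' empirical distribution over the sorted values.
#'
#' @param deltas Numeric vector of delta-E values, kcal/mol (n >= 1).
#' @return A `"delta_summary"`: `n`, `q1`, `median`, `q3`, `p90`, `mean`,
#'   `sd`, and `cumulative` (data frame of sorted `delta_e` and
#'   `fraction` <= delta-E, ending at 1).
#' @examples
#' summarize_deltas(c(0:10))
#' @export
summarize_deltas <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (!length(deltas)) err_empty_distribution()
  stopifnot(all(is.finite(deltas)))
  qs <- stats::quantile(deltas, c(0.25, 0.5, 0.75, 0.9), type = 7, names = FALSE)
  s <- sort(deltas)
  structure(list(n = length(deltas),
                 q1 = qs[1L], median = qs[2L], q3 = qs[3L], p90 = qs[4L],
                 mean = mean(deltas), sd = stats::sd(deltas),
                 cumulative = data.frame(delta_e = s,
                                         fraction = seq_along(s) / length(s))),
            class = "delta_summary")
}

#' @export
print.delta_summary <- function(x, ...) {
  cat(sprintf("<delta_summary> n = %d\n", x$n))
  cat(sprintf("  q1 %.3f | median %.3f | q3 %.3f | p90 %.3f kcal/mol\n",
              x$q1, x$median, x$q3, x$p90))
  cat(sprintf("  mean %.3f +/- %.3f kcal/mol\n", x$mean,
              ifelse(is.na(x$sd), 0, x$sd)))
  invisible(x)
}

#' @export
plot.delta_summary <- function(x, ...) {
  graphics::plot(x$cumulative$delta_e, 100 * x$cumulative$fraction, type = "s",
                 xlab = expression(Delta * E ~ "(kcal/mol)"),
                 ylab = "cumulative % of ligands", ...)
  graphics::abline(h = c(50, 90), lty = 3)
  invisible(x)
}

#' Pruning-threshold trade-off
#'
#' For an energy cutoff T applied to conformer ensembles: the fraction of
#' all ensemble conformers whose energy lies more than T above their
#' ensemble's global minimum (these would be discarded from a conformer
#' library), against the fraction of bound conformations that would be
#' lost because their own delta-E exceeds T.
#'
#' @param records List of `"ensemble_record"` objects (typically subset 2).
#' @param thresholds Numeric vector of cutoffs T, kcal/mol.
#' @return Data frame with columns `threshold`,
#'   `frac_conformers_removed`, `frac_bound_lost`.
#' @export
threshold_tradeoff <- function(records, thresholds) {
  stopifnot(length(records) >= 1L, length(thresholds) >= 1L)
  rel <- lapply(records, function(r) r$member_energies - r$e_global)
  all_rel <- unlist(rel)
  n_conf <- length(all_rel)
  deltas <- vapply(records, function(r) r$delta_e, 0)
  out <- data.frame(
    threshold = thresholds,
    frac_conformers_removed = vapply(thresholds,
                                     function(T) sum(all_rel > T) / n_conf, 0),
    frac_bound_lost = vapply(thresholds,
                             function(T) sum(deltas > T) / length(deltas), 0))
  rownames(out) <- NULL
  out
}

ATOM_COUNT_BREAKS <- c(1, 30, 40, 50, 60, 70, Inf)
ATOM_COUNT_LABELS <- c("<30", "30-40", "40-50", "50-60", "60-70", ">70")

#' Strain-energy statistics binned by molecule size
#'
#' Partitions records into six half-open atom-count bins, [1,30), [30,40),
#' [40,50), [50,60), [60,70) and [70, Inf), and summarizes delta-E within
#' each.
#'
#' @param records List of `"ensemble_record"` objects.
#' @return Data frame with one row per non-empty bin: `bin`, `count`,
#'   `q1`, `median`, `q3`, `p90`, `mean`, `sd`.
#' @export
bin_by_atom_count <- function(records) {
  stopifnot(length(records) >= 1L)
  df <- records_df(records)
  bin <- cut(df$atom_count, breaks = ATOM_COUNT_BREAKS,
             labels = ATOM_COUNT_LABELS, right = FALSE,
             include.lowest = FALSE)
  out <- lapply(levels(bin), function(b) {
    d <- df$delta_e[!is.na(bin) & bin == b]
    if (!length(d)) return(NULL)
    s <- summarize_deltas(d)
    data.frame(bin = b, count = s$n, q1 = s$q1, median = s$median,
               q3 = s$q3, p90 = s$p90, mean = s$mean, sd = s$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-molecule benchmark metrics against a reference method
#'
#' Compares two methods' conformer energies molecule by molecule on the
#' relative-energy scale: each method's energies minus that method's value
#' on the conformer where the *reference* method is lowest, so a
#' per-molecule constant offset between methods cancels. R-squared is the
#' coefficient of determination about the identity line (1 - SS_res/SS_tot
#' of the test relative energies treated as predictions of the reference
#' ones), which can go negative; molecules with negative R-squared are
#' excluded from the aggregates and counted, as are molecules whose
#' relative energies are degenerate (zero variance, correlations
#' undefined). RMSE is between the two relative-energy vectors; Spearman's
#' rho is rank-based.
#'
#' @param reference Named list of numeric vectors: per-molecule conformer
#'   energies of the reference method (kcal/mol, >= 2 conformers each).
#' @param test Matching list for the test method (same molecules, same
#'   conformer order).
#' @param rmsd Optional numeric vector, one geometry RMSD per molecule, to
#'   aggregate alongside the energy metrics.
#' @param net_charge Optional integer vector of per-molecule net charges;
#'   when present the aggregates are also reported stratified into neutral
#'   (charge 0) and charged groups.
#' @return A `"benchmark_metrics"` object: `per_molecule` data frame,
#'   `aggregate` data frame (mean/median/sd per metric over retained
#'   molecules), `n_omitted_negative_r2`, `n_excluded_degenerate`, and
#'   optionally `by_charge`.
#' @export
benchmark_metrics <- function(reference, test, rmsd = NULL, net_charge = NULL) {
  stopifnot(is.list(reference), is.list(test),
            length(reference) == length(test), length(reference) >= 1L)
  ids <- names(reference)
  if (is.null(ids)) ids <- as.character(seq_along(reference))
  rows <- lapply(seq_along(reference), function(k) {
    r_abs <- as.numeric(reference[[k]])
    t_abs <- as.numeric(test[[k]])
    if (length(r_abs) != length(t_abs))
      err_shape(sprintf("molecule '%s': conformer counts differ", ids[k]))
    if (length(r_abs) < 2L)
      err_shape(sprintf("molecule '%s': correlations need >= 2 conformers", ids[k]))
    i0 <- which.min(r_abs)
    r <- r_abs - r_abs[i0]
    t <- t_abs - t_abs[i0]
    ss_tot <- sum((r - mean(r))^2)
    reason <- NA_character_
    if (ss_tot == 0) {
      r2 <- NA_real_; rho <- NA_real_
      reason <- "zero-variance reference energies"
    } else {
      r2 <- 1 - sum((t - r)^2) / ss_tot
      rho <- suppressWarnings(stats::cor(r, t, method = "spearman"))
      if (is.na(rho)) reason <- "zero-variance test energies"
    }
    data.frame(molecule = ids[k], r2 = r2, spearman_rho = rho,
               rmse_kcal = sqrt(mean((t - r)^2)),
               rmsd_ang = if (is.null(rmsd)) NA_real_ else rmsd[k],
               net_charge = if (is.null(net_charge)) NA_integer_
                            else as.integer(net_charge[k]),
               excluded_reason = reason, stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, rows)
  pm$retained <- is.na(pm$excluded_reason) & pm$r2 >= 0
  pm$excluded_reason[is.na(pm$excluded_reason) & pm$r2 < 0] <- "negative R2"

  agg <- function(d) {
    metrics <- c("r2", "spearman_rho", "rmse_kcal", "rmsd_ang")
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]][d$retained]
      v <- v[!is.na(v)]
      data.frame(metric = m, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(per_molecule = pm, aggregate = agg(pm),
              n_omitted_negative_r2 = sum(pm$excluded_reason == "negative R2",
                                          na.rm = TRUE),
              n_excluded_degenerate = sum(!is.na(pm$excluded_reason) &
                                            pm$excluded_reason != "negative R2"))
  if (!is.null(net_charge)) {
    out$by_charge <- list(neutral = agg(pm[pm$net_charge == 0L, , drop = FALSE]),
                          charged = agg(pm[pm$net_charge != 0L, , drop = FALSE]))
  }
  structure(out, class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat(sprintf("<benchmark_metrics> %d molecules, %d omitted (negative R2), %d degenerate\n",
              nrow(x$per_molecule), x$n_omitted_negative_r2,
              x$n_excluded_degenerate))
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}
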