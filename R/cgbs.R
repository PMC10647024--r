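#' Optimizer settings for conjugate-gradient backtracking line search
#'
#' The convergence quartet (maximum force, RMS force, maximum displacement,
#' RMS displacement, all in atomic units) defaults to the Gaussian geometry
#' optimization defaults; the iteration cap defaults to 10,000 so rough
#' machine-learned surfaces still converge. Internally the package works in
#' kcal/mol and Angstrom - the atomic-unit conversion happens only inside
#' [check_convergence()].
#'
#' @param max_force_au Largest allowed Cartesian gradient component,
#'   Hartree/Bohr.
#' @param rms_force_au Allowed RMS over all 3N gradient components,
#'   Hartree/Bohr.
#' @param max_disp_au Largest allowed per-component step, Bohr.
#' @param rms_disp_au Allowed RMS step over all 3N components, Bohr.
#' @param max_iterations Iteration cap.
#' @param armijo_c1 Sufficient-decrease constant of the line search.
#' @param curvature_c2 Wolfe curvature constant; a violated curvature check
#'   accepts the step but schedules a steepest-descent restart.
#' @param backtrack_factor Step-shrink factor of the backtracking search,
#'   in (0,1).
#' @param initial_step First trial step (internal units); later iterations
#'   warm-start from the previous accepted step, doubled and capped at
#'   `max_step`.
#' @param max_step Cap on the warm-started trial step.
#' @param restart_interval Steepest-descent restart period; `NULL` means
#'   the number of degrees of freedom (3N).
#' @param min_step Smallest trial step before the line search gives up
#'   (termination reason `"line_search_failure"`).
#' @return A `"cgbs_settings"` list.
#' @export
cgbs_settings <- function(max_force_au = 0.00045, rms_force_au = 0.00030,
                          max_disp_au = 0.0018, rms_disp_au = 0.0012,
                          max_iterations = 10000L,
                          armijo_c1 = 1e-4, curvature_c2 = 0.9,
                          backtrack_factor = 0.5,
                          initial_step = 1.0, max_step = 4.0,
                          restart_interval = NULL, min_step = 1e-12) {
  stopifnot(max_force_au > 0, rms_force_au > 0, max_disp_au > 0, rms_disp_au > 0,
            max_iterations >= 1, armijo_c1 > 0, armijo_c1 < curvature_c2,
            curvature_c2 < 1, backtrack_factor > 0, backtrack_factor < 1,
            initial_step > 0, max_step >= initial_step, min_step > 0,
            is.null(restart_interval) || restart_interval >= 1)
  structure(list(max_force_au = max_force_au, rms_force_au = rms_force_au,
                 max_disp_au = max_disp_au, rms_disp_au = rms_disp_au,
                 max_iterations = as.integer(max_iterations),
                 armijo_c1 = armijo_c1, curvature_c2 = curvature_c2,
                 backtrack_factor = backtrack_factor,
                 initial_step = initial_step, max_step = max_step,
                 restart_interval = restart_interval, min_step = min_step),
            class = "cgbs_settings")
}

#' Convergence quartet test
#'
#' Converts the Cartesian gradient (kcal/mol/Angstrom) and the last step
#' (Angstrom) to atomic units (1 Hartree = 627.509474 kcal/mol, 1 Bohr =
#' 0.529177210903 Angstrom) and applies the four Gaussian-style criteria:
#' maximum and RMS force, maximum and RMS displacement. "Maximum" is the
#' largest per-component magnitude; RMS runs over all 3N components. All
#' comparisons are inclusive (<=).
#'
#' @param force Gradient, kcal/mol/Angstrom (matrix or vector).
#' @param displacement Last geometry step, Angstrom (same shape).
#' @param settings A [cgbs_settings()] object.
#' @return List with the four logical flags (`max_force`, `rms_force`,
#'   `max_disp`, `rms_disp`), `converged` (all four), and `values` - the
#'   four measured quantities in atomic units.
#' @export
check_convergence <- function(force, displacement, settings = cgbs_settings()) {
  f <- as.numeric(force); d <- as.numeric(displacement)
  if (length(f) != length(d)) err_shape("force and displacement shapes differ")
  f_au <- force_kcal_to_au(f)
  d_au <- length_ang_to_au(d)
  vals <- c(max_force = max(abs(f_au)),
            rms_force = sqrt(mean(f_au^2)),
            max_disp = max(abs(d_au)),
            rms_disp = sqrt(mean(d_au^2)))
  flags <- list(max_force = vals[["max_force"]] <= settings$max_force_au,
                rms_force = vals[["rms_force"]] <= settings$rms_force_au,
                max_disp  = vals[["max_disp"]]  <= settings$max_disp_au,
                rms_disp  = vals[["rms_disp"]]  <= settings$rms_disp_au)
  flags$converged <- all(unlist(flags))
  flags$values <- vals
  flags
}

#' Conjugate-gradient geometry optimization with backtracking line search
#'
#' Minimizes a potential-energy surface from a starting geometry using
#' Polak-Ribiere+ conjugate gradients. The step length is found by
#' backtracking from a warm-started trial step until the Armijo
#' sufficient-decrease condition holds; the Wolfe curvature condition is
#' checked on the accepted step and, when violated, a steepest-descent
#' restart is scheduled. The search direction is also reset whenever it is
#' not a descent direction or every `restart_interval` iterations.
#' Optimization stops when the four convergence criteria of
#' [check_convergence()] hold simultaneously, at the iteration cap, or when
#' the line search cannot find a decreasing step above `min_step`.
#'
#' @param potential A `pes_*` potential.
#' @param start A [conformation()] or bare numeric coordinates.
#' @param settings A [cgbs_settings()] object.
#' @return A `"cgbs_fit"` with `start`, `final` (same class as `start`,
#'   conformations retagged role `"optimized"`), `energy` (final, kcal/mol),
#'   `converged`, `termination_reason`, `rmsd_start_final` (Angstrom;
#'   optimal superposition for conformations, plain RMSD for bare
#'   coordinates), the final `"pes_result"` in `last_eval`, and a per-
#'   iteration `trace` data frame (columns iter, energy_kcal, max_force_au,
#'   rms_force_au, max_disp_au, rms_disp_au, step, n_evals).
#' @examples
#' fit <- cgbs_optimize(pes_harmonic(k = 1), matrix(c(1, 0, 0), 1))
#' fit$converged
#' @export
cgbs_optimize <- function(potential, start, settings = cgbs_settings()) {
  stopifnot(inherits(settings, "cgbs_settings"))
  is_conf <- inherits(start, "conformation")
  x <- if (is_conf) start$coords else {
    if (is.matrix(start)) start else matrix(start, nrow = 1L)
  }
  eval_at <- function(coords) {
    if (is_conf) pes_evaluate(potential, set_coords(start, coords))
    else pes_evaluate(potential, coords)
  }
  restart_interval <- if (is.null(settings$restart_interval)) length(x)
                      else settings$restart_interval

  res <- eval_at(x); n_evals_total <- 1L
  g <- res$gradient; dim(g) <- dim(x)
  e <- res$energy
  d <- -g
  alpha_try <- settings$initial_step
  since_restart <- 0L
  restart_pending <- FALSE

  tr <- vector("list", 64L); tr_n <- 0L
  push_trace <- function(iter, energy, vals, step, nev) {
    tr_n <<- tr_n + 1L
    if (tr_n > length(tr)) tr[length(tr) * 2L] <<- list(NULL)
    names(vals) <- paste0(names(vals), "_au")
    tr[[tr_n]] <<- c(iter = iter, energy_kcal = energy, vals,
                     step = step, n_evals = nev)
  }

  converged <- FALSE
  reason <- "max_iterations"
  iter <- 0L
  while (iter < settings$max_iterations) {
    iter <- iter + 1L
    # restart to steepest descent when scheduled or direction is uphill
    gd <- sum(g * d)
    if (restart_pending || since_restart >= restart_interval || gd >= 0) {
      d <- -g
      gd <- sum(g * d)
      since_restart <- 0L
      restart_pending <- FALSE
    }
    if (max(abs(g)) == 0) {
      # already at a stationary point: zero displacement, force flags decide
      cc <- check_convergence(g, 0 * g, settings)
      push_trace(iter, e, cc$values, 0, 0L)
      converged <- cc$converged
      reason <- if (converged) "converged" else "line_search_failure"
      break
    }
    # backtracking line search on the Armijo condition
    alpha <- alpha_try
    nev <- 0L
    accepted <- FALSE
    while (alpha >= settings$min_step) {
      x_new <- x + alpha * d
      res_new <- tryCatch(eval_at(x_new), confstrain_evaluation_error = function(e) NULL)
      nev <- nev + 1L
      if (!is.null(res_new) &&
          res_new$energy <= e + settings$armijo_c1 * alpha * gd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * settings$backtrack_factor
    }
    n_evals_total <- n_evals_total + nev
    if (!accepted) {
      reason <- "line_search_failure"
      cc <- check_convergence(g, 0 * g, settings)
      push_trace(iter, e, cc$values, 0, nev)
      converged <- FALSE
      break
    }
    g_new <- res_new$gradient; dim(g_new) <- dim(x)
    # Wolfe curvature check on the accepted step; violation schedules restart
    if (sum(g_new * d) < settings$curvature_c2 * gd) restart_pending <- TRUE
    step_vec <- alpha * d
    cc <- check_convergence(g_new, step_vec, settings)
    push_trace(iter, res_new$energy, cc$values, alpha, nev)
    # Polak-Ribiere+ update
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    d <- -g_new + beta * d
    x <- x_new; e <- res_new$energy; g <- g_new; res <- res_new
    since_restart <- since_restart + 1L
    alpha_try <- min(2 * alpha, settings$max_step)
    if (cc$converged) {
      converged <- TRUE
      reason <- "converged"
      break
    }
  }

  trace <- as.data.frame(do.call(rbind, tr[seq_len(tr_n)]))
  final <- if (is_conf) set_coords(start, x, role = "optimized") else x
  rmsd <- if (is_conf) kabsch_rmsd(start, final)
          else sqrt(mean((as.numeric(final) - as.numeric(
            if (is.matrix(start)) start else matrix(start, nrow = 1L)))^2))
  structure(list(start = start, final = final, energy = e,
                 converged = converged, termination_reason = reason,
                 trace = trace, last_eval = res,
                 n_iterations = iter, n_evaluations = n_evals_total,
                 rmsd_start_final = rmsd, settings = settings),
            class = "cgbs_fit")
}

#' @export
print.cgbs_fit <- function(x, ...) {
  cat(sprintf("<cgbs_fit> %s after %d iterations (%d energy evaluations)\n",
              x$termination_reason, x$n_iterations, x$n_evaluations))
  cat(sprintf("  E: %.6f -> %.6f kcal/mol, displacement RMSD %.4f A\n",
              x$trace$energy_kcal[[1L]], x$energy, x$rmsd_start_final))
  invisible(x)
}

#' @export
summary.cgbs_fit <- function(object, ...) {
  last <- object$trace[nrow(object$trace), ]
  cat(sprintf("Conjugate-gradient backtracking line-search fit: %s\n",
              object$termination_reason))
  cat(sprintf("  iterations: %d, energy evaluations: %d\n",
              object$n_iterations, object$n_evaluations))
  cat(sprintf("  final energy: %.6f kcal/mol (drop %.6f)\n", object$energy,
              object$trace$energy_kcal[[1L]] - object$energy))
  cat(sprintf("  final max|F| %.2e au (<= %.2e), RMS F %.2e au (<= %.2e)\n",
              last$max_force_au, object$settings$max_force_au,
              last$rms_force_au, object$settings$rms_force_au))
  cat(sprintf("  final max disp %.2e au (<= %.2e), RMS disp %.2e au (<= %.2e)\n",
              last$max_disp_au, object$settings$max_disp_au,
              last$rms_disp_au, object$settings$rms_disp_au))
  cat(sprintf("  start/final RMSD: %.4f A\n", object$rmsd_start_final))
  invisible(object)
}

#' @export
plot.cgbs_fit <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iter, tr$energy_kcal, type = "l", xlab = "iteration",
                 ylab = "energy (kcal/mol)", main = "energy descent", ...)
  graphics::matplot(tr$iter, cbind(tr$max_force_au, tr$rms_force_au),
                    type = "l", log = "y", lty = 1:2, col = c(1, 2),
                    xlab = "iteration", ylab = "force (au)",
                    main = "force convergence")
  graphics::abline(h = c(x$settings$max_force_au, x$settings$rms_force_au),
                   lty = 3, col = c(1, 2))
  invisible(x)
}
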