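#' Potential-energy surfaces
#'
#' All energy models used by the optimizer and the ensemble analysis share
#' one contract: [pes_evaluate()] takes a potential and a geometry and
#' returns energy (kcal/mol) plus the analytic gradient (kcal/mol/Angstrom),
#' and, for committee potentials, the per-member energies. Analytic surfaces
#' (harmonic well, Lennard-Jones, 2D Rosenbrock) exercise the optimizer
#' against known minima; `pes_mock_ensemble()` emulates an
#' ensemble-of-models molecular potential (smooth multi-well surface with
#' committee spread) without requiring any trained model;
#' `pes_forcefield()` and `pes_ml_ensemble()` are adapter contracts around
#' user-supplied calculators.
#'
#' @name potentials
NULL

new_pes <- function(kind, params, supported_elements = NULL) {
  structure(c(list(kind = kind, supported_elements = supported_elements), params),
            class = c(paste0("pes_", kind), "pes"))
}

#' @export
print.pes <- function(x, ...) {
  el <- if (is.null(x$supported_elements)) "any"
        else paste(x$supported_elements, collapse = ",")
  cat(sprintf("<pes> kind '%s', elements: %s\n", x$kind, el))
  invisible(x)
}

#' @rdname potentials
#' @param k Force constant, kcal/mol/Angstrom^2 (scalar or one per coordinate).
#' @param center Well center: scalar (broadcast), vector, or N x 3 matrix.
#' @export
pes_harmonic <- function(k = 1, center = 0) {
  stopifnot(all(k > 0))
  new_pes("harmonic_well", list(k = k, center = center))
}

#' @rdname potentials
#' @param epsilon,sigma Lennard-Jones well depth (kcal/mol) and zero-crossing
#'   distance (Angstrom).
#' @export
pes_lennard_jones <- function(epsilon = 1, sigma = 1) {
  stopifnot(epsilon > 0, sigma > 0)
  new_pes("lennard_jones", list(epsilon = epsilon, sigma = sigma))
}

#' @rdname potentials
#' @param a,b Rosenbrock parameters; the global minimum sits at (a, a^2).
#' @export
pes_rosenbrock <- function(a = 1, b = 100) {
  new_pes("rosenbrock2d", list(a = a, b = b))
}

#' @rdname potentials
#' @param centers A single N x 3 matrix (one well) or a list of N x 3
#'   matrices (several wells combined by a smooth soft-minimum).
#' @param tau Soft-minimum temperature in kcal/mol; small values approach a
#'   hard minimum over wells.
#' @param n_members Committee size.
#' @param member_offsets Optional numeric vector of per-member constant
#'   energy shifts (kcal/mol); defaults to seeded normal draws of sd
#'   `member_sd`.
#' @param member_sd Spread of the default member offsets, kcal/mol.
#' @param well_depths Optional per-well depth offsets (kcal/mol), default 0.
#' @param supported_elements Chemical symbols accepted by the potential.
#' @param seed Integer seed for the default member offsets.
#' @export
pes_mock_ensemble <- function(centers, k = 50, tau = 1, n_members = 5,
                              member_offsets = NULL, member_sd = 0.3,
                              well_depths = NULL,
                              supported_elements = c("C", "H", "N", "O", "S", "F", "Cl"),
                              seed = 1L) {
  if (!is.list(centers)) centers <- list(as.matrix(centers))
  centers <- lapply(centers, as.matrix)
  if (is.null(well_depths)) well_depths <- numeric(length(centers))
  stopifnot(length(well_depths) == length(centers), k > 0, tau > 0, n_members >= 1)
  if (is.null(member_offsets)) {
    member_offsets <- withr_seed(seed, stats::rnorm(n_members, 0, member_sd))
  }
  stopifnot(length(member_offsets) == n_members)
  if (length(supported_elements) < 1L)
    err_shape("supported_elements must be non-empty for molecular potentials")
  new_pes("mock_ensemble",
          list(centers = centers, k = k, tau = tau,
               member_offsets = member_offsets, well_depths = well_depths),
          supported_elements = supported_elements)
}

# evaluate an expression under a local RNG seed without touching the
# caller's RNG stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @rdname potentials
#' @param calculator Function `(elements, coords) -> list(energy, gradient)`
#'   (gradient optional; when absent it is taken by central finite
#'   differences of the calculator energy, step `fd_step`). For a classical
#'   force field, see [obenergy_calculator()].
#' @param fd_step Finite-difference step in Angstrom for energy-only
#'   calculators.
#' @export
pes_forcefield <- function(calculator,
                           supported_elements = names(ELEMENT_MASSES),
                           fd_step = 1e-4) {
  stopifnot(is.function(calculator))
  if (length(supported_elements) < 1L)
    err_shape("supported_elements must be non-empty for molecular potentials")
  new_pes("forcefield_adapter",
          list(calculator = calculator, fd_step = fd_step),
          supported_elements = supported_elements)
}

#' @rdname potentials
#' @param calculators List of >= 2 member calculators, each
#'   `(elements, coords) -> list(energy, gradient)`; committee energy is
#'   their arithmetic mean.
#' @export
pes_ml_ensemble <- function(calculators,
                            supported_elements = c("C", "H", "N", "O", "S", "F", "Cl")) {
  stopifnot(is.list(calculators), length(calculators) >= 1L,
            all(vapply(calculators, is.function, TRUE)))
  if (length(supported_elements) < 1L)
    err_shape("supported_elements must be non-empty for molecular potentials")
  new_pes("ml_ensemble_adapter", list(calculators = calculators),
          supported_elements = supported_elements)
}

#' Classical force-field calculator via Open Babel
#'
#' Convenience calculator for [pes_forcefield()] that shells out to the
#' `obenergy` command-line tool for single-point energies (the gradient is
#' then taken by finite differences inside the adapter). Requires Open
#' Babel on the PATH; intended for interactive use, not for tight
#' optimization loops.
#'
#' @param forcefield Force-field name understood by obenergy
#'   (e.g. "MMFF94", "UFF", "GAFF").
#' @return A calculator function.
#' @export
obenergy_calculator <- function(forcefield = "MMFF94") {
  if (Sys.which("obenergy") == "")
    err_evaluation("obenergy not found on PATH; supply your own calculator")
  function(elements, coords) {
    tmp <- tempfile(fileext = ".xyz")
    on.exit(unlink(tmp))
    writeLines(c(length(elements), "confstrain",
                 sprintf("%s %.8f %.8f %.8f", elements,
                         coords[, 1L], coords[, 2L], coords[, 3L])), tmp)
    out <- suppressWarnings(system2("obenergy", c("-ff", forcefield, tmp),
                                    stdout = TRUE, stderr = FALSE))
    ln <- grep("TOTAL ENERGY", out, value = TRUE)
    if (!length(ln)) err_evaluation("obenergy produced no energy")
    list(energy = as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", ln[[1L]])))
  }
}

pes_result <- function(energy, gradient, member_energies = NULL) {
  if (!is.finite(energy)) err_evaluation("potential returned a non-finite energy")
  if (!all(is.finite(gradient))) err_evaluation("potential returned a non-finite gradient")
  if (!is.null(member_energies)) {
    stopifnot(abs(energy - mean(member_energies)) <= 1e-8)
  }
  structure(list(energy = energy, gradient = gradient,
                 member_energies = member_energies),
            class = "pes_result")
}

#' @export
print.pes_result <- function(x, ...) {
  cat(sprintf("<pes_result> E = %.6f kcal/mol, |grad|max = %.3e kcal/mol/A%s\n",
              x$energy, max(abs(x$gradient)),
              if (is.null(x$member_energies)) ""
              else sprintf(", %d member energies", length(x$member_energies))))
  invisible(x)
}

# Accept a conformation or bare coordinates; returns list(coords, conf?)
resolve_geometry <- function(x) {
  if (inherits(x, "conformation")) list(coords = x$coords, conf = x)
  else if (is.numeric(x)) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
    list(coords = m, conf = NULL)
  } else err_shape("geometry must be a conformation or a numeric matrix/vector")
}

check_elements <- function(potential, conf) {
  if (is.null(conf) || is.null(potential$supported_elements)) return(invisible())
  bad <- setdiff(unique(conf$elements), potential$supported_elements)
  if (length(bad)) err_unsupported_element(bad)
  invisible()
}

#' Evaluate a potential on a geometry
#'
#' @param potential A potential created by one of the `pes_*()` constructors.
#' @param x A [conformation()] or, for analytic surfaces, a bare numeric
#'   vector/matrix of coordinates in Angstrom.
#' @return A `"pes_result"` with `energy` (kcal/mol), `gradient` (same shape
#'   as the coordinates, kcal/mol/Angstrom) and, for committee potentials,
#'   `member_energies`.
#' @examples
#' pes_evaluate(pes_harmonic(k = 1), matrix(c(1, 0, 0), 1))
#' @export
pes_evaluate <- function(potential, x) UseMethod("pes_evaluate")

#' @export
pes_evaluate.default <- function(potential, x) {
  err_shape("not a potential object")
}

#' @export
pes_evaluate.pes_harmonic_well <- function(potential, x) {
  g <- resolve_geometry(x)
  d <- g$coords - potential$center      # center broadcast (scalar) or matched
  grad <- potential$k * d
  pes_result(0.5 * sum(potential$k * d * d), grad)
}

#' @export
pes_evaluate.pes_lennard_jones <- function(potential, x) {
  g <- resolve_geometry(x)
  xyz <- g$coords
  n <- nrow(xyz)
  if (n < 2L) err_shape("Lennard-Jones needs at least two atoms")
  eps <- potential$epsilon; sig <- potential$sigma
  energy <- 0
  grad <- matrix(0, n, 3L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dv <- xyz[i, ] - xyz[j, ]
    r2 <- sum(dv * dv)
    if (r2 < 1e-12) err_evaluation("coincident atoms in Lennard-Jones evaluation")
    sr2 <- sig * sig / r2
    sr6 <- sr2^3; sr12 <- sr6 * sr6
    energy <- energy + 4 * eps * (sr12 - sr6)
    # dE/dr * (1/r) * dv
    fscal <- 4 * eps * (-12 * sr12 + 6 * sr6) / r2
    grad[i, ] <- grad[i, ] + fscal * dv
    grad[j, ] <- grad[j, ] - fscal * dv
  }
  pes_result(energy, grad)
}

#' @export
pes_evaluate.pes_rosenbrock2d <- function(potential, x) {
  g <- resolve_geometry(x)
  v <- as.numeric(g$coords)
  if (length(v) != 2L) err_shape("the 2D Rosenbrock surface takes exactly two coordinates")
  a <- potential$a; b <- potential$b
  x1 <- v[1L]; x2 <- v[2L]
  e <- (a - x1)^2 + b * (x2 - x1^2)^2
  grad <- c(-2 * (a - x1) - 4 * b * x1 * (x2 - x1^2), 2 * b * (x2 - x1^2))
  if (is.matrix(g$coords) && ncol(g$coords) == 2L) dim(grad) <- dim(g$coords)
  pes_result(e, grad)
}

# softmin over wells: E(x) = -tau*log sum_j exp(-(0.5*k|x-C_j|^2 + d_j)/tau)
softmin_wells <- function(xyz, centers, depths, k, tau) {
  ev <- vapply(seq_along(centers), function(j) {
    d <- xyz - centers[[j]]
    0.5 * k * sum(d * d) + depths[j]
  }, 0)
  m <- min(ev)
  w <- exp(-(ev - m) / tau)
  z <- sum(w)
  w <- w / z
  grad <- 0 * xyz
  for (j in seq_along(centers)) {
    grad <- grad + w[j] * k * (xyz - centers[[j]])
  }
  list(value = m - tau * log(z), weights = w, grad = grad)
}

#' @export
pes_evaluate.pes_mock_ensemble <- function(potential, x) {
  g <- resolve_geometry(x)
  check_elements(potential, g$conf)
  xyz <- g$coords
  if (!all(dim(xyz) == dim(potential$centers[[1L]])))
    err_shape("geometry shape does not match the mock-ensemble well centers")
  base <- softmin_wells(xyz, potential$centers, potential$well_depths,
                        potential$k, potential$tau)
  members <- base$value + potential$member_offsets
  pes_result(mean(members), base$grad, member_energies = members)
}

#' @export
pes_evaluate.pes_forcefield_adapter <- function(potential, x) {
  g <- resolve_geometry(x)
  check_elements(potential, g$conf)
  elements <- if (is.null(g$conf)) rep("C", nrow(g$coords)) else g$conf$elements
  res <- potential$calculator(elements, g$coords)
  if (is.numeric(res)) res <- list(energy = res)
  grad <- res$gradient
  if (is.null(grad)) {
    h <- potential$fd_step
    grad <- g$coords * 0
    for (i in seq_len(nrow(g$coords))) for (d in 1:3) {
      xp <- g$coords; xp[i, d] <- xp[i, d] + h
      xm <- g$coords; xm[i, d] <- xm[i, d] - h
      ep <- potential$calculator(elements, xp)
      em <- potential$calculator(elements, xm)
      if (is.list(ep)) ep <- ep$energy
      if (is.list(em)) em <- em$energy
      grad[i, d] <- (ep - em) / (2 * h)
    }
  }
  pes_result(res$energy, grad)
}

#' @export
pes_evaluate.pes_ml_ensemble_adapter <- function(potential, x) {
  g <- resolve_geometry(x)
  check_elements(potential, g$conf)
  elements <- if (is.null(g$conf)) rep("C", nrow(g$coords)) else g$conf$elements
  outs <- lapply(potential$calculators, function(f) f(elements, g$coords))
  energies <- vapply(outs, function(o) o$energy, 0)
  grads <- lapply(outs, function(o) o$gradient)
  if (any(vapply(grads, is.null, TRUE)))
    err_evaluation("every committee calculator must return a gradient")
  grad <- Reduce(`+`, grads) / length(grads)
  pes_result(mean(energies), grad, member_energies = energies)
}

#' Committee (rho) uncertainty of an ensemble prediction
#'
#' Spread of the per-member energies of an ensemble-of-models potential,
#' scaled by the square root of the molecule's atom count - the
#' active-learning reliability flag for ensemble potentials. Uses the
#' sample standard deviation (denominator n-1) by default.
#'
#' @param result A `"pes_result"` carrying `member_energies`.
#' @param n_atoms Number of atoms in the molecule.
#' @param sample Logical; `TRUE` (default) for the sample standard
#'   deviation, `FALSE` for the population one.
#' @return rho in kcal/mol (non-negative scalar).
#' @examples
#' r <- pes_evaluate(pes_mock_ensemble(matrix(0, 1, 3)), matrix(0.1, 1, 3))
#' rho_uncertainty(r, n_atoms = 1)
#' @export
rho_uncertainty <- function(result, n_atoms, sample = TRUE) {
  stopifnot(inherits(result, "pes_result"), n_atoms >= 1)
  m <- result$member_energies
  if (is.null(m) || length(m) < 2L) err_insufficient_ensemble(length(m))
  s <- stats::sd(m)
  if (!sample) s <- s * sqrt((length(m) - 1) / length(m))
  s / sqrt(n_atoms)
}
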