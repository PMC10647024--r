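HARTREE <- 627.509474
BOHR <- 0.529177210903

# build a force matrix whose per-component value is exactly `au` Hartree/Bohr
uniform_force_kcal <- function(au, n) matrix(au * HARTREE / BOHR, n, 3)

test_that("convergence quartet converts units and tests each flag independently", {
  s <- cgbs_settings()
  z <- matrix(0, 4, 3)
  cc <- check_convergence(z, z, s)
  expect_true(cc$converged)

  # a uniform force at exactly the max-force threshold passes the inclusive
  # max test but fails the RMS test (RMS of a uniform field equals the
  # component value, above 0.00030)
  cc <- check_convergence(uniform_force_kcal(0.00045, 4), z, s)
  expect_true(cc$max_force)
  expect_false(cc$rms_force)
  expect_true(cc$max_disp)
  expect_true(cc$rms_disp)

  # boundary fixtures at exactly each threshold flip exactly one flag when
  # nudged over it
  disp_at <- function(au) matrix(au * BOHR, 4, 3)
  cc <- check_convergence(z, disp_at(0.0018), s)
  expect_true(cc$max_disp)
  expect_false(cc$rms_disp)         # 0.0018 > 0.0012
  cc <- check_convergence(z, disp_at(0.0012), s)
  expect_true(cc$max_disp)
  expect_true(cc$rms_disp)
  cc <- check_convergence(z, disp_at(0.0012 * (1 + 1e-9)), s)
  expect_false(cc$rms_disp)
  cc <- check_convergence(uniform_force_kcal(0.00030, 4), z, s)
  expect_true(cc$rms_force)
  cc <- check_convergence(uniform_force_kcal(0.00045 * (1 + 1e-9), 4), z, s)
  expect_false(cc$max_force)
})

test_that("convergence flags agree with a brute-force recomputation", {
  set.seed(21)
  s <- cgbs_settings()
  for (rep in 1:20) {
    f_au <- matrix(runif(60, 0, 1e-4) * sample(c(-1, 1), 60, TRUE), 20, 3)
    d_au <- matrix(runif(60, 0, 5e-3) * sample(c(-1, 1), 60, TRUE), 20, 3)
    cc <- check_convergence(f_au * HARTREE / BOHR, d_au * BOHR, s)
    expect_equal(cc$max_force, max(abs(f_au)) <= 0.00045)
    expect_equal(cc$rms_force, sqrt(mean(f_au^2)) <= 0.00030)
    expect_equal(cc$max_disp, max(abs(d_au)) <= 0.0018)
    expect_equal(cc$rms_disp, sqrt(mean(d_au^2)) <= 0.0012)
    expect_equal(cc$converged, cc$max_force && cc$rms_force &&
                   cc$max_disp && cc$rms_disp)
  }
})

test_that("harmonic wells are minimized to the centre with full convergence", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    ctr <- matrix(rnorm(3 * n), n)
    fit <- cgbs_optimize(pes_harmonic(k = runif(1, 0.5, 3), center = ctr),
                         ctr + matrix(rnorm(3 * n), n))
    expect_true(fit$converged)
    expect_lt(max(abs(fit$final - ctr)), 1e-3)
    cc <- check_convergence(fit$last_eval$gradient, 0 * ctr, fit$settings)
    expect_true(cc$max_force && cc$rms_force)
  }
})

tight <- cgbs_settings(max_force_au = 1e-8, rms_force_au = 1e-8,
                       max_disp_au = 1e-6, rms_disp_au = 1e-6)

test_that("known analytic minima are recovered", {
  # Rosenbrock valley from the classic start
  fit <- cgbs_optimize(pes_rosenbrock(), c(-1.2, 1), tight)
  expect_lt(max(abs(as.numeric(fit$final) - c(1, 1))), 1e-2)

  # LJ dimer relaxes to the 2^(1/6) separation
  fit <- cgbs_optimize(pes_lennard_jones(), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_true(fit$converged)
  expect_lt(abs(sqrt(sum((fit$final[1, ] - fit$final[2, ])^2)) - 2^(1 / 6)),
            1e-3)
})

test_that("final energies match a trusted general-purpose minimizer", {
  # Rosenbrock, same start, BFGS with analytic gradient as oracle
  o <- optim(c(-1.2, 1), function(v) pes_evaluate(pes_rosenbrock(), v)$energy,
             function(v) as.numeric(pes_evaluate(pes_rosenbrock(), v)$gradient),
             method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  fit <- cgbs_optimize(pes_rosenbrock(), c(-1.2, 1), tight)
  expect_lt(abs(fit$energy - o$value), 1e-4)

  # LJ dimer parameterized by separation
  lj <- pes_lennard_jones()
  o2 <- optim(1.5, function(r) pes_evaluate(lj, rbind(0, c(r, 0, 0)))$energy,
              method = "Brent", lower = 0.8, upper = 3)
  fit2 <- cgbs_optimize(lj, rbind(c(0, 0, 0), c(1.5, 0, 0)), tight)
  expect_lt(abs(fit2$energy - o2$value), 1e-4)
})

test_that("a multi-well committee surface yields a force-converged 7-atom cluster", {
  set.seed(77)
  wells <- list(matrix(rnorm(21), 7), matrix(rnorm(21), 7) + 2)
  pot <- pes_mock_ensemble(wells, k = 30, tau = 1, well_depths = c(0, -3))
  fit <- cgbs_optimize(pot, wells[[1]] + matrix(rnorm(21, sd = 0.3), 7))
  expect_true(fit$converged)
  # derived check: criteria recomputed directly from the final gradient
  cc <- check_convergence(fit$last_eval$gradient, matrix(0, 7, 3),
                          fit$settings)
  expect_true(cc$max_force)
  expect_true(cc$rms_force)
})

test_that("accepted-step energies never increase", {
  set.seed(41)
  fits <- list(
    cgbs_optimize(pes_rosenbrock(), c(-1.2, 1), tight),
    cgbs_optimize(pes_lennard_jones(), rbind(c(0, 0, 0), c(1.2, 0.3, 0))),
    cgbs_optimize(pes_harmonic(k = 2, center = 1), matrix(rnorm(12), 4)),
    cgbs_optimize(pes_mock_ensemble(list(matrix(0, 3, 3), matrix(1.5, 3, 3)),
                                    k = 25, well_depths = c(0, -2)),
                  matrix(rnorm(9, sd = 0.8), 3)))
  for (fit in fits) expect_true(all(diff(fit$trace$energy_kcal) <= 1e-12))
})

test_that("optimization is translation-equivariant on translation-invariant surfaces", {
  start <- rbind(c(0, 0, 0), c(1.4, 0.1, -0.2), c(0.3, 1.5, 0.4))
  shift <- c(5.5, -2.25, 11)
  pot <- pes_lennard_jones()
  f0 <- cgbs_optimize(pot, start)
  f1 <- cgbs_optimize(pot, sweep(start, 2, shift, "+"))
  expect_lt(max(abs(sweep(f1$final, 2, shift) - f0$final)), 1e-6)
})

test_that("strictly convex quadratics converge within 50 iterations per dimension", {
  set.seed(51)
  for (d_atoms in c(1, 4, 10)) {
    k <- runif(3 * d_atoms, 0.5, 4)
    ctr <- matrix(rnorm(3 * d_atoms), d_atoms)
    fit <- cgbs_optimize(pes_harmonic(k = matrix(k, d_atoms), center = ctr),
                         ctr + matrix(rnorm(3 * d_atoms), d_atoms))
    expect_true(fit$converged)
    expect_lte(fit$n_iterations, 50 * 3 * d_atoms)
  }
})

test_that("the optimizer is deterministic", {
  start <- matrix(c(0.9, -0.4, 0.2, -1.1, 0.5, 0.8), 2)
  pot <- pes_mock_ensemble(list(matrix(0, 2, 3)), k = 15)
  f1 <- cgbs_optimize(pot, start)
  f2 <- cgbs_optimize(pot, start)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$final, f2$final)
})

test_that("an unfindable decrease terminates as line-search failure, not an error", {
  # V-shaped cusp: |x| in the first coordinate; gradient never vanishes so
  # the force criteria cannot be met, and near the cusp no Armijo step exists
  cusp <- pes_forcefield(function(elements, coords)
    list(energy = abs(coords[1, 1]) + 0.5 * sum(coords[, 2:3]^2),
         gradient = cbind(c(sign(coords[1, 1])),
                          coords[, 2, drop = FALSE],
                          coords[, 3, drop = FALSE])))
  fit <- cgbs_optimize(cusp, conformation("C", matrix(c(0.737, 0, 0), 1)),
                       cgbs_settings(max_iterations = 500))
  expect_false(fit$converged)
  expect_identical(fit$termination_reason, "line_search_failure")
  expect_true(all(diff(fit$trace$energy_kcal) <= 1e-12))
})

test_that("optimizing a conformation preserves identity metadata and reports RMSD", {
  conf <- conformation(c("C", "C"), rbind(c(0, 0, 0), c(1.9, 0, 0)),
                       net_charge = -1L)
  fit <- cgbs_optimize(pes_lennard_jones(sigma = 1.4), conf)
  expect_s3_class(fit$final, "conformation")
  expect_identical(fit$final$elements, conf$elements)
  expect_identical(fit$final$net_charge, -1L)
  expect_identical(fit$final$role, "optimized")
  expect_gte(fit$rmsd_start_final, 0)
  expect_lte(fit$energy, pes_evaluate(pes_lennard_jones(sigma = 1.4), conf)$energy)
})
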