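test_that("best-resolution selection keeps the smallest resolution per ligand", {
  entries <- data.frame(
    ligand_id = c("L1", "L1", "L2", "L3", "L3", "L3"),
    structure_id = c("A", "B", "N1", "ZZZ", "AAA", "MMM"),
    resolution = c(1.8, 2.5, NA, 1.90, 1.90, 2.2),
    method = c("xray", "xray", "nmr", "xray", "xray", "xray"),
    stringsAsFactors = FALSE)
  out <- select_best_resolution(entries)
  expect_identical(out$selected$structure_id[out$selected$ligand_id == "L1"], "A")
  # NMR-only ligand dropped and reported
  expect_identical(out$dropped, "L2")
  # resolution tie at 1.90 breaks to the lexicographically smallest id
  expect_identical(out$selected$structure_id[out$selected$ligand_id == "L3"], "AAA")
  expect_identical(nrow(out$selected), 2L)
})

test_that("element filtering distinguishes the basic and extended sets", {
  expect_false(filter_elements(FX$bromobenzene$graph, "CHONSFCl"))
  expect_false(filter_elements(FX$bromobenzene$graph, "CHON"))
  expect_true(filter_elements(FX$chlorobenzene$graph, "CHONSFCl"))
  expect_false(filter_elements(FX$chlorobenzene$graph, "CHON"))
  expect_true(filter_elements(FX$ethanol$graph, "CHON"))
  expect_true(filter_elements(c("C", "H", "N", "O"), "CHON"))
})

test_that("subset assignment uses the inclusive 20 kcal/mol window", {
  expect_identical(assign_subset(-0.5), "subset1")
  expect_identical(assign_subset(0), "subset2")
  expect_identical(assign_subset(20.0), "subset2")
  expect_identical(assign_subset(20.01), "subset3")
  expect_identical(assign_subset(c(-1, 5, 25)),
                   c("subset1", "subset2", "subset3"))
  # custom cutoff honoured
  expect_identical(assign_subset(12, cutoff = 10), "subset3")
  # a record at e_active == e_min has delta zero: subset2, scenario within
  r <- ensemble_record("B", 3, c(3, 9), atom_count = 12)
  expect_identical(assign_subset(r), "subset2")
  expect_identical(r$scenario, "within")
})

test_that("subset assignment and scenario classification agree on subset1", {
  set.seed(121)
  for (rep in 1:50) {
    members <- rnorm(sample(2:20, 1), sd = 6)
    r <- ensemble_record("X", rnorm(1, sd = 8), members, atom_count = 10)
    expect_identical(assign_subset(r) == "subset1", r$scenario == "below_min")
  }
})

test_that("distribution summaries use interpolated quantiles and a proper cdf", {
  s <- summarize_deltas(0:10)
  expect_identical(s$median, 5)
  expect_identical(s$q1, 2.5)
  s3 <- summarize_deltas(c(3, 3, 3))
  expect_identical(c(s3$q1, s3$median, s3$q3, s3$p90), rep(3, 4))
  expect_identical(s3$sd, 0)
  expect_true(all(diff(s$cumulative$fraction) >= 0))
  expect_identical(s$cumulative$fraction[nrow(s$cumulative)], 1)
  expect_true(s$q1 <= s$median && s$median <= s$q3 && s$q3 <= s$p90)
  expect_error(summarize_deltas(numeric(0)),
               class = "confstrain_empty_distribution_error")
})

test_that("the exponential median is recovered from a large seeded sample", {
  set.seed(131)
  n <- 10000
  x <- rexp(n, rate = 1 / 4.2)
  s <- summarize_deltas(x)
  med_theory <- 4.2 * log(2)
  # order-statistic sd of the sample median: 1/(2 f(q) sqrt(n))
  sd_med <- 1 / (2 * dexp(med_theory, 1 / 4.2) * sqrt(n))
  expect_lt(abs(s$median - med_theory), 3 * sd_med)
})

test_that("threshold trade-off fractions match exhaustive enumeration", {
  # hand-listed 3-record fixture
  recs <- list(
    ensemble_record("A", e_active = 4, member_energies = c(0, 3, 8, 12), atom_count = 20),
    ensemble_record("B", e_active = 11, member_energies = c(2, 4, 9), atom_count = 35),
    ensemble_record("C", e_active = 6.5, member_energies = c(1, 6, 7), atom_count = 50))
  tt <- threshold_tradeoff(recs, 5)
  # relative member energies: A {0,3,8,12}; B {0,2,7}; C {0,5,6}
  # above 5: A 2, B 1, C 1 -> 4/10; deltas {4,9,5.5}: above 5 -> 2/3
  expect_equal(tt$frac_conformers_removed, 4 / 10)
  expect_equal(tt$frac_bound_lost, 2 / 3)

  # limits
  tinf <- threshold_tradeoff(recs, c(0, 1e9))
  expect_equal(tinf$frac_conformers_removed[2], 0)
  expect_equal(tinf$frac_bound_lost[2], 0)
  # at T = 0 only each global (relative 0) survives here
  expect_equal(tinf$frac_conformers_removed[1], (4 - 1 + 3 - 1 + 3 - 1) / 10)

  # random cohorts against a brute-force count
  set.seed(141)
  for (rep in 1:25) {
    recs <- lapply(seq_len(sample(2:8, 1)), function(i)
      ensemble_record(paste0("R", i), rnorm(1, 2, 3),
                      rnorm(sample(2:10, 1), 0, 6), atom_count = 25))
    T <- runif(1, 0, 8)
    tt <- threshold_tradeoff(recs, T)
    n_above <- 0; n_tot <- 0; n_lost <- 0
    for (r in recs) {
      rel <- r$member_energies - min(r$member_energies)
      n_above <- n_above + sum(rel > T)
      n_tot <- n_tot + length(rel)
      n_lost <- n_lost + (r$e_active - min(r$member_energies) > T)
    }
    expect_equal(tt$frac_conformers_removed, n_above / n_tot)
    expect_equal(tt$frac_bound_lost, n_lost / length(recs))
  }
})

test_that("threshold trade-off is monotone non-increasing in the cutoff", {
  set.seed(151)
  recs <- lapply(1:40, function(i)
    ensemble_record(paste0("R", i), rnorm(1, 3, 4),
                    rnorm(sample(2:30, 1), 0, 8), atom_count = 30))
  grid <- seq(0, 25, length.out = 200)
  tt <- threshold_tradeoff(recs, grid)
  expect_true(all(diff(tt$frac_conformers_removed) <= 0))
  expect_true(all(diff(tt$frac_bound_lost) <= 0))
  expect_true(all(tt$frac_conformers_removed >= 0 &
                    tt$frac_conformers_removed <= 1))
})

test_that("atom-count bins are half-open and partition the records", {
  rec_at <- function(n) ensemble_record(paste0("A", n), 1, c(0, 2),
                                        atom_count = n)
  bins <- bin_by_atom_count(lapply(c(29, 30, 40, 69, 70, 150), rec_at))
  expect_identical(bins$bin[bins$count > 0],
                   c("<30", "30-40", "40-50", "60-70", ">70"))
  expect_identical(bins$count[bins$bin == "30-40"], 1L)   # atom count 30 rounds up into [30,40)
  expect_identical(bins$count[bins$bin == ">70"], 2L)     # 70 and 150 both land in [70,Inf)
  set.seed(161)
  recs <- lapply(1:60, function(i)
    ensemble_record(paste0("R", i), rnorm(1, 2, 2), rnorm(3, 0, 5),
                    atom_count = sample(10:100, 1)))
  bins <- bin_by_atom_count(recs)
  expect_identical(sum(bins$count), 60L)
})

test_that("benchmark metrics are exact on identical and shifted energies", {
  set.seed(171)
  ref <- lapply(1:6, function(i) rnorm(5, sd = 3))
  names(ref) <- paste0("M", 1:6)
  bm <- benchmark_metrics(ref, ref)
  expect_true(all(bm$per_molecule$r2 == 1))
  expect_equal(bm$per_molecule$spearman_rho, rep(1, 6), tolerance = 1e-12)
  expect_true(all(bm$per_molecule$rmse_kcal == 0))
  # per-molecule constant shifts cancel on the relative-energy scale
  shifted <- lapply(seq_along(ref), function(i) ref[[i]] + 10 * i)
  names(shifted) <- names(ref)
  bm2 <- benchmark_metrics(ref, shifted)
  expect_equal(bm2$per_molecule$r2, rep(1, 6))
  expect_equal(bm2$per_molecule$rmse_kcal, rep(0, 6))
  # noise must lower R2 below 1
  set.seed(172)
  noisy <- lapply(ref, function(v) v + rnorm(5, sd = 0.3))
  names(noisy) <- names(ref)
  expect_true(all(benchmark_metrics(ref, noisy)$per_molecule$r2 < 1))
})

test_that("benchmark metrics equal direct formula evaluation on a printed fixture", {
  ref <- list(mol = c(0.0, 1.2, 2.5, 0.8, 3.1))
  test <- list(mol = c(0.3, 1.0, 3.0, 0.5, 2.4))
  bm <- benchmark_metrics(ref, test)
  # spreadsheet-style evaluation: reference minimum is conformer 1
  r <- ref$mol - ref$mol[1]
  t <- test$mol - test$mol[1]
  r2_hand <- 1 - sum((t - r)^2) / sum((r - mean(r))^2)
  rho_hand <- cor(rank(r), rank(t))
  rmse_hand <- sqrt(mean((t - r)^2))
  expect_equal(bm$per_molecule$r2, r2_hand, tolerance = 1e-10)
  expect_equal(bm$per_molecule$spearman_rho, rho_hand, tolerance = 1e-10)
  expect_equal(bm$per_molecule$rmse_kcal, rmse_hand, tolerance = 1e-10)
})

test_that("negative-R2 and degenerate molecules are excluded and counted", {
  ref <- list(good = c(0, 1, 2, 3),
              bad = c(0, 0.1, 0.2, 0.3),
              flat = c(2, 2, 2, 2))
  test <- list(good = c(0, 1.1, 1.9, 3.2),
               bad = c(0, -3, 4, -6),      # wildly wrong: negative R2
               flat = c(1, 5, 2, 7))
  bm <- benchmark_metrics(ref, test)
  expect_identical(bm$n_omitted_negative_r2, 1L)
  expect_identical(bm$n_excluded_degenerate, 1L)
  expect_identical(bm$per_molecule$retained, c(TRUE, FALSE, FALSE))
  # aggregates cover only the retained molecule
  expect_identical(unique(bm$aggregate$n[bm$aggregate$metric != "rmsd_ang"]), 1L)
})

test_that("charge stratification groups the same metrics without new math", {
  set.seed(181)
  ref <- lapply(1:8, function(i) rnorm(4, sd = 2))
  names(ref) <- paste0("M", 1:8)
  test <- lapply(ref, function(v) v + rnorm(4, sd = 0.2))
  names(test) <- names(ref)
  charges <- c(0L, 0L, 0L, 1L, -1L, 0L, 1L, 0L)
  bm <- benchmark_metrics(ref, test, net_charge = charges)
  expect_named(bm$by_charge, c("neutral", "charged"))
  n_neutral <- bm$by_charge$neutral$n[bm$by_charge$neutral$metric == "r2"]
  n_charged <- bm$by_charge$charged$n[bm$by_charge$charged$metric == "r2"]
  expect_identical(n_neutral + n_charged,
                   sum(bm$per_molecule$retained))
})
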