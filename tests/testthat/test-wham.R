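# Binless WHAM: reduced energies, gauge and exchangeability, zero-snapshot
# inertness, reweighted expectations, titration curves and pKa fits.

test_that("reduced energies are linear in the proton count and conditions", {
  expect_equal(reduced_energy(0, 7, -300), 0)
  expect_equal(reduced_energy(0, 2, 500), 0)
  expect_equal(reduced_energy(1, 5, 0) - reduced_energy(1, 4, 0), log(10))
  # differences depend only on condition differences
  d1 <- reduced_energy(2, 6, 40) - reduced_energy(2, 3, -20)
  d2 <- reduced_energy(2, 7, 100) - reduced_energy(2, 4, 40)
  expect_equal(d1, d2)
})

test_that("gauge, exchangeability and equivalent conditions behave", {
  rs <- make_protonation_series(4, data.frame(pH = 4, phi_mV = 0,
                                              n_snapshots = 200), seed = 2)
  sol <- solve_wham(rs)
  expect_equal(sol$conditions$f, 0)

  # a pH shift and the Nernst-equivalent potential shift are the same
  # condition: their free energies must agree closely
  nernst <- kBT(298.15) * log(10) / phys_constants()$eV_to_kcal * 1000
  cond <- data.frame(pH = c(5, 4), phi_mV = c(0, nernst),
                     n_snapshots = c(300, 300))
  rs2 <- make_protonation_series(4, cond, seed = 3)
  sol2 <- solve_wham(rs2)
  expect_lt(abs(diff(sol2$conditions$f)), 1e-6)

  # duplicating every snapshot rescales counts but not free energies
  dup <- as_runset(dplyr::bind_rows(rs2, dplyr::mutate(
    rs2, run_id = run_id + 10)), n_sites = 1)
  sol3 <- solve_wham(dup)
  expect_equal(sol3$conditions$f, sol2$conditions$f, tolerance = 1e-7)
})

test_that("zero-snapshot conditions never perturb sampled free energies", {
  cond <- data.frame(pH = c(3, 4, 5), phi_mV = 0, n_snapshots = 150)
  rs <- make_protonation_series(4, cond, seed = 4)
  sol_plain <- solve_wham(rs)
  grid <- data.frame(pH = seq(0, 9, 0.5), phi_mV = -120)
  sol_grid <- solve_wham(rs, conditions = grid)
  expect_equal(sol_grid$conditions$f[1:3], sol_plain$conditions$f,
               tolerance = 1e-7)
})

test_that("expectations are normalized and self-consistent", {
  cond <- data.frame(pH = c(3.5, 4.5), phi_mV = 0, n_snapshots = 250)
  rs <- make_protonation_series(4, cond, n_sites = 2, seed = 5)
  sol <- solve_wham(rs)
  for (k in 1:2) {
    expect_equal(wham_expectation(sol, k, observable = function(n) 1), 1)
  }
  # single-run case: the expectation at the sampled condition is the
  # sample mean
  rs1 <- make_protonation_series(4, data.frame(pH = 4.2, phi_mV = 0,
                                               n_snapshots = 300),
                                 n_sites = 2, seed = 6)
  sol1 <- solve_wham(rs1)
  expect_equal(wham_expectation(sol1, 1), mean(rs1$n_protons),
               tolerance = 1e-9)
})

test_that("exact Henderson-Hasselbalch inputs reproduce the generator pKa", {
  # analytic counts: at pH = pKa -1, pKa, pKa + 1 the probabilities are
  # 10/11, 1/2 and 1/11, so 22 snapshots realize them exactly
  mk <- function(ph, n1, n0) {
    tibble::tibble(run_id = ph, pH = ph, phi_mV = 0, T_K = 298.15,
                   snapshot = 1:22,
                   n_protons = c(rep(1L, n1), rep(0L, n0)))
  }
  rs <- as_runset(dplyr::bind_rows(mk(3, 20, 2), mk(4, 11, 11),
                                   mk(5, 2, 20)), n_sites = 1)
  curve <- titration_curve(rs, seq(1.5, 6.5, 0.25))
  expect_lt(abs(attr(curve, "pKa") - 4), 1e-3)
  # fractions are monotone non-increasing in pH and within [0, 1]
  expect_true(all(diff(curve$fraction) <= 1e-12))
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))
})

test_that("titration curves span their asymptotes and carry the HH shape", {
  cond <- data.frame(pH = 2:7, phi_mV = 0, n_snapshots = 400)
  rs <- make_protonation_series(4.5, cond, seed = 7)
  curve <- titration_curve(rs, seq(0, 10, 0.5))
  expect_lt(curve$fraction[curve$pH == 10], 0.01)
  expect_gt(curve$fraction[curve$pH == 0], 0.99)
  expect_lt(abs(attr(curve, "pKa") - 4.5), 0.15)
})

test_that("pKa fitting is exact on clean curves and covariant under shifts", {
  ph <- seq(1, 8, 0.25)
  clean <- data.frame(pH = ph, fraction = 1 / (1 + 10^(ph - 4)))
  expect_equal(fit_pka(clean)$pKa, 4, tolerance = 1e-6)
  shifted <- data.frame(pH = ph, fraction = 1 / (1 + 10^(ph - 7)))
  expect_equal(fit_pka(shifted)$pKa, fit_pka(clean)$pKa + 3,
               tolerance = 1e-6)
  # a curve that does not span its midpoint warns and is flagged
  top <- data.frame(pH = seq(1, 2, 0.25),
                    fraction = 1 / (1 + 10^(seq(1, 2, 0.25) - 4)))
  expect_warning(f <- fit_pka(top), "midpoint")
  expect_true(f$extrapolated)
  expect_false(fit_pka(clean)$extrapolated)
  g <- glance(fit_pka(clean))
  expect_equal(g$hill, 1)
})

test_that("synthetic run sets recover the generator pKa without bias", {
  cond <- data.frame(pH = 2:7, phi_mV = 0, n_snapshots = 400)
  errs <- vapply(1:20, function(s) {
    rs <- make_protonation_series(4.0, cond, seed = 1000 + s)
    curve <- titration_curve(rs, seq(1, 8, 0.5))
    attr(curve, "pKa") - 4.0
  }, 1.0)
  expect_lt(abs(mean(errs)), 0.05)
  expect_lt(max(abs(errs)), 0.15)
})

test_that("titration at a nonzero potential is the translated zero-potential curve", {
  cond <- data.frame(pH = 2:7, phi_mV = 0, n_snapshots = 400)
  rs <- make_protonation_series(4.0, cond, seed = 9)
  c0 <- titration_curve(rs, seq(1, 8, 0.5), phi_mV = 0)
  nernst <- kBT(298.15) * log(10) / phys_constants()$eV_to_kcal * 1000
  c1 <- titration_curve(rs, seq(1, 8, 0.5), phi_mV = -nernst)
  shift <- attr(c1, "pKa") - attr(c0, "pKa")
  expect_equal(shift, -delta_pka(-nernst), tolerance = 0.02)
})

test_that("the potential-to-pKa-shift conversion matches its closed forms", {
  expect_equal(delta_pka(0), 0)
  expect_equal(delta_pka(59.1584, 298.15), 1, tolerance = 1e-3)
  expect_equal(round(delta_pka(78, 310), 1), 1.3)
  expect_equal(delta_pka(-59.1584), -delta_pka(59.1584))
})

test_that("WHAM arithmetic survives extreme reduced energies", {
  cond <- data.frame(pH = c(4, 300), phi_mV = 0, n_snapshots = c(100, 100))
  rs <- make_protonation_series(4, cond, seed = 10)
  grid <- data.frame(pH = c(1, 250), phi_mV = 0)
  sol <- solve_wham(rs, conditions = grid)
  expect_true(all(is.finite(sol$conditions$f)))
  expect_lt(wham_expectation(sol, 4), 1e-10)
  expect_gt(wham_expectation(sol, 3), 0.99)
})

test_that("degenerate inputs raise errors", {
  rs <- make_protonation_series(4, data.frame(pH = 4, phi_mV = 0,
                                              n_snapshots = 10), seed = 1)
  expect_error(solve_wham(rs[0, ]), "empty|runset")
  cond <- data.frame(pH = c(1, 9), phi_mV = c(-400, 400),
                     n_snapshots = c(50, 50))
  rs2 <- make_protonation_series(4, cond, seed = 2)
  expect_error(solve_wham(rs2, tol = 1e-14, max_iter = 2), "converge")
  expect_error(as_runset(data.frame(run_id = 1, pH = 4, phi_mV = 0,
                                    T_K = 298.15, snapshot = 1,
                                    n_protons = 5), n_sites = 1),
               "proton counts")
})
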