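# Occupancy maps, cell classification, region histograms, the bulk-water
# peak, and the volume-fraction analysis of the Galvani potential.

make_occ <- function(maps, box) {
  dims <- dim(maps[[1]])
  structure(list(maps = maps, dims = dims, box = box,
                 spacing = box / dims, smear = 1),
            class = "occupancy_grid")
}

test_that("occupancy deposition is normalized, peaked and symmetric under relabeling", {
  box <- c(16, 16, 16)
  pos <- rbind(c(8, 8, 8), c(3, 12, 5))
  sys <- charge_system(pos, c(0, 0), box,
                       species = c("solvent", "membrane"))
  occ <- build_occupancy(sys, dims = c(16, 16, 16))
  cellvol <- prod(occ$spacing)
  expect_lt(abs(sum(occ$maps$solvent) * cellvol - 1), 0.01)
  expect_lt(abs(sum(occ$maps$membrane) * cellvol - 1), 0.01)
  # atom sits exactly on node (8,8,8) -> index 9; map peaks there and
  # decays monotonically along an axis
  expect_equal(which.max(occ$maps$solvent),
               which(array(seq_len(16^3), c(16, 16, 16)) ==
                       seq_len(16^3)[9 + 8 * 16 + 8 * 256]))
  ray <- occ$maps$solvent[9:14, 9, 9]
  expect_true(all(diff(ray) < 0))
  # swapping the two species labels swaps the maps exactly
  sys2 <- charge_system(pos, c(0, 0), box,
                        species = c("membrane", "solvent"))
  occ2 <- build_occupancy(sys2, dims = c(16, 16, 16))
  expect_identical(occ$maps$solvent, occ2$maps$membrane)
  expect_identical(occ$maps$membrane, occ2$maps$solvent)
})

test_that("missing species labels are reported", {
  sys <- charge_system(rbind(c(1, 1, 1)), 1, c(10, 10, 10))
  expect_error(build_occupancy(sys), "species")
})

test_that("classification is argmax with vacuum floor and protein-first ties", {
  dims <- c(2, 2, 2)
  z <- array(0, dims)
  s <- z; s[1, 1, 1] <- 0.9
  m <- z; m[1, 1, 1] <- 0.1; m[2, 1, 1] <- 0.5; m[1, 2, 1] <- 0.5
  p <- z; p[1, 2, 1] <- 0.5
  occ <- make_occ(list(solvent = s, membrane = m, protein = p), c(2, 2, 2))
  lab <- classify_cells(occ, floor = 0.01)
  expect_equal(lab$labels[1, 1, 1], "solvent")     # argmax
  expect_equal(lab$labels[2, 1, 1], "membrane")
  expect_equal(lab$labels[1, 2, 1], "protein")     # exact tie -> protein
  expect_equal(lab$labels[2, 2, 2], "vacuum")      # all below floor
})

test_that("water fraction counts solvent over non-vacuum cells", {
  dims <- c(4, 4, 4)
  s <- array(1, dims)
  occ <- make_occ(list(solvent = s), c(4, 4, 4))
  expect_equal(water_fraction(classify_cells(occ)), 1)
  m <- array(0, dims); m[, , 1:2] <- 2
  s2 <- array(1, dims); s2[, , 1:2] <- 0
  occ2 <- make_occ(list(solvent = s2, membrane = m), c(4, 4, 4))
  expect_equal(water_fraction(classify_cells(occ2)), 0.5)
  vac <- make_occ(list(solvent = array(0, dims)), c(4, 4, 4))
  expect_error(water_fraction(classify_cells(vac)), "vacuum")
})

test_that("slab geometry yields the constructed water fraction", {
  # slab occupying 26% of the box height
  box <- c(20, 20, 100)
  slab <- make_capacitor_slab(2e-4, d = 8, box = box, thickness = 26)
  occ <- build_occupancy(slab)
  f_w <- water_fraction(classify_cells(occ))
  # the smeared label boundary can move ~one cell layer per interface
  expect_lt(abs(f_w - 0.74), 3 / 100)
})

test_that("region histograms conserve counts and split the slab bimodally", {
  box <- c(16, 16, 72)
  slab <- make_capacitor_slab(5e-4, d = 8, box = box, thickness = 30)
  g <- compute_potential_grid(slab, ewald_params())
  occ <- build_occupancy(slab)
  lab <- classify_cells(occ)
  h <- region_histogram(g, lab)
  # counts per region equal region cell counts
  counts <- table(lab$labels)
  for (r in c("solvent", "membrane")) {
    expect_equal(sum(h$count[h$region == r]), unname(counts[r]))
  }
  gt <- attr(slab, "ground_truth")
  solv_mode <- estimate_bulk_potential(h)
  # 10 mV bins collect the gently varying core plateau into one mode bin
  h10 <- region_histogram(g, lab, bin_width = 10)
  mem <- h10[h10$region == "membrane", ]
  mem_mode <- mem$bin_mid[which.max(mem$count)]
  # solvent bins concentrate near the exterior plateau, membrane bins near
  # the interior plateau
  expect_lt(abs(solv_mode - gt$phi_w_mV), 0.05 * gt$delta_phi_mV)
  expect_lt(abs(mem_mode - gt$phi_core_mV), 0.05 * gt$delta_phi_mV)
  # single-region constant field occupies exactly one bin
  flat <- potential_grid(array(42, c(4, 4, 4)), c(4, 4, 4))
  lab1 <- classify_cells(make_occ(list(solvent = array(1, c(4, 4, 4))),
                                  c(4, 4, 4)))
  h1 <- region_histogram(flat, lab1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$bin_mid, 42)
  # mismatched lattices error
  expect_error(region_histogram(flat, lab), "lattice")
})

test_that("bulk peak estimation refines the mode and resolves ties", {
  w <- 1
  mk <- function(mids, counts) {
    tibble::new_tibble(
      tibble::tibble(region = "solvent", bin_mid = mids, count = counts),
      bin_width = w, class = "region_histogram")
  }
  # symmetric unimodal peak at -100
  mids <- seq(-110, -90)
  counts <- round(1000 * exp(-(mids + 100)^2 / 8))
  expect_equal(estimate_bulk_potential(mk(mids, counts)), -100,
               tolerance = 0.5)
  # bimodal: taller mode wins regardless of mass balance
  mids2 <- c(seq(-155, -145), seq(-5, 5))
  counts2 <- c(round(600 * exp(-(seq(-155, -145) + 150)^2 / 2)),
               round(400 * exp(-(seq(-5, 5))^2 / 8)))
  expect_equal(estimate_bulk_potential(mk(mids2, counts2)), -150,
               tolerance = 0.5)
  # exact tie -> bin closer to the solvent mean
  mids3 <- c(-10, 0, 2)
  counts3 <- c(5, 1, 5)
  expect_equal(estimate_bulk_potential(mk(mids3, counts3)), 2,
               tolerance = 0.5)
  # empty solvent region errors
  h_empty <- tibble::new_tibble(
    tibble::tibble(region = "membrane", bin_mid = 0, count = 1L),
    bin_width = w, class = "region_histogram")
  expect_error(estimate_bulk_potential(h_empty), "solvent")
})

test_that("slab pipeline recovers the closed-form bulk potential within 2%", {
  cases <- expand.grid(sigma = c(1e-4, 1e-3), d = c(5, 20))
  for (i in seq_len(nrow(cases))) {
    sg <- cases$sigma[i]; d <- cases$d[i]
    slab <- make_capacitor_slab(sg, d = d, box = c(16, 16, 120),
                                thickness = max(3 * d, 30))
    gt <- attr(slab, "ground_truth")
    res <- galvani_offset(slab)
    expect_lt(abs(res$phi_w_mV - gt$phi_w_mV), 0.02 * abs(gt$phi_w_mV))
    expect_equal(res$phi_offset_mV, -res$phi_w_mV)
  }
})

test_that("region balance holds and the bulk potential scales with box height", {
  heights <- c(90, 120, 180)
  pts <- lapply(heights, function(L) {
    slab <- make_capacitor_slab(5e-4, d = 10, box = c(16, 16, L))
    gt <- attr(slab, "ground_truth")
    g <- compute_potential_grid(slab, ewald_params())
    occ <- build_occupancy(slab)
    lab <- classify_cells(occ)
    h <- region_histogram(g, lab)
    # volume-weighted region balance (vacuum-free frame)
    agg <- dplyr::summarise(dplyr::group_by(h, region),
                            m = sum(bin_mid * count) / sum(count),
                            n = sum(count), .groups = "drop")
    balance <- sum(agg$m * agg$n) / sum(agg$n)
    expect_lt(abs(balance), 1)
    c(f_w = water_fraction(lab), phi = estimate_bulk_potential(h),
      exp_phi = gt$phi_w_mV)
  })
  pts <- do.call(rbind, pts)
  # enlarging the solvent region moves the bulk potential strictly toward 0
  expect_true(all(diff(pts[, "phi"]) > 0))
  expect_true(all(pts[, "phi"] < 0))
  # the three (f_w, phi_w) points lie on a line through (1, 0)
  fit <- linear_fit_fw(data.frame(f_w = pts[, "f_w"],
                                  phi_w_mV = pts[, "phi"]))
  expect_gt(fit$r_squared, 0.99)
  phi_at_1 <- fit$slope + fit$intercept
  expect_lt(abs(phi_at_1), 0.05 * max(abs(pts[, "phi"])))
})

test_that("classification is stable under sub-cell position perturbations", {
  slab <- make_capacitor_slab(5e-4, d = 10, box = c(16, 16, 90))
  lab1 <- classify_cells(build_occupancy(slab))
  set.seed(5)
  jitter <- matrix(stats::rnorm(3 * nrow(slab$positions), sd = 0.01),
                   ncol = 3)
  slab2 <- charge_system(slab$positions + jitter, slab$charges, slab$box,
                         slab$species)
  lab2 <- classify_cells(build_occupancy(slab2))
  changed <- mean(lab1$labels != lab2$labels)
  expect_lt(changed, 0.01)
})

test_that("the water-fraction line fits and predicts as closed forms require", {
  # two points: exact interpolation
  fit2 <- linear_fit_fw(data.frame(f_w = c(0.5, 1), phi_w_mV = c(-100, 0)))
  expect_equal(fit2$r_squared, 1)
  expect_equal(fit2$slope, 200)
  # five-system table: R^2 rounds to 0.99, slope ~733 from rounded inputs
  pts <- data.frame(f_w = c(0.74, 0.81, 0.81, 0.88, 0.88),
                    phi_w_mV = c(-178, -125, -121, -78, -71))
  fit5 <- linear_fit_fw(pts)
  expect_equal(round(fit5$r_squared, 2), 0.99)
  expect_equal(fit5$slope, 733, tolerance = 0.001)
  expect_equal(nrow(tidy(fit5)), 2)
  expect_equal(glance(fit5)$nobs, 5)
  # degenerate inputs
  expect_error(linear_fit_fw(data.frame(f_w = c(0.5, 0.5),
                                        phi_w_mV = c(0, 1))), "degenerate")
  # volume-fraction prediction
  expect_equal(predict_phi_from_fraction(1, -540), 0)
  expect_equal(predict_phi_from_fraction(0.74, -540), -140.4)
  expect_equal(predict_phi_from_fraction(0, -540), -540)
})

test_that("multi-frame offset averaging validates frames and the sign convention", {
  s1 <- make_capacitor_slab(5e-4, d = 10, box = c(16, 16, 90))
  res1 <- galvani_offset(s1)
  res_list <- galvani_offset(list(s1))
  expect_equal(res1$phi_w_mV, res_list$phi_w_mV)
  expect_equal(res1$phi_offset_mV, -res1$phi_w_mV)
  expect_equal(res1$f_w + res1$f_r, 1)
  s2 <- make_random_electrolyte(10, c(16, 16, 90), seed = 1)
  expect_error(galvani_offset(list(s1, s2)), "particle counts")
})

test_that("a homogeneous neutral electrolyte has no interfacial offset", {
  # a single snapshot of a point-charge gas is dominated by long-wavelength
  # potential modes, so the per-frame solvent mode fluctuates; without an
  # interfacial dipole layer it is symmetric about zero, and the
  # frame-averaged peak must be statistically indistinguishable from 0
  frames <- lapply(1:16, function(s) {
    make_random_electrolyte(100, box = c(20, 20, 20), seed = 100 + s)
  })
  res <- galvani_offset(frames, bin_width = 25)
  per_frame <- tidy(res)$phi_w_mV
  se <- stats::sd(per_frame) / sqrt(length(per_frame))
  expect_lt(abs(res$phi_w_mV), 3 * se)
  # and it is small compared with the spread of the potential itself
  g1 <- compute_potential_grid(frames[[1]], ewald_params())
  expect_lt(abs(res$phi_w_mV), 0.5 * stats::sd(g1$values))
})
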