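# Seeded synthetic generators with closed-form ground truth.  These stand in
# for the membrane-protein MD systems: a structureless neutral electrolyte
# (bulk water mimic, no interfacial dipole), a membrane-mimicking charged
# slab whose interfacial potential step is known exactly, and Bernoulli
# protonation series drawn from the Henderson-Hasselbalch probability.

#' Random neutral electrolyte fixture
#'
#' `n/2` charges of +1 e and `n/2` of -1 e at uniform random positions in the
#' box, all labeled solvent.  A homogeneous neutral medium has no interfacial
#' dipole layer, so its bulk solvent potential peak sits at ~0 mV.
#'
#' @param n Even number of particles.
#' @param box Box edge lengths (A).
#' @param seed Integer seed; identical seeds give identical systems.
#' @param min_separation Minimum pair distance (A); overlapping draws are
#'   rejected and redrawn.
#' @return A [charge_system()] with attribute `ground_truth`.
#' @export
#' @examples
#' sys <- make_random_electrolyte(50, box = c(20, 20, 20), seed = 1)
#' sum(sys$charges)  # 0
make_random_electrolyte <- function(n, box, seed, min_separation = 1.0) {
  if (n %% 2 != 0) stop("`n` must be even for a neutral system", call. = FALSE)
  box <- as.numeric(box)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    cand <- stats::runif(3) * box
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand, `-`)
      for (ax in 1:3) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
      ok <- min(sqrt(rowSums(d^2))) >= min_separation
    }
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  sys <- charge_system(pos, rep(c(1, -1), each = n / 2), box,
                       species = rep("solvent", n))
  attr(sys, "ground_truth") <- list(kind = "electrolyte", net_charge = 0,
                                    phi_w_mV = 0, seed = seed)
  sys
}

#' Membrane-mimicking charged slab with closed-form interfacial potential
#'
#' Builds a mirror-symmetric slab spanning the box cross-section, the
#' simplest periodic system with an exactly known interior-exterior Galvani
#' potential step.  Each face of the slab carries a dipole layer: a square
#' lattice of charges `-sigma * lattice^2` on the outer sheet and
#' `+sigma * lattice^2` on a sheet a distance `d` inward (negative side
#' facing the solvent, as for a lipid leaflet).  Because the two leaflets
#' mirror each other the cell carries no net dipole, the exterior field
#' vanishes, and the potential is an exact plateau in the solvent and in the
#' slab core.
#'
#' Closed-form ground truth (continuum sheets, tinfoil conventions):
#' interior step `delta_phi = 4 pi k_C sigma d` (converted to mV); the slab
#' interior averages `delta_phi * (1 - d/T)` above the solvent for slab
#' thickness `T`; and the zero box average pins the solvent plateau at
#' `phi_w = -delta_phi * (T - d) / Lz`, equivalently `-f_r` times the mean
#' slab offset with `f_r = T / Lz`.  All of these are returned in the
#' `ground_truth` attribute.
#'
#' Neutral filler particles make the geometry visible to the occupancy
#' classifier without perturbing the potential: a membrane-labeled lattice
#' fills the slab and a solvent-labeled lattice fills the exterior.
#'
#' @param sigma Plate charge density in e/A^2 (magnitude of each sheet).
#' @param d Dipole-layer separation within each leaflet (A).
#' @param box Box edge lengths (A); the slab is normal to z.
#' @param thickness Total slab thickness T (A); must exceed `2 * d`.
#' @param lattice Charged-sheet lattice spacing (A).
#' @param filler_spacing Spacing of the neutral filler lattices (A).
#' @param z_center Slab center along z; default mid-box.
#' @return A [charge_system()] with attribute `ground_truth`.
#' @export
#' @examples
#' slab <- make_capacitor_slab(5e-4, d = 10, box = c(24, 24, 120))
#' attr(slab, "ground_truth")$phi_w_mV
make_capacitor_slab <- function(sigma, d, box, thickness = 30,
                                lattice = 2, filler_spacing = 3,
                                z_center = box[3] / 2) {
  box <- as.numeric(box)
  if (thickness <= 2 * d) {
    stop("`thickness` must exceed 2*d so the slab has an interior core",
         call. = FALSE)
  }
  z_lo <- z_center - thickness / 2
  z_hi <- z_center + thickness / 2
  if (z_lo <= 0 || z_hi >= box[3]) {
    stop("slab touches the periodic boundary; enlarge the box or move ",
         "`z_center`", call. = FALSE)
  }
  xy <- expand.grid(x = seq(lattice / 2, box[1], by = lattice),
                    y = seq(lattice / 2, box[2], by = lattice))
  q_site <- sigma * lattice^2
  sheet <- function(z, q) {
    cbind(as.matrix(xy), z = rep(z, nrow(xy)), q = rep(q, nrow(xy)))
  }
  sheets <- rbind(
    sheet(z_lo,      -q_site),   # lower leaflet, negative face out
    sheet(z_lo + d,  +q_site),
    sheet(z_hi - d,  +q_site),   # upper leaflet, mirrored
    sheet(z_hi,      -q_site)
  )
  fil_xy <- expand.grid(x = seq(filler_spacing / 2, box[1], by = filler_spacing),
                        y = seq(filler_spacing / 2, box[2], by = filler_spacing))
  mem_z <- seq(z_lo, z_hi, by = filler_spacing)
  sol_z <- c(seq(filler_spacing / 2, z_lo - filler_spacing / 2, by = filler_spacing),
             seq(z_hi + filler_spacing / 2, box[3] - filler_spacing / 4,
                 by = filler_spacing))
  filler <- function(zs) {
    do.call(rbind, lapply(zs, function(z) {
      cbind(as.matrix(fil_xy), z = rep(z, nrow(fil_xy)), q = 0)
    }))
  }
  mem_fill <- filler(mem_z)
  sol_fill <- filler(sol_z)
  all <- rbind(sheets, mem_fill, sol_fill)
  species <- c(rep("membrane", nrow(sheets)), rep("membrane", nrow(mem_fill)),
               rep("solvent", nrow(sol_fill)))
  sys <- charge_system(all[, 1:3], all[, 4], box, species = species)

  kC <- .galvanic_constants$coulomb_k
  delta_phi <- kcal_to_mv(4 * pi * kC * sigma * d)      # interior plateau step
  f_r <- thickness / box[3]
  delta_phi_eff <- delta_phi * (1 - d / thickness)      # mean slab offset
  phi_w <- -f_r * delta_phi_eff
  attr(sys, "ground_truth") <- list(
    kind = "capacitor_slab", sigma = sigma, d = d, thickness = thickness,
    delta_phi_mV = delta_phi, delta_phi_eff_mV = delta_phi_eff,
    f_r = f_r, f_w = 1 - f_r, phi_w_mV = phi_w,
    phi_core_mV = delta_phi + phi_w,
    z_lo = z_lo, z_hi = z_hi
  )
  sys
}

#' Bernoulli protonation series with Henderson-Hasselbalch probabilities
#'
#' Emulates the per-snapshot proton counts of constant-pH runs: at each
#' condition, each of `n_sites` independent sites is protonated with
#' probability [analytic_protonation_probability()] for the generator's true
#' pKa, the run pH, and the run Galvani potential.
#'
#' @param pKa True site pKa of the generator.
#' @param conditions Data frame with columns `pH`, `phi_mV`, `n_snapshots`.
#' @param n_sites Number of independent identical sites.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return A run-set tibble (columns `run_id`, `pH`, `phi_mV`, `T_K`,
#'   `snapshot`, `n_protons`) with attributes `n_sites` and `ground_truth`.
#' @export
#' @examples
#' rs <- make_protonation_series(4, data.frame(pH = 4, phi_mV = 0,
#'                                             n_snapshots = 100), seed = 1)
#' mean(rs$n_protons)  # ~0.5
make_protonation_series <- function(pKa, conditions, n_sites = 1,
                                    temperature = .galvanic_constants$T_reference,
                                    seed = 1) {
  stopifnot(all(c("pH", "phi_mV", "n_snapshots") %in% names(conditions)),
            all(conditions$n_snapshots >= 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    ph <- conditions$pH[i]; phi <- conditions$phi_mV[i]
    m <- conditions$n_snapshots[i]
    p <- analytic_protonation_probability(pKa, ph, phi, temperature)
    tibble::tibble(
      run_id = i, pH = ph, phi_mV = phi, T_K = temperature,
      snapshot = seq_len(m),
      n_protons = stats::rbinom(m, size = n_sites, prob = p)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- new_runset(out, n_sites = n_sites)
  attr(out, "ground_truth") <- list(kind = "protonation_series", pKa = pKa,
                                    temperature = temperature, seed = seed)
  out
}

#' Toy titratable-site model with analytic free-energy gap
#'
#' Instantiates the two-state harmonic toy Hamiltonian: unprotonated well
#' `U_u = k x^2 / 2`, protonated well `U_p = k (x - d)^2 / 2 + eps`.  With
#' equal force constants the configurational partition functions cancel, so
#' the model-compound free-energy difference is exactly `deltaG = eps`, and
#' the calibration constant is `C = kB T ln(10) pKa_ref + deltaG`.
#'
#' @param pKa_ref Reference model-compound pKa.
#' @param k Force constant (kcal/mol/A^2).
#' @param d Offset between the two well minima (A).
#' @param eps Energy gap between the wells (kcal/mol); equals the analytic
#'   deltaG.
#' @param n_sites Number of identical independent replicas.
#' @return A list with elements `sites` (list of [titratable_site()]) and
#'   `ground_truth` (analytic deltaG and pKa).
#' @export
make_toy_cph_model <- function(pKa_ref = 4, k = 2, d = 1, eps = 1,
                               n_sites = 1) {
  site <- titratable_site(pKa_ref = pKa_ref, k = k, d = d, eps = eps)
  list(
    sites = replicate(n_sites, site, simplify = FALSE),
    ground_truth = list(deltaG = eps, pKa = pKa_ref)
  )
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
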