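# Toy-scale constant-pH neMD/MC engine.  Each titratable site is a 1D
# particle in one of two harmonic wells (unprotonated / protonated); a cycle
# alternates short equilibrium overdamped Langevin dynamics with a
# nonequilibrium switch of the coupling parameter lambda, accepted by a
# Metropolis criterion on the accumulated (offset-corrected) work.

#' Titratable site of the toy constant-pH model
#'
#' Two-state harmonic site: unprotonated potential `U_u(x) = k x^2 / 2`,
#' protonated `U_p(x) = k (x - d)^2 / 2 + eps`.  Equal force constants make
#' the model-compound free-energy difference analytic, `deltaG = eps`, so
#' the calibration constant `C = kB T ln(10) pKa_ref + deltaG` is exact.
#'
#' @param pKa_ref Reference model-compound pKa.
#' @param deltaQ Charge increment on protonation (e), default +1.
#' @param k Force constant (kcal/mol/A^2).
#' @param d Offset of the protonated well minimum (A).
#' @param eps Energy gap between the wells (kcal/mol).
#' @return An object of class `titratable_site`.
#' @export
titratable_site <- function(pKa_ref = 4, deltaQ = 1, k = 2, d = 1, eps = 1) {
  stopifnot(k > 0)
  structure(list(pKa_ref = pKa_ref, deltaQ = deltaQ, k = k, d = d,
                 eps = eps, deltaG = eps),
            class = "titratable_site")
}

#' Electrostatic environment of the toy model
#'
#' `phi_env` is the Galvani potential felt by the protonated charge (the
#' artifact being modeled: in a periodic simulation this is the bulk-water
#' offset); `phi_offset` is the correction applied to the switching work as
#' `deltaQ_tot * phi_offset`.  The correction is exact when
#' `phi_offset = -phi_env`.
#'
#' @param phi_env_mV Environment Galvani potential (mV).
#' @param phi_offset_mV Applied offset correction (mV).
#' @param temperature Temperature (K).
#' @return An object of class `cph_environment`.
#' @export
cph_environment <- function(phi_env_mV = 0, phi_offset_mV = 0,
                            temperature = .galvanic_constants$T_reference) {
  stopifnot(temperature > 0)
  structure(list(phi_env_mV = phi_env_mV, phi_offset_mV = phi_offset_mV,
                 temperature = temperature),
            class = "cph_environment")
}

#' Nonequilibrium switching protocol
#'
#' The production protocol mirrors the standard constant-pH setup at toy
#' scale: `cycles` neMD/MC cycles, each with `n_equil` equilibrium dynamics
#' steps followed by one attempted protonation-state switch of `n_switch`
#' steps along a linear lambda schedule.  Dynamics are overdamped Langevin
#' with timestep `dt` and friction `friction` (time units arbitrary).
#'
#' @param n_switch Number of lambda increments per switch.
#' @param n_equil Equilibrium dynamics steps per cycle.
#' @param cycles Number of neMD/MC cycles.
#' @param dt Langevin timestep.
#' @param friction Langevin friction coefficient.
#' @return An object of class `switch_protocol`.
#' @export
switch_protocol <- function(n_switch = 200, n_equil = 10, cycles = 400,
                            dt = 0.01, friction = 1) {
  stopifnot(n_switch >= 1, n_equil >= 0, cycles >= 1, dt > 0, friction > 0)
  structure(list(n_switch = n_switch, n_equil = n_equil, cycles = cycles,
                 dt = dt, friction = friction),
            class = "switch_protocol")
}

#' Extended pH-dependent potential of a toy site
#'
#' `U(x, lambda) = (1 - lambda) U_u(x) + lambda * (U_p(x) +
#' deltaQ * phi_env - C + kB T ln(10) pH)` with
#' `C = kB T ln(10) pKa_ref + deltaG`.  At `lambda = 0` this is the
#' unprotonated well; at `lambda = 1` and `pH = pKa_ref`, `phi_env = 0` the
#' two wells are exactly degenerate in free energy.
#'
#' @param x Site coordinate (A); vectorized.
#' @param lambda Coupling parameter in `[0, 1]`.
#' @param site A [titratable_site()].
#' @param env A [cph_environment()].
#' @param pH Simulation pH.
#' @return Energy in kcal/mol.
#' @export
extended_potential <- function(x, lambda, site, env, pH) {
  if (any(lambda < 0 | lambda > 1)) {
    stop("`lambda` must lie in [0, 1]", call. = FALSE)
  }
  kT <- kBT(env$temperature)
  C <- kT * log(10) * site$pKa_ref + site$deltaG
  U_u <- 0.5 * site$k * x^2
  U_p <- 0.5 * site$k * (x - site$d)^2 + site$eps
  shift <- site$deltaQ * mv_to_kcal(env$phi_env_mV) - C + kT * log(10) * pH
  (1 - lambda) * U_u + lambda * (U_p + shift)
}

# force of the extended potential (analytic, x scalar or vector)
extended_force <- function(x, lambda, site) {
  -((1 - lambda) * site$k * x + lambda * site$k * (x - site$d))
}

# one overdamped Langevin (Euler-Maruyama) step at fixed lambda
langevin_step <- function(x, lambda, site, protocol, kT) {
  mob <- protocol$dt / protocol$friction
  x + mob * extended_force(x, lambda, site) +
    sqrt(2 * kT * mob) * stats::rnorm(length(x))
}

#' Nonequilibrium switching work
#'
#' Drives the coupling parameter from `lambda` to `lambda_to` over
#' `protocol$n_switch` equal increments, alternating a lambda increment
#' (accumulating `U(x; lambda_next) - U(x; lambda)` into the work) with one
#' Langevin dynamics substep at the new lambda.  For `n_switch = 1` the work
#' is the instantaneous endpoint energy difference.
#'
#' @param x Current site coordinate.
#' @param lambda,lambda_to Endpoint coupling values in `{0, 1}`.
#' @inheritParams extended_potential
#' @param protocol A [switch_protocol()].
#' @return List with `work` (kcal/mol) and `x_end` (coordinate after the
#'   switch).
#' @export
switch_work <- function(x, lambda, lambda_to, site, env, pH, protocol) {
  stopifnot(lambda %in% c(0, 1), lambda_to %in% c(0, 1), lambda != lambda_to)
  kT <- kBT(env$temperature)
  n <- protocol$n_switch
  dl <- (lambda_to - lambda) / n
  # the potential is linear in lambda, so each increment contributes
  # dl * (U_p(x) + shift - U_u(x)) at the current coordinate
  C <- kT * log(10) * site$pKa_ref + site$deltaG
  shift <- site$deltaQ * mv_to_kcal(env$phi_env_mV) - C + kT * log(10) * pH
  k <- site$k; d <- site$d; eps <- site$eps
  mob <- protocol$dt / protocol$friction
  noise_sd <- sqrt(2 * kT * mob)
  xi <- stats::rnorm(n, sd = noise_sd)
  W <- 0
  lam <- lambda
  for (i in seq_len(n)) {
    W <- W + dl * (0.5 * k * ((x - d)^2 - x^2) + eps + shift)
    lam <- lambda + i * dl
    x <- x + mob * (-((1 - lam) * k * x + lam * k * (x - d))) + xi[i]
  }
  if (!is.finite(W)) stop("non-finite switching work", call. = FALSE)
  list(work = W, x_end = x)
}

#' Galvani offset correction of the switching work
#'
#' `W_corr = W + deltaQ_tot * phi_offset`, with the mV to kcal/mol
#' conversion routed through [phys_constants()].  `deltaQ_tot` is the total
#' charge increment of the attempted move (in e): `+1` for a single-site
#' protonation, `-1` for a deprotonation.
#'
#' @param W Raw switching work (kcal/mol).
#' @param deltaQ_tot Total charge increment (e).
#' @param phi_offset_mV Offset potential (mV).
#' @return Corrected work in kcal/mol.
#' @export
#' @examples
#' corrected_work(0, 1, 178)  # +4.105 kcal/mol
corrected_work <- function(W, deltaQ_tot, phi_offset_mV) {
  W + deltaQ_tot * mv_to_kcal(phi_offset_mV)
}

#' Metropolis acceptance on the corrected work
#'
#' Accepts with probability `min(1, exp(-W_corr / kB T))`.
#'
#' @param W_corr Corrected work (kcal/mol).
#' @param temperature Temperature (K).
#' @return Logical, `TRUE` when the move is accepted.
#' @export
metropolis_accept <- function(W_corr,
                              temperature = .galvanic_constants$T_reference) {
  stopifnot(temperature > 0)
  if (W_corr <= 0) return(TRUE)
  stats::runif(1) < exp(-W_corr / kBT(temperature))
}

#' Run a toy constant-pH neMD/MC simulation
#'
#' Per cycle: equilibrium Langevin dynamics on every site at its current
#' protonation state, a uniformly random site pick, a proposed deterministic
#' flip of that site's lambda, a nonequilibrium switch accumulating the
#' work, the Galvani offset correction, and a Metropolis test on the
#' corrected work.  Rejected attempts restore the pre-switch state exactly.
#' Only endpoint states (lambda 0 or 1) are ever retained.
#'
#' Site occupancies are initialized from the analytic protonation
#' probability at the run's effective potential so short runs start near
#' stationarity.
#'
#' @param sites A [titratable_site()] or list of them (independent sites).
#' @param env A [cph_environment()].
#' @param protocol A [switch_protocol()].
#' @param pH Simulation pH.
#' @param seed Integer seed.
#' @return A tibble of class `cph_trajectory` with one row per cycle
#'   (`cycle`, `site`, `dn`, `work`, `work_corr`, `accepted`, `n_protons`)
#'   and attributes `pH`, `phi_env_mV`, `phi_offset_mV`, `temperature`,
#'   `n_sites`, `seed`, `occupancy` (cycles x sites matrix) and
#'   `acceptance_rate`.
#' @export
run_constant_pH <- function(sites, env = cph_environment(),
                            protocol = switch_protocol(), pH, seed = 1) {
  if (inherits(sites, "titratable_site")) sites <- list(sites)
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, TRUE, "titratable_site")))
  ns <- length(sites)
  kT <- kBT(env$temperature)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # effective residual potential felt by the chain
  phi_eff <- env$phi_env_mV + env$phi_offset_mV
  occ <- vapply(sites, function(s) {
    p <- analytic_protonation_probability(s$pKa_ref, pH, phi_eff,
                                          env$temperature, s$deltaQ)
    as.numeric(stats::runif(1) < p)
  }, 1.0)
  x <- vapply(sites, function(s) 0, 1.0)

  n_cyc <- protocol$cycles
  rec_site <- integer(n_cyc); rec_dn <- integer(n_cyc)
  rec_W <- numeric(n_cyc); rec_Wc <- numeric(n_cyc)
  rec_acc <- logical(n_cyc); rec_np <- integer(n_cyc)
  occ_mat <- matrix(NA_real_, n_cyc, ns)

  ks <- vapply(sites, `[[`, 1.0, "k")
  ds <- vapply(sites, `[[`, 1.0, "d")
  mob <- protocol$dt / protocol$friction
  noise_sd <- sqrt(2 * kT * mob)
  for (cyc in seq_len(n_cyc)) {
    for (step in seq_len(protocol$n_equil)) {
      x <- x + mob * (-((1 - occ) * ks * x + occ * ks * (x - ds))) +
        stats::rnorm(ns, sd = noise_sd)
    }
    i <- if (ns == 1) 1L else sample.int(ns, 1)
    lam_to <- 1 - occ[i]
    sw <- switch_work(x[i], occ[i], lam_to, sites[[i]], env, pH, protocol)
    dn <- as.integer(lam_to - occ[i])
    dq <- dn * sites[[i]]$deltaQ
    Wc <- corrected_work(sw$work, dq, env$phi_offset_mV)
    acc <- metropolis_accept(Wc, env$temperature)
    if (acc) {
      occ[i] <- lam_to
      x[i] <- sw$x_end
    }
    rec_site[cyc] <- i; rec_dn[cyc] <- dn
    rec_W[cyc] <- sw$work; rec_Wc[cyc] <- Wc
    rec_acc[cyc] <- acc; rec_np[cyc] <- sum(occ)
    occ_mat[cyc, ] <- occ
  }

  out <- tibble::tibble(
    cycle = seq_len(n_cyc), site = rec_site, dn = rec_dn,
    work = rec_W, work_corr = rec_Wc, accepted = rec_acc,
    n_protons = rec_np
  )
  tibble::new_tibble(
    out, pH = pH, phi_env_mV = env$phi_env_mV,
    phi_offset_mV = env$phi_offset_mV, temperature = env$temperature,
    n_sites = ns, seed = seed, occupancy = occ_mat,
    acceptance_rate = mean(rec_acc),
    class = "cph_trajectory"
  )
}

#' Analytic Henderson-Hasselbalch protonation probability
#'
#' `p = 1 / (1 + 10^(pH - pKa_app))` with the apparent pKa shifted by the
#' environment potential, `pKa_app = pKa - deltaQ * e * phi_env / (kB T
#' ln 10)`.  A potential of -59.16 mV at 298.15 K is equivalent to lowering
#' the pH by exactly one unit.
#'
#' @param pKa Reference pKa.
#' @param pH Solution pH.
#' @param phi_env_mV Environment Galvani potential (mV).
#' @param temperature Temperature (K).
#' @param deltaQ Charge increment on protonation (e).
#' @return Protonation probability in `[0, 1]`.
#' @export
#' @examples
#' analytic_protonation_probability(4, 4)        # 0.5
#' analytic_protonation_probability(4, 5)        # 1/11
analytic_protonation_probability <- function(pKa, pH, phi_env_mV = 0,
                                             temperature = .galvanic_constants$T_reference,
                                             deltaQ = 1) {
  stopifnot(temperature > 0)
  pKa_app <- pKa - deltaQ * mv_to_kcal(phi_env_mV) /
    (kBT(temperature) * log(10))
  1 / (1 + 10^(pH - pKa_app))
}

#' Collect constant-pH trajectories into a run set
#'
#' Converts per-cycle proton counts of one or more [run_constant_pH()]
#' trajectories into the tabular run-set format consumed by the WHAM
#' titration module.  Each trajectory is labeled with its pH and, by
#' default, the residual effective potential `phi_env + phi_offset` it
#' actually sampled; pass `phi_label = 0` to analyze runs "as recorded",
#' i.e. unaware of any uncorrected environment potential.
#'
#' @param trajectories A `cph_trajectory` or list of them.
#' @param phi_label Either `"effective"` (default) or a numeric potential in
#'   mV applied to every run.
#' @param burn_in Number of initial cycles to drop per run.
#' @return A run-set tibble (see [make_protonation_series()] for columns).
#' @export
runs_from_trajectories <- function(trajectories, phi_label = "effective",
                                   burn_in = 0) {
  if (inherits(trajectories, "cph_trajectory")) {
    trajectories <- list(trajectories)
  }
  ns <- unique(vapply(trajectories, function(t) attr(t, "n_sites"), 1L))
  stopifnot(length(ns) == 1)
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    keep <- tr$cycle > burn_in
    phi <- if (identical(phi_label, "effective")) {
      attr(tr, "phi_env_mV") + attr(tr, "phi_offset_mV")
    } else as.numeric(phi_label)
    tibble::tibble(
      run_id = i, pH = attr(tr, "pH"), phi_mV = phi,
      T_K = attr(tr, "temperature"),
      snapshot = seq_len(sum(keep)), n_protons = tr$n_protons[keep]
    )
  })
  new_runset(dplyr::bind_rows(rows), n_sites = ns)
}
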