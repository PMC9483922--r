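# Binless WHAM over constant-pH runs at multiple (pH, Galvani potential)
# conditions.  Because the condition-dependent part of the reduced energy is
# linear in the total proton count n, snapshots collapse onto the distinct n
# values with multiplicities, and all arithmetic is carried out in log space.

new_runset <- function(df, n_sites) {
  stopifnot(all(c("run_id", "pH", "phi_mV", "T_K", "snapshot",
                  "n_protons") %in% names(df)))
  if (any(df$n_protons < 0) || any(df$n_protons > n_sites) ||
      any(df$n_protons != round(df$n_protons))) {
    stop("proton counts must be integers in [0, n_sites]", call. = FALSE)
  }
  tibble::new_tibble(df, n_sites = as.integer(n_sites), class = "runset")
}

#' Run-set constructor
#'
#' Bundles constant-pH run records (per-snapshot total proton counts with
#' their run pH, Galvani potential and temperature) into the tabular form
#' used by [solve_wham()] and [titration_curve()].
#'
#' @param df Data frame with columns `run_id`, `pH`, `phi_mV`, `T_K`,
#'   `snapshot`, `n_protons`.
#' @param n_sites Total number of titratable sites bounding the counts.
#' @return A tibble of class `runset`.
#' @export
as_runset <- function(df, n_sites) new_runset(tibble::as_tibble(df), n_sites)

#' Dimensionless reduced energy of a snapshot under a condition
#'
#' The condition-dependent part of the extended potential for a snapshot
#' with total proton count `n` evaluated at condition `(pH_j, phi_j)`:
#' `u_j(n) = n ln(10) pH_j + n deltaQ phi_j / (kB T)`.
#' Condition-independent configurational terms are dropped; they cancel in
#' every WHAM difference.
#'
#' @param n Total proton count (vectorized).
#' @param pH Condition pH.
#' @param phi_mV Condition Galvani potential (mV).
#' @param temperature Temperature (K).
#' @param deltaQ Charge increment per proton (e).
#' @return Dimensionless energy.
#' @export
#' @examples
#' reduced_energy(1, 5, 0) - reduced_energy(1, 4, 0)  # ln 10
reduced_energy <- function(n, pH, phi_mV,
                           temperature = .galvanic_constants$T_reference,
                           deltaQ = 1) {
  stopifnot(temperature > 0)
  n * log(10) * pH + n * deltaQ * mv_to_kcal(phi_mV) / kBT(temperature)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve the binless WHAM equations
#'
#' Self-consistent solution for the per-condition dimensionless free
#' energies `f_k` over all snapshots of a run set, with the gauge
#' `f[1] = 0`.  Conditions carrying zero snapshots (appended analysis
#' conditions) are permitted and do not influence the sampled-condition
#' free energies.  All sums are evaluated in log space.
#'
#' @param runs A run-set tibble ([as_runset()], [make_protonation_series()]
#'   or [runs_from_trajectories()]).
#' @param conditions Optional data frame with columns `pH` and `phi_mV` of
#'   extra zero-snapshot conditions to append after the sampled ones.
#' @param tol Convergence tolerance on `max |delta f|` (default 1e-8).
#' @param max_iter Maximum self-consistent iterations.
#' @param deltaQ Charge increment per proton (e).
#' @return An object of class `wham_solution`: a conditions tibble (`pH`,
#'   `phi_mV`, `n_snapshots`, `f`), iteration count, final residual, and the
#'   collapsed snapshot table used for [wham_expectation()].
#' @export
solve_wham <- function(runs, conditions = NULL, tol = 1e-8, max_iter = 1e5,
                       deltaQ = 1) {
  stopifnot(inherits(runs, "runset"))
  if (nrow(runs) == 0) stop("empty run set", call. = FALSE)
  temperature <- unique(runs$T_K)
  if (length(temperature) != 1) {
    stop("all runs must share one temperature", call. = FALSE)
  }
  sampled <- dplyr::summarise(
    dplyr::group_by(runs, .data$pH, .data$phi_mV),
    n_snapshots = dplyr::n(), .groups = "drop")
  cond <- sampled
  if (!is.null(conditions)) {
    extra <- tibble::tibble(pH = conditions$pH, phi_mV = conditions$phi_mV,
                            n_snapshots = 0L)
    cond <- dplyr::bind_rows(cond, extra)
  }
  K <- nrow(cond)

  # collapse snapshots: u_k depends on a snapshot only through n
  tab <- dplyr::count(runs, n = .data$n_protons, name = "weight")
  M <- nrow(tab)
  u <- matrix(0, K, M)          # u[k, m] = reduced energy of count m at k
  for (k in seq_len(K)) {
    u[k, ] <- reduced_energy(tab$n, cond$pH[k], cond$phi_mV[k],
                             temperature, deltaQ)
  }
  logN <- ifelse(cond$n_snapshots > 0, log(cond$n_snapshots), -Inf)
  logw <- log(tab$weight)

  f <- numeric(K)
  resid <- Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    # log denominator per collapsed snapshot
    logden <- vapply(seq_len(M), function(m) {
      logsumexp(logN + f - u[, m])
    }, 1.0)
    f_new <- vapply(seq_len(K), function(k) {
      -logsumexp(logw - u[k, ] - logden)
    }, 1.0)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid <= tol || iter >= max_iter) break
  }
  if (resid > tol) {
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", format(resid), ")", call. = FALSE)
  }
  cond$f <- f
  structure(
    list(conditions = cond, iterations = iter, residual = resid,
         snapshots = tab, temperature = temperature, deltaQ = deltaQ,
         n_sites = attr(runs, "n_sites")),
    class = "wham_solution"
  )
}

#' @export
print.wham_solution <- function(x, ...) {
  cat("<wham_solution> ", nrow(x$conditions), " conditions, ",
      sum(x$snapshots$weight), " snapshots, ", x$iterations,
      " iterations (residual ", format(x$residual, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' Reweighted expectation under a WHAM solution
#'
#' Importance-weighted average of a per-snapshot observable at one of the
#' solution's conditions, with normalized weights computed in log space.
#'
#' @param solution A [solve_wham()] result.
#' @param condition Index into `solution$conditions`.
#' @param observable Function of the proton count `n` returning the
#'   per-snapshot observable (default the count itself).
#' @return The expectation at that condition.
#' @export
wham_expectation <- function(solution, condition,
                             observable = function(n) n) {
  stopifnot(inherits(solution, "wham_solution"))
  cond <- solution$conditions
  stopifnot(condition >= 1, condition <= nrow(cond))
  tab <- solution$snapshots
  logN <- ifelse(cond$n_snapshots > 0, log(cond$n_snapshots), -Inf)
  logden <- vapply(seq_len(nrow(tab)), function(m) {
    u_m <- reduced_energy(tab$n[m], cond$pH, cond$phi_mV,
                          solution$temperature, solution$deltaQ)
    logsumexp(logN + cond$f - u_m)
  }, 1.0)
  u_k <- reduced_energy(tab$n, cond$pH[condition], cond$phi_mV[condition],
                        solution$temperature, solution$deltaQ)
  logwk <- log(tab$weight) - u_k - logden
  logZ <- logsumexp(logwk)
  if (!is.finite(logZ)) {
    stop("all snapshot weights vanish at this condition", call. = FALSE)
  }
  wts <- exp(logwk - logZ)
  sum(wts * vapply(tab$n, observable, 1.0))
}

#' WHAM titration curve over a pH grid
#'
#' Appends the requested `(pH, phi)` grid as zero-snapshot conditions,
#' solves the binless WHAM equations once over sampled and appended
#' conditions together, and reports the mean protonated fraction at every
#' grid point, together with a Henderson-Hasselbalch pKa fit.
#'
#' @param runs A run-set tibble.
#' @param pH_grid Numeric vector of pH values for the curve.
#' @param phi_mV Galvani potential at which the curve is evaluated
#'   (default 0, the corrected bulk reference).
#' @param ... Passed to [solve_wham()].
#' @return A tibble of class `titration_curve` (columns `pH`, `phi_mV`,
#'   `fraction`) with attributes `fit` (a `pka_fit`), `pKa` and `solution`.
#' @export
titration_curve <- function(runs, pH_grid, phi_mV = 0, ...) {
  stopifnot(inherits(runs, "runset"), length(pH_grid) >= 2)
  grid <- tibble::tibble(pH = as.numeric(pH_grid), phi_mV = phi_mV)
  sol <- solve_wham(runs, conditions = grid, ...)
  K <- nrow(sol$conditions)
  idx <- seq(K - nrow(grid) + 1, K)
  ns <- sol$n_sites
  frac <- vapply(idx, function(k) {
    wham_expectation(sol, k) / ns
  }, 1.0)
  out <- tibble::tibble(pH = grid$pH, phi_mV = grid$phi_mV, fraction = frac)
  out <- out[order(out$pH), ]
  fit <- fit_pka(out)
  tibble::new_tibble(out, fit = fit, pKa = fit$pKa, solution = sol,
                     class = "titration_curve")
}

#' Henderson-Hasselbalch pKa fit of a titration curve
#'
#' One-parameter least-squares fit of `f(pH) = 1 / (1 + 10^(pH - pKa))`
#' (unit Hill coefficient, independent sites).  An optional Hill exponent
#' can be co-fitted but is off by default.  If the curve does not span its
#' midpoint (no fraction on both sides of 0.5) the fit is flagged as
#' extrapolated with a warning.
#'
#' @param curve Data frame with columns `pH` and `fraction`.
#' @param hill If `TRUE`, also fit a Hill exponent.
#' @return An object of class `pka_fit` with elements `pKa`, `hill`, `sse`,
#'   `n` and `extrapolated`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
#' @examples
#' ph <- seq(2, 6, 0.5)
#' fit_pka(data.frame(pH = ph, fraction = 1 / (1 + 10^(ph - 4))))$pKa  # 4
fit_pka <- function(curve, hill = FALSE) {
  stopifnot(all(c("pH", "fraction") %in% names(curve)))
  ph <- curve$pH; fr <- curve$fraction
  extrapolated <- !(any(fr > 0.5) && any(fr < 0.5))
  if (extrapolated) {
    warning("titration curve does not span its midpoint; ",
            "fitted pKa is an extrapolation", call. = FALSE)
  }
  lo <- min(ph) - 6; hi <- max(ph) + 6
  if (!hill) {
    sse <- function(pka) sum((fr - 1 / (1 + 10^(ph - pka)))^2)
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
    res <- list(pKa = opt$minimum, hill = 1, sse = opt$objective)
  } else {
    obj <- function(par) {
      sum((fr - 1 / (1 + 10^(par[2] * (ph - par[1]))))^2)
    }
    opt <- stats::optim(c(mean(ph), 1), obj, method = "L-BFGS-B",
                        lower = c(lo, 0.1), upper = c(hi, 10))
    res <- list(pKa = opt$par[1], hill = opt$par[2], sse = opt$value)
  }
  structure(c(res, list(n = length(ph), extrapolated = extrapolated)),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("<pka_fit> pKa = %.3f (hill = %.2f, sse = %.3g, n = %d)%s\n",
              x$pKa, x$hill, x$sse, x$n,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Galvani-potential to pKa-shift conversion
#'
#' `delta pKa = e * delta phi / (kB T ln 10)`: the apparent pKa shift
#' induced by a bulk Galvani potential difference.  At 298.15 K one pKa
#' unit corresponds to 59.16 mV.
#'
#' @param delta_phi_mV Potential difference in mV.
#' @param temperature Temperature (K).
#' @return pKa shift (pH units).
#' @export
#' @examples
#' delta_pka(59.16)       # ~1
#' delta_pka(78, 310)     # ~1.27
delta_pka <- function(delta_phi_mV,
                      temperature = .galvanic_constants$T_reference) {
  stopifnot(temperature > 0)
  mv_to_kcal(delta_phi_mV) / (kBT(temperature) * log(10))
}
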