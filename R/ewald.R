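# Tinfoil Ewald summation for orthorhombic periodic point-charge systems.
#
# The reciprocal-space potential of Gaussian-smeared charges is
#   phi(r) = k_C * (4*pi/V) * sum_{k != 0} exp(-k^2/(4 beta^2)) / k^2 *
#            sum_j q_j exp(i k.(r - r_j))
# Dropping k = 0 pins the box-average potential to zero (tinfoil boundary
# conditions) and implicitly neutralizes non-neutral systems with a uniform
# background.  compute_potential_grid() evaluates this on a regular lattice
# via an FFT over the structure factor; direct_ksum_potential() is the naive
# explicit k-sum used as its oracle; exact_ewald_potential() adds the
# complementary erfc short-range term to recover the point-charge potential.

# signed FFT frequency indices 0,1,...,-1 for length n
fft_freqs <- function(n) {
  m <- 0:(n - 1)
  ifelse(m <= (n - 1) %/% 2, m, m - n)
}

#' Tinfoil Ewald potential on a regular grid
#'
#' Computes the reciprocal-space (Gaussian-smeared) Ewald potential of a
#' periodic point-charge system at every node of a regular lattice, with the
#' k = 0 Fourier component omitted.  The result is the exact periodic
#' potential of the smeared charge density, in millivolts, and its volume
#' average is zero by construction.
#'
#' The structure factor is accumulated exactly (no charge-assignment
#' interpolation), so the map agrees with the explicit summation of
#' [direct_ksum_potential()] to floating-point accuracy when the same
#' k-space cutoff is used.
#'
#' @param system A [charge_system()].
#' @param params An [ewald_params()]; `params$kmax = NULL` uses every mode
#'   representable on the grid.
#' @param dims Integer grid dimensions (nx, ny, nz); default
#'   [grid_dims_for_box()] at 1 A spacing.
#' @return A [potential_grid()] in mV.
#' @export
#' @examples
#' sys <- make_random_electrolyte(20, box = c(12, 12, 12), seed = 1)
#' g <- compute_potential_grid(sys, ewald_params(), dims = c(12, 12, 12))
#' box_average(g)   # ~0: tinfoil constraint
compute_potential_grid <- function(system, params = ewald_params(),
                                   dims = grid_dims_for_box(system$box)) {
  stopifnot(inherits(system, "charge_system"))
  check_params_for_box(params, system$box)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) {
    stop("`dims` must be three positive integers", call. = FALSE)
  }
  box <- system$box
  spacing <- box / dims
  # the grid must resolve the smeared charges: Gaussian width 1/beta
  if (max(spacing) > 2 / params$smear_width) {
    stop("grid spacing ", format(max(spacing)),
         " A is coarser than twice the smearing length ",
         format(1 / params$smear_width), " A; increase `dims`", call. = FALSE)
  }
  beta <- params$smear_width
  V <- prod(box)
  pos <- wrap_positions(system$positions, box)
  q <- system$charges
  live <- q != 0
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  kx <- 2 * pi * fft_freqs(nx) / box[1]
  ky <- 2 * pi * fft_freqs(ny) / box[2]
  kz <- 2 * pi * fft_freqs(nz) / box[3]

  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  amp <- array(0, dims)
  nonzero <- k2 > 0
  amp[nonzero] <- .galvanic_constants$coulomb_k * (4 * pi / V) *
    exp(-k2[nonzero] / (4 * beta^2)) / k2[nonzero]
  if (!is.null(params$kmax)) {
    nmax <- params$kmax
    keep <- outer(outer(abs(fft_freqs(nx)) <= nmax,
                        abs(fft_freqs(ny)) <= nmax, `&`),
                  abs(fft_freqs(nz)) <= nmax, `&`)
    amp[!keep] <- 0
  }

  if (!any(live)) {
    vals <- array(0, dims)
    return(potential_grid(vals, box))
  }
  # structure factor S(k) = sum_j q_j exp(-i k.r_j), accumulated as a
  # complex matrix product over the separable per-axis phase factors
  px <- pos[live, 1]; py <- pos[live, 2]; pz <- pos[live, 3]
  Ex <- exp(outer(-1i * kx, px))                  # nx x N
  Ey <- exp(outer(-1i * ky, py))                  # ny x N
  Ez <- exp(outer(-1i * kz, pz))                  # nz x N
  XY <- Ex[rep(seq_len(nx), times = ny), , drop = FALSE] *
        Ey[rep(seq_len(ny), each = nx), , drop = FALSE]   # (nx*ny) x N
  S <- XY %*% (q[live] * t(Ez))                   # (nx*ny) x nz
  S <- array(S, dims)

  vals <- Re(stats::fft(amp * S, inverse = TRUE))
  potential_grid(kcal_to_mv(vals), box)
}

# enumerate reciprocal vectors with per-axis |n| <= kmax, excluding k = 0
kvector_table <- function(box, kmax) {
  n <- -kmax:kmax
  g <- expand.grid(nx = n, ny = n, nz = n)
  g <- g[!(g$nx == 0 & g$ny == 0 & g$nz == 0), , drop = FALSE]
  cbind(2 * pi * g$nx / box[1], 2 * pi * g$ny / box[2], 2 * pi * g$nz / box[3])
}

#' Naive reciprocal-space Ewald potential at arbitrary points
#'
#' Explicit double summation over charges and reciprocal vectors with
#' per-axis index `|n| <= kmax` (k = 0 excluded), without any FFT.  Serves
#' as an independent oracle for [compute_potential_grid()]; intended for at
#' most a few hundred charges.
#'
#' @param system A [charge_system()].
#' @param params An [ewald_params()] with finite `kmax`.
#' @param points Matrix of probe coordinates (rows = points, columns x,y,z).
#' @return Numeric vector of potentials in mV, one per probe point.
#' @export
direct_ksum_potential <- function(system, params, points) {
  stopifnot(inherits(system, "charge_system"))
  if (is.null(params$kmax)) {
    stop("direct_ksum_potential() requires a finite `kmax`", call. = FALSE)
  }
  points <- matrix(as.numeric(points), ncol = 3)
  if (params$kmax == 0) return(rep(0, nrow(points)))
  box <- system$box
  beta <- params$smear_width
  V <- prod(box)
  K <- kvector_table(box, params$kmax)
  k2 <- rowSums(K^2)
  amp <- .galvanic_constants$coulomb_k * (4 * pi / V) *
    exp(-k2 / (4 * beta^2)) / k2
  # S_k = sum_j q_j exp(-i k.r_j)
  phase_q <- K %*% t(system$positions)            # M x N
  S <- as.vector(exp(-1i * phase_q) %*% system$charges)
  phase_p <- K %*% t(points)                      # M x P
  pot <- as.vector(t(exp(1i * phase_p)) %*% (amp * S))
  kcal_to_mv(Re(pot))
}

#' Exact Ewald potential (reciprocal plus short-range erfc term)
#'
#' Full Ewald potential of the periodic point-charge system at arbitrary
#' probe points: the Gaussian-smeared reciprocal sum of
#' [direct_ksum_potential()] plus the complementary short-range term
#' `k_C q erfc(beta r)/r` over minimum images within `rcut`.  When a probe
#' point coincides with a charge, that charge's smeared self-potential
#' `2 beta k_C q / sqrt(pi)` is subtracted and its singular direct term is
#' skipped, so the result is the potential created by all other charges and
#' all periodic images.  For converged cutoffs the result is independent of
#' `smear_width`.
#'
#' @inheritParams direct_ksum_potential
#' @return Numeric vector of potentials in mV.
#' @export
exact_ewald_potential <- function(system, params, points) {
  stopifnot(inherits(system, "charge_system"))
  if (params$mode != "exact") {
    stop("exact_ewald_potential() requires `mode = \"exact\"`", call. = FALSE)
  }
  check_params_for_box(params, system$box)
  points <- matrix(as.numeric(points), ncol = 3)
  box <- system$box
  beta <- params$smear_width
  kC <- .galvanic_constants$coulomb_k

  # distinct charges at identical coordinates have a divergent interaction
  pos <- wrap_positions(system$positions, box)
  if (nrow(pos) > 1 && nrow(pos) <= 2000) {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    if (min(d) < 1e-8) {
      stop("two distinct charges coincide: singular configuration",
           call. = FALSE)
    }
  }

  recip <- mv_to_kcal(direct_ksum_potential(system, params, points))
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    dvec <- sweep(pos, 2, points[p, ], `-`)
    for (ax in 1:3) {
      dvec[, ax] <- dvec[, ax] - box[ax] * round(dvec[, ax] / box[ax])
    }
    r <- sqrt(rowSums(dvec^2))
    self <- r < 1e-8
    near <- !self & r <= params$rcut
    direct <- sum(kC * system$charges[near] *
                    erfc_vec(beta * r[near]) / r[near])
    selfterm <- sum(2 * beta * kC * system$charges[self] / sqrt(pi))
    out[p] <- recip[p] + direct - selfterm
  }
  kcal_to_mv(out)
}

# complementary error function via pnorm (no extra dependency)
erfc_vec <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
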