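# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's Ewald code paths: real-space lattice summation and
# quadrature only.

# Madelung constant of rock salt by Evjen's expanding-cube summation:
# charges on the simple-cubic +-1 lattice, boundary sites weighted by the
# fraction of the cube they occupy (1/2 face, 1/4 edge, 1/8 corner).
evjen_madelung <- function(m) {
  idx <- -m:m
  g <- expand.grid(i = idx, j = idx, k = idx)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  sgn <- (-1)^(abs(g$i) + abs(g$j) + abs(g$k))
  w <- (1 - 0.5 * (abs(g$i) == m)) *
       (1 - 0.5 * (abs(g$j) == m)) *
       (1 - 0.5 * (abs(g$k) == m))
  r <- sqrt(g$i^2 + g$j^2 + g$k^2)
  sum(sgn * w / r)
}

# Potential (kcal/mol per e) at `point` from periodic images of a charge
# set, summed over expanding cubes of image cells.  Only valid for cells
# with zero net charge AND zero net dipole, for which the cube-ordered sum
# converges to the tinfoil Ewald value (no shape-dependent surface term).
image_sum_potential <- function(positions, charges, box, point, shells) {
  kC <- 332.0637
  total <- 0
  idx <- -shells:shells
  shifts <- as.matrix(expand.grid(nx = idx, ny = idx, nz = idx))
  for (j in seq_along(charges)) {
    dv <- matrix(point - positions[j, ], nrow(shifts), 3, byrow = TRUE) +
      shifts %*% diag(box)
    r <- sqrt(rowSums(dv^2))
    total <- total + kC * charges[j] * sum(1 / r)
  }
  total
}

# Model-compound free-energy difference by numerical thermodynamic
# integration over lambda: dG = int_0^1 <U_p - U_u>_lambda dlambda with the
# configurational average evaluated by 1D quadrature at each lambda node
# (Simpson's rule over lambda).
ti_delta_g <- function(site, temperature = 298.15, n_lambda = 41) {
  kT <- 1.987204e-3 * temperature
  U_u <- function(x) 0.5 * site$k * x^2
  U_p <- function(x) 0.5 * site$k * (x - site$d)^2 + site$eps
  mean_dudl <- function(lam) {
    U <- function(x) (1 - lam) * U_u(x) + lam * U_p(x)
    Z <- stats::integrate(function(x) exp(-(U(x) - U(lam * site$d)) / kT),
                          -Inf, Inf)$value
    num <- stats::integrate(function(x) {
      (U_p(x) - U_u(x)) * exp(-(U(x) - U(lam * site$d)) / kT)
    }, -Inf, Inf)$value
    num / Z
  }
  lam <- seq(0, 1, length.out = n_lambda)
  y <- vapply(lam, mean_dudl, 1.0)
  h <- lam[2] - lam[1]
  # Simpson composite (n_lambda odd)
  h / 3 * (y[1] + y[n_lambda] +
             4 * sum(y[seq(2, n_lambda - 1, 2)]) +
             2 * sum(y[seq(3, n_lambda - 2, 2)]))
}

# shared toy model used across engine tests
toy_site <- function(...) titratable_site(pKa_ref = 4, k = 2, d = 1,
                                          eps = 1, ...)
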