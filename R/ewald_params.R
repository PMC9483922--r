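#' Parameters of the tinfoil Ewald summation
#'
#' Controls the Gaussian charge smearing and the reciprocal / real space
#' truncation used by [compute_potential_grid()], [direct_ksum_potential()]
#' and [exact_ewald_potential()].
#'
#' In `"smoothed"` mode only the reciprocal-space sum of Gaussian-smeared
#' charges is evaluated (the convention of grid-based potential-map tools):
#' the map is the exact electrostatic potential of the periodic system of
#' Gaussian charges of width `1/smear_width`, with the k = 0 term dropped
#' (tinfoil conventions, implicit neutralizing background).  In `"exact"`
#' mode the complementary short-range erfc term over minimum images within
#' `rcut` is added, giving the true point-charge Ewald potential, which is
#' independent of `smear_width`.
#'
#' @param smear_width Gaussian smearing parameter beta (1/angstrom); the
#'   smeared charge density is proportional to exp(-beta^2 r^2).  Default
#'   0.25 1/A for potential maps.
#' @param kmax Per-axis reciprocal-space cutoff (integer >= 1): wave vectors
#'   k = 2*pi*(nx/Lx, ny/Ly, nz/Lz) with max(|n|) <= kmax are summed.  `NULL`
#'   (default) lets [compute_potential_grid()] use every mode representable
#'   on its grid; the explicit summation operations require a finite value.
#' @param rcut Real-space cutoff in angstrom, exact mode only; must be less
#'   than half the smallest box edge so that minimum images suffice.
#' @param mode `"smoothed"` or `"exact"`.
#'
#' @return An object of class `ewald_params`.
#' @export
#' @examples
#' ewald_params(smear_width = 0.25, kmax = 8)
ewald_params <- function(smear_width = 0.25, kmax = NULL, rcut = NULL,
                         mode = c("smoothed", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(smear_width) || length(smear_width) != 1 || smear_width <= 0) {
    stop("`smear_width` must be a single positive number (1/A)", call. = FALSE)
  }
  if (!is.null(kmax)) {
    kmax <- as.integer(kmax)
    if (kmax < 0) stop("`kmax` must be >= 0", call. = FALSE)
  }
  if (mode == "exact") {
    if (is.null(rcut) || rcut <= 0) {
      stop("exact mode requires a positive `rcut`", call. = FALSE)
    }
    if (is.null(kmax)) {
      stop("exact mode requires a finite `kmax`", call. = FALSE)
    }
  }
  structure(list(smear_width = smear_width, kmax = kmax, rcut = rcut,
                 mode = mode),
            class = "ewald_params")
}

check_params_for_box <- function(params, box) {
  if (params$mode == "exact" && params$rcut >= min(box) / 2) {
    stop("`rcut` (", params$rcut, " A) must be < half the smallest box edge (",
         min(box) / 2, " A)", call. = FALSE)
  }
  invisible(params)
}
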