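#' Regular 3D map of the electrostatic potential
#'
#' A `potential_grid` stores the tinfoil Ewald potential (millivolts) on a
#' regular lattice spanning the periodic cell.  Lattice nodes sit at
#' `origin + (i, j, k) * spacing` for zero-based indices, x varying over the
#' first array dimension; under tinfoil conventions the volume average of the
#' values is zero.
#'
#' @param values Numeric 3D array of potentials in mV.
#' @param box Box edge lengths (Lx, Ly, Lz) in angstrom.
#' @param origin Cartesian coordinate of node (0,0,0); default `c(0,0,0)`.
#'
#' @return An object of class `potential_grid`.
#' @export
potential_grid <- function(values, box, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0))
  structure(
    list(values = values, dims = dim(values), box = box,
         spacing = box / dim(values), origin = as.numeric(origin)),
    class = "potential_grid"
  )
}

#' @export
print.potential_grid <- function(x, ...) {
  cat("<potential_grid> ", paste(x$dims, collapse = " x "), " nodes, box ",
      paste(format(x$box), collapse = " x "), " A\n", sep = "")
  cat(sprintf("  potential [mV]: mean %.3g, min %.4g, max %.4g\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Volume average of a potential grid
#'
#' Arithmetic mean over all lattice cells (uniform cell volumes).  Under
#' tinfoil Ewald conventions this is zero to within numerical roundoff for
#' any charge configuration, because the k = 0 Fourier component is dropped.
#'
#' @param grid A [potential_grid()].
#' @return The mean potential in mV.
#' @export
#' @examples
#' g <- potential_grid(array(1:8, c(2, 2, 2)), box = c(2, 2, 2))
#' box_average(g)  # 4.5
box_average <- function(grid) {
  stopifnot(inherits(grid, "potential_grid"))
  if (length(grid$values) == 0) stop("empty grid", call. = FALSE)
  mean(grid$values)
}

# node coordinates along one axis
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Default grid dimensions for a box at a target spacing
#'
#' One node per `spacing` angstrom, i.e. `round(box / spacing)` per axis
#' (minimum 1), so that per-frame grids track fluctuating box dimensions at
#' a fixed nominal resolution.
#'
#' @param box Box edge lengths in angstrom.
#' @param spacing Target lattice spacing in angstrom (default 1).
#' @return Integer vector of grid dimensions.
#' @export
grid_dims_for_box <- function(box, spacing = 1) {
  pmax(1L, as.integer(round(box / spacing)))
}
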