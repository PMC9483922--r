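#' Periodic point-charge configuration
#'
#' A `charge_system` holds the microscopic content of one frame of a periodic
#' simulation cell: Cartesian positions (angstrom), per-particle charges
#' (units of the elementary charge e), the orthorhombic box edge lengths, and
#' an optional per-particle species label used by the region classifier.
#' Positions may lie outside the primary cell; all computations reduce them by
#' lattice translation, which leaves every derived potential unchanged.
#'
#' @param positions Numeric matrix with one row per particle and columns
#'   x, y, z in angstrom (a data frame with those columns is accepted).
#' @param charges Numeric vector of per-particle charges in e.
#' @param box Numeric length-3 vector of box edge lengths (Lx, Ly, Lz) in
#'   angstrom; all must be positive.
#' @param species Optional character vector with one of `"solvent"`,
#'   `"protein"`, `"membrane"` per particle.
#'
#' @return An object of class `charge_system`.
#' @export
#' @examples
#' sys <- charge_system(rbind(c(1, 1, 1), c(5, 5, 5)), c(1, -1), box = c(10, 10, 10))
#' sys
charge_system <- function(positions, charges, box, species = NULL) {
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  charges <- as.numeric(charges)
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("`box` must be three positive finite edge lengths (invalid geometry)",
         call. = FALSE)
  }
  if (nrow(positions) != length(charges)) {
    stop("number of positions (", nrow(positions),
         ") must equal number of charges (", length(charges), ")",
         call. = FALSE)
  }
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != length(charges)) {
      stop("`species` must have one label per particle", call. = FALSE)
    }
    bad <- !species %in% c("solvent", "protein", "membrane")
    if (any(bad)) {
      stop("unknown species label(s): ",
           paste(unique(species[bad]), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(positions = positions, charges = charges, box = box,
         species = species),
    class = "charge_system"
  )
}

#' @export
print.charge_system <- function(x, ...) {
  cat("<charge_system> ", nrow(x$positions), " particles, net charge ",
      format(sum(x$charges)), " e\n", sep = "")
  cat("  box: ", paste(format(x$box), collapse = " x "), " A\n", sep = "")
  if (!is.null(x$species)) {
    tab <- table(x$species)
    cat("  species:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method as_tibble charge_system
#' @export
as_tibble.charge_system <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$positions))
  out$q <- x$charges
  out$species <- if (is.null(x$species)) NA_character_ else x$species
  out
}

# reduce positions into [0, L) per axis
wrap_positions <- function(positions, box) {
  for (ax in 1:3) {
    positions[, ax] <- positions[, ax] %% box[ax]
  }
  positions
}

n_particles <- function(system) nrow(system$positions)
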