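# Species occupancy maps and region classification.  Each grid cell is
# assigned to solvent, protein or membrane from Gaussian-smeared atomic
# densities on the same lattice as the potential map; the bulk-water Galvani
# potential is read off as the dominant solvent peak of the per-region
# potential histogram.

#' Gaussian occupancy maps per molecular species
#'
#' Deposits every atom onto the 3D map of its species as a periodic
#' normalized Gaussian of width `smear` (angstrom), on the same lattice
#' convention as [compute_potential_grid()].  The integral of each species
#' map over the box recovers that species' atom count.
#'
#' @param system A [charge_system()] with species labels.
#' @param dims Grid dimensions; default [grid_dims_for_box()] at `spacing`.
#' @param spacing Target lattice spacing in angstrom (default 1).
#' @param smear Gaussian width sigma per atom (A), default 1.0.
#' @return An object of class `occupancy_grid`: named list of density arrays
#'   (atoms/A^3) plus lattice metadata.
#' @export
build_occupancy <- function(system, dims = NULL, spacing = 1, smear = 1.0) {
  stopifnot(inherits(system, "charge_system"))
  if (is.null(system$species)) {
    stop("`system` has no species labels; label every atom as solvent, ",
         "protein or membrane before building occupancy maps", call. = FALSE)
  }
  box <- system$box
  if (is.null(dims)) dims <- grid_dims_for_box(box, spacing)
  dims <- as.integer(dims)
  h <- box / dims
  pos <- wrap_positions(system$positions, box)
  species <- unique(system$species)
  maps <- stats::setNames(
    lapply(species, function(s) array(0, dims)), species)
  pref <- (2 * pi * smear^2)^(-3 / 2)
  # per-axis window half-width: 4 sigma, clamped to the grid size
  w <- pmin(ceiling(4 * smear / h), (dims - 1L) %/% 2L)
  offs <- lapply(1:3, function(ax) seq(-w[ax], w[ax]))
  for (a in seq_len(nrow(pos))) {
    idx <- gx <- vector("list", 3)
    for (ax in 1:3) {
      i0 <- round(pos[a, ax] / h[ax])
      ii <- i0 + offs[[ax]]
      dx <- pos[a, ax] - ii * h[ax]
      idx[[ax]] <- (ii %% dims[ax]) + 1L
      gx[[ax]] <- exp(-dx^2 / (2 * smear^2))
    }
    blob <- pref * outer(outer(gx[[1]], gx[[2]]), gx[[3]])
    s <- system$species[a]
    maps[[s]][idx[[1]], idx[[2]], idx[[3]]] <-
      maps[[s]][idx[[1]], idx[[2]], idx[[3]]] + blob
  }
  structure(list(maps = maps, dims = dims, box = box, spacing = h,
                 smear = smear),
            class = "occupancy_grid")
}

#' Classify grid cells by molecular species
#'
#' Per cell, the species with the highest smeared density wins; exact ties
#' are broken by the fixed priority protein > membrane > solvent.  Cells
#' where every density falls below `floor` are labeled vacuum (and later
#' excluded from volume fractions and histograms).
#'
#' @param occ An [build_occupancy()] result.
#' @param floor Density threshold (atoms/A^3) below which a cell is vacuum.
#' @return An object of class `region_label_grid`: a character 3D array with
#'   lattice metadata.
#' @export
classify_cells <- function(occ, floor = 1e-3) {
  stopifnot(inherits(occ, "occupancy_grid"))
  dims <- occ$dims
  labels <- array("vacuum", dims)
  best <- array(-Inf, dims)
  # increasing priority: later species win exact ties
  for (s in c("solvent", "membrane", "protein")) {
    if (is.null(occ$maps[[s]])) next
    m <- occ$maps[[s]]
    take <- m >= best & m >= floor
    labels[take] <- s
    best <- pmax(best, m)
  }
  structure(list(labels = labels, dims = dims, box = occ$box,
                 spacing = occ$spacing),
            class = "region_label_grid")
}

#' Water volume fraction of a labeled grid
#'
#' Fraction of non-vacuum cells labeled solvent.
#'
#' @param labels A [classify_cells()] result.
#' @return `f_w` in `[0, 1]`.
#' @export
water_fraction <- function(labels) {
  stopifnot(inherits(labels, "region_label_grid"))
  occupied <- sum(labels$labels != "vacuum")
  if (occupied == 0) stop("all cells are vacuum; no phases present",
                          call. = FALSE)
  sum(labels$labels == "solvent") / occupied
}

#' Per-region histogram of the potential map
#'
#' Histograms the cell potentials separately for each labeled region
#' (vacuum cells excluded), with bin centers at integer multiples of
#' `bin_width` mV.
#'
#' @param pot A [potential_grid()].
#' @param labels A [classify_cells()] result on the same lattice.
#' @param bin_width Histogram bin width in mV (default 1).
#' @return A tibble of class `region_histogram` with columns `region`,
#'   `bin_mid` (mV) and `count`; attribute `bin_width`.
#' @export
region_histogram <- function(pot, labels, bin_width = 1) {
  stopifnot(inherits(pot, "potential_grid"),
            inherits(labels, "region_label_grid"))
  if (!identical(pot$dims, labels$dims)) {
    stop("potential grid and label grid live on different lattices (",
         paste(pot$dims, collapse = "x"), " vs ",
         paste(labels$dims, collapse = "x"), ")", call. = FALSE)
  }
  keep <- labels$labels != "vacuum"
  df <- tibble::tibble(
    region = as.vector(labels$labels[keep]),
    bin = as.integer(round(as.vector(pot$values[keep]) / bin_width))
  )
  out <- dplyr::count(df, .data$region, .data$bin, name = "count")
  out <- dplyr::mutate(out, bin_mid = .data$bin * bin_width)
  out <- dplyr::select(out, "region", "bin_mid", "count")
  out <- tibble::new_tibble(out, bin_width = bin_width,
                            class = "region_histogram")
  out
}

#' Bulk-water Galvani potential from the dominant solvent peak
#'
#' The bulk phase is identified with the highest peak of the solvent-region
#' histogram (the largest homogeneous region); near-interface cells bias a
#' spatial mean, so the mode is used instead.  The mode bin is refined by a
#' three-point parabolic fit through the peak and its neighbors; an exact
#' tie between bins is resolved toward the solvent-region mean.
#'
#' @param hist A [region_histogram()].
#' @return The bulk solvent potential in mV.
#' @export
estimate_bulk_potential <- function(hist) {
  stopifnot(inherits(hist, "region_histogram"))
  w <- attr(hist, "bin_width")
  solv <- hist[hist$region == "solvent", ]
  if (nrow(solv) == 0) stop("solvent region is empty", call. = FALSE)
  peak <- max(solv$count)
  modes <- solv$bin_mid[solv$count == peak]
  if (length(modes) > 1) {
    smean <- sum(solv$bin_mid * solv$count) / sum(solv$count)
    modes <- modes[which.min(abs(modes - smean))]
  }
  m <- modes[1]
  cnt <- function(mid) {
    i <- which(abs(solv$bin_mid - mid) < w / 2)
    if (length(i)) solv$count[i[1]] else 0
  }
  cm <- cnt(m - w); c0 <- cnt(m); cp <- cnt(m + w)
  denom <- cm - 2 * c0 + cp
  if (denom < 0) m + 0.5 * w * (cm - cp) / denom else m
}

#' Measure the Galvani offset potential over trajectory frames
#'
#' Runs the full per-frame pipeline on one or more frames: tinfoil Ewald
#' potential map at `spacing` (grid dimensions follow each frame's box),
#' species occupancy and classification, per-region histogram, and the
#' dominant solvent peak.  Reports frame-averaged bulk potential, water
#' fraction, and the offset correction `phi_offset = -<phi_w>`.
#'
#' @param frames A [charge_system()] or list of them (one per frame, with
#'   per-frame boxes honored).
#' @param params [ewald_params()] for the map (default smoothed,
#'   beta = 0.25/A).
#' @param spacing Grid spacing (A), default 1.
#' @param smear Occupancy smear width (A), default 1.
#' @param bin_width Histogram bin width (mV), default 1.
#' @param floor Vacuum density threshold for [classify_cells()].
#' @return An object of class `galvani_result`; see [tidy.galvani_result()].
#' @export
galvani_offset <- function(frames, params = ewald_params(), spacing = 1,
                           smear = 1.0, bin_width = 1, floor = 1e-3) {
  if (inherits(frames, "charge_system")) frames <- list(frames)
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, TRUE, "charge_system")))
  np <- vapply(frames, n_particles, 1L)
  if (length(unique(np)) != 1) {
    stop("inconsistent particle counts across frames: ",
         paste(unique(np), collapse = ", "), call. = FALSE)
  }
  per_frame <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    dims <- grid_dims_for_box(fr$box, spacing)
    pot <- compute_potential_grid(fr, params, dims)
    occ <- build_occupancy(fr, dims = dims, smear = smear)
    lab <- classify_cells(occ, floor = floor)
    hist <- region_histogram(pot, lab, bin_width = bin_width)
    regions <- dplyr::summarise(
      dplyr::group_by(hist, .data$region),
      mean_phi = sum(.data$bin_mid * .data$count) / sum(.data$count),
      cells = sum(.data$count), .groups = "drop")
    list(frame = i,
         phi_w = estimate_bulk_potential(hist),
         f_w = water_fraction(lab),
         regions = regions)
  })
  frames_tbl <- tibble::tibble(
    frame = vapply(per_frame, `[[`, 1L, "frame"),
    phi_w_mV = vapply(per_frame, `[[`, 1.0, "phi_w"),
    f_w = vapply(per_frame, `[[`, 1.0, "f_w")
  )
  all_regions <- dplyr::bind_rows(lapply(per_frame, `[[`, "regions"))
  regions <- dplyr::summarise(
    dplyr::group_by(all_regions, .data$region),
    mean_phi_mV = stats::weighted.mean(.data$mean_phi, .data$cells),
    cells = sum(.data$cells),
    .groups = "drop")
  regions$fraction <- regions$cells / sum(regions$cells)
  regions <- regions[, c("region", "fraction", "mean_phi_mV", "cells")]
  phi_w <- mean(frames_tbl$phi_w_mV)
  f_w <- mean(frames_tbl$f_w)
  structure(
    list(phi_w_mV = phi_w, phi_offset_mV = -phi_w,
         f_w = f_w, f_r = 1 - f_w,
         regions = regions, frames = frames_tbl,
         n_frames = length(frames)),
    class = "galvani_result"
  )
}

#' @export
print.galvani_result <- function(x, ...) {
  cat("<galvani_result> ", x$n_frames, " frame(s)\n", sep = "")
  cat(sprintf("  <phi_w> = %.1f mV   phi_offset = %.1f mV\n",
              x$phi_w_mV, x$phi_offset_mV))
  cat(sprintf("  f_w = %.3f   f_r = %.3f\n", x$f_w, x$f_r))
  invisible(x)
}

#' Linear fit of the bulk potential against the water fraction
#'
#' Ordinary least squares of `phi_w` on `f_w` over a set of simulation
#' systems, mirroring the empirical linear relation between the bulk-water
#' Galvani potential and the water volume fraction.
#'
#' @param points Data frame with columns `f_w` and `phi_w_mV` (aliases `fw`,
#'   `phi` accepted).
#' @return An object of class `fw_fit` with `slope` (mV per unit fraction),
#'   `intercept` (mV), `r_squared` and `n`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
#' @examples
#' pts <- data.frame(f_w = c(0.74, 0.81, 0.81, 0.88, 0.88),
#'                   phi_w_mV = c(-178, -125, -121, -78, -71))
#' glance(linear_fit_fw(pts))
linear_fit_fw <- function(points) {
  points <- as.data.frame(points)
  if (!"f_w" %in% names(points) && "fw" %in% names(points))
    points$f_w <- points$fw
  if (!"phi_w_mV" %in% names(points) && "phi" %in% names(points))
    points$phi_w_mV <- points$phi
  stopifnot(all(c("f_w", "phi_w_mV") %in% names(points)))
  if (nrow(points) < 2) stop("need at least two points", call. = FALSE)
  if (length(unique(points$f_w)) < 2) {
    stop("all `f_w` values identical: degenerate fit", call. = FALSE)
  }
  fit <- stats::lm(phi_w_mV ~ f_w, data = points)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n = nrow(points), model = fit, data = points),
    class = "fw_fit"
  )
}

#' @export
print.fw_fit <- function(x, ...) {
  cat(sprintf(
    "<fw_fit> phi_w = %.1f * f_w %+.1f mV   (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Predict the bulk potential from the water fraction
#'
#' The volume-fraction balance under tinfoil conventions gives
#' `phi_w = (1 - f_w) * Phi`, where `Phi` is the mean interfacial Galvani
#' potential between water and the non-water remainder (for example the
#' water-vacuum value of about -540 mV as an order-of-magnitude proxy).
#'
#' @param f_w Water volume fraction in `[0, 1]`.
#' @param Phi Interfacial potential in mV.
#' @return Predicted bulk-water potential in mV.
#' @export
#' @examples
#' predict_phi_from_fraction(0.74, -540)  # -140.4
predict_phi_from_fraction <- function(f_w, Phi) {
  stopifnot(all(f_w >= 0 & f_w <= 1))
  (1 - f_w) * Phi
}
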