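# broom-style tidiers for the package's fitted and measured objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the water-fraction linear fit
#'
#' @param x An `fw_fit` from [linear_fit_fw()].
#' @param ... Unused.
#' @return `tidy()`: one row per model term with `estimate`, `std.error`;
#'   `glance()`: one row with `r.squared`, `slope`, `intercept`, `nobs`.
#' @method tidy fw_fit
#' @export
tidy.fw_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "f_w"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2])
  )
}

#' @rdname tidy.fw_fit
#' @method glance fw_fit
#' @export
glance.fw_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, nobs = x$n)
}

#' Tidy a Henderson-Hasselbalch pKa fit
#'
#' @param x A `pka_fit` from [fit_pka()].
#' @param ... Unused.
#' @return `tidy()`: one row per fitted parameter; `glance()`: one row with
#'   `pKa`, `hill`, `sse`, `nobs`, `extrapolated`.
#' @method tidy pka_fit
#' @export
tidy.pka_fit <- function(x, ...) {
  tibble::tibble(term = c("pKa", "hill"),
                 estimate = c(x$pKa, x$hill))
}

#' @rdname tidy.pka_fit
#' @method glance pka_fit
#' @export
glance.pka_fit <- function(x, ...) {
  tibble::tibble(pKa = x$pKa, hill = x$hill, sse = x$sse, nobs = x$n,
                 extrapolated = x$extrapolated)
}

#' Tidy a WHAM solution
#'
#' @param x A `wham_solution` from [solve_wham()].
#' @param ... Unused.
#' @return One row per condition: `pH`, `phi_mV`, `n_snapshots`, `f`.
#' @method tidy wham_solution
#' @export
tidy.wham_solution <- function(x, ...) {
  tibble::as_tibble(x$conditions)
}

#' Tidy a Galvani offset measurement
#'
#' @param x A `galvani_result` from [galvani_offset()].
#' @param ... Unused.
#' @return `tidy()`: one row per frame (`frame`, `phi_w_mV`, `f_w`);
#'   `glance()`: one row with the frame-averaged `phi_w_mV`,
#'   `phi_offset_mV`, `f_w`, `f_r` and `n_frames`.
#' @method tidy galvani_result
#' @export
tidy.galvani_result <- function(x, ...) {
  x$frames
}

#' @rdname tidy.galvani_result
#' @method glance galvani_result
#' @export
glance.galvani_result <- function(x, ...) {
  tibble::tibble(phi_w_mV = x$phi_w_mV, phi_offset_mV = x$phi_offset_mV,
                 f_w = x$f_w, f_r = x$f_r, n_frames = x$n_frames)
}
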