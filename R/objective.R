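#' Fitting objective: summed modulus of the complex relative error
#'
#' The quantity minimized during parameter extraction:
#' `sum_i | (Z_model(f_i) - Z_measured(f_i)) / Z_measured(f_i) |`,
#' where `|.|` is the complex modulus.  It is zero exactly when the model
#' reproduces the measurement at every frequency, and it equals the sum of
#' the per-frequency relative-error curve divided by 100.
#'
#' @param params A [param_vector()] or numeric parameter values.
#' @param measured An [impedance_spectrum()]; no entry may be exactly zero.
#' @param model_id Model identifier; defaults to the `param_vector`'s model.
#' @return An `objective_value` with fields `value` and `n_points`.
#' @export
objective <- function(params, measured, model_id = NULL) {
  stopifnot(inherits(measured, "impedance_spectrum"))
  if (is.null(model_id)) {
    if (!inherits(params, "param_vector")) {
      stop("model_id is required when params is not a param_vector",
           call. = FALSE)
    }
    model_id <- params$spec$model_id
  }
  if (any(Mod(measured$z) == 0)) {
    stop("measured spectrum contains zero impedance; relative error undefined",
         call. = FALSE)
  }
  v <- .param_values(params, model_id)
  zm <- .z_eval(model_id, v, measured$grid$frequencies)
  value <- sum(Mod(zm - measured$z) / Mod(measured$z))
  structure(list(value = value, n_points = length(measured$z)),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("<objective_value> %.8g over %d points\n", x$value, x$n_points))
  invisible(x)
}

#' Per-frequency relative-error curve
#'
#' `100 * |Z_model(f_i) - Z_measured(f_i)| / |Z_measured(f_i)|` in percent
#' at each grid frequency, with the maximum and mean attached.  This is the
#' quantity plotted against frequency when comparing fitted models.
#'
#' @inheritParams objective
#' @return An `error_curve` with fields `grid`, `rel_err_percent`, `max`,
#'   `mean`.
#' @export
error_curve <- function(params, measured, model_id = NULL) {
  stopifnot(inherits(measured, "impedance_spectrum"))
  if (is.null(model_id)) {
    if (!inherits(params, "param_vector")) {
      stop("model_id is required when params is not a param_vector",
           call. = FALSE)
    }
    model_id <- params$spec$model_id
  }
  if (any(Mod(measured$z) == 0)) {
    stop("measured spectrum contains zero impedance; relative error undefined",
         call. = FALSE)
  }
  v <- .param_values(params, model_id)
  zm <- .z_eval(model_id, v, measured$grid$frequencies)
  err <- 100 * Mod(zm - measured$z) / Mod(measured$z)
  structure(list(grid = measured$grid, rel_err_percent = err,
                 max = max(err), mean = mean(err)),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("<error_curve> %d points, max %.6g%%, mean %.6g%%\n",
              length(x$rel_err_percent), x$max, x$mean))
  invisible(x)
}

#' Nyquist-plane table of a spectrum
#'
#' Rows `(freq_hz, z_real_ohm, neg_z_imag_ohm)` with the negated imaginary
#' part in the third column, following the EIS convention of plotting
#' `-Im(Z)` upward so capacitive arcs appear above the real axis.
#'
#' @param spectrum An [impedance_spectrum()].
#' @return A `data.frame` with columns `freq_hz`, `z_real_ohm`,
#'   `neg_z_imag_ohm`.
#' @export
nyquist_table <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  data.frame(freq_hz = spectrum$grid$frequencies,
             z_real_ohm = Re(spectrum$z),
             neg_z_imag_ohm = -Im(spectrum$z))
}
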