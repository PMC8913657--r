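# Complex frequency convention: s = j * 2*pi*f (angular), with the principal
# fractional power s^a = (2*pi*f)^a * exp(j*a*pi/2).  This is the standard
# convention in electrochemical impedance spectroscopy.
.s_pow <- function(freq, order) {
  (2 * pi * freq)^order * exp(1i * order * pi / 2)
}

#' Constant phase element
#'
#' The fractional-order circuit primitive: impedance `1/(c * s^order)` with
#' `s = j*2*pi*f`.  Its magnitude falls as `1/(c * omega^order)` and its
#' phase is constant at `-order * pi/2`.  `order = 1` is an ideal capacitor,
#' `order = 0` a resistor of value `1/c`.  The pseudo-capacitance `c` has
#' units F.s^(order-1), so tabulated nF/uF values are used verbatim.
#'
#' @param c Pseudo-capacitance, must be positive.
#' @param order Dispersion exponent in \[0, 1\].
#' @return A `cpe` object.
#' @export
cpe <- function(c, order) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("CPE pseudo-capacitance must be a positive number", call. = FALSE)
  }
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order < 0 || order > 1) {
    stop("CPE order must lie in [0, 1]", call. = FALSE)
  }
  structure(list(c = c, order = order), class = "cpe")
}

#' Impedance of a constant phase element over a grid
#'
#' @param element A [cpe()].
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()] with
#'   `z = 1/(c * (j*2*pi*f)^order)` on the principal branch.
#' @examples
#' g <- freq_grid(159.1549431)
#' cpe_impedance(cpe(1e-6, 1), g)$z  # ~ -1000j: ideal 1 uF capacitor
#' @export
cpe_impedance <- function(element, grid) {
  stopifnot(inherits(element, "cpe"), inherits(grid, "freq_grid"))
  z <- 1 / (element$c * .s_pow(grid$frequencies, element$order))
  impedance_spectrum(grid, z)
}

# ---------------------------------------------------------------------------
# Fast unvalidated evaluators, one per model, canonical parameter order.
# These are the closed rational forms; the circuit-topology oracle in
# oracle.R provides the independent cross-check.  Factors are kept in the
# (1 + s^a*R*C) shape to avoid overflow in the high-order products.

.z_cole <- function(v, freq) {
  # v = alpha, R_inf, R_o, C_alpha
  sa <- .s_pow(freq, v[1L])
  dR <- v[3L] - v[2L]
  v[2L] + dR / (1 + sa * v[4L] * dR)
}

.z_double_cole <- function(v, freq) {
  # v = alpha, beta, R_inf, R_1, R_2, C_alpha, C_beta
  sa <- .s_pow(freq, v[1L])
  sb <- .s_pow(freq, v[2L])
  v[3L] + v[4L] / (1 + sa * v[4L] * v[6L]) + v[5L] / (1 + sb * v[5L] * v[7L])
}

.z_double_shell <- function(v, freq) {
  # v = alpha, beta, R_1, R_2, R_3, C_alpha, C_beta
  R1 <- v[3L]; R2 <- v[4L]; R3 <- v[5L]
  wa <- .s_pow(freq, v[1L]) * v[6L]   # s^alpha * C_alpha
  wb <- .s_pow(freq, v[2L]) * v[7L]   # s^beta  * C_beta
  num <- R1 * (wa * wb * R2 * R3 + wa * R2 + wb * (R2 + R3) + 1)
  den <- wa * wb * (R2 * R3 + (R2 + R3) * R1) + wb * (R2 + R3) +
    wa * (R1 + R2) + 1
  num / den
}

.z_stem <- function(v, freq) {
  # v = alpha..lambda, R_o, R_1..R_4, C_alpha..C_lambda
  Ro <- v[6L]; R1 <- v[7L]; R2 <- v[8L]; R3 <- v[9L]; R4 <- v[10L]
  wa <- .s_pow(freq, v[1L]) * v[11L]
  wb <- .s_pow(freq, v[2L]) * v[12L]
  wg <- .s_pow(freq, v[3L]) * v[13L]
  wz <- .s_pow(freq, v[4L]) * v[14L]
  wl <- .s_pow(freq, v[5L]) * v[15L]
  fa <- 1 + wa * R1; fb <- 1 + wb * R2; fg <- 1 + wg * R3; fz <- 1 + wz * R4
  num <- Ro * fa * fb * fg * fz
  z_f <- (wa * R1 + wa * Ro + 1) * fb * fg * fz
  z_k <- Ro * fa * (wb * wg * (R3 + R2) + wb + wg) * fz
  z_p <- fb * fg * fa * wz * Ro
  z_m <- wl * Ro * fa * fb * fg * fz
  num / (z_f + z_k + z_p + z_m)
}

.z_simplified_stem <- function(v, freq) {
  # v = alpha, beta, gamma, R_o, R_1, R_2, C_alpha, C_beta, C_gamma
  Ro <- v[4L]; R1 <- v[5L]; R2 <- v[6L]
  wa <- .s_pow(freq, v[1L]) * v[7L]
  wb <- .s_pow(freq, v[2L]) * v[8L]
  wg <- .s_pow(freq, v[3L]) * v[9L]
  fa <- 1 + wa * R1; fb <- 1 + wb * R2
  z_k <- wa * wb * (R1 + R2) + wb + wa
  z_m <- wg * (wa * wb * R1 * R2 + wb * R2 + wa * R1 + 1)
  Ro + fb * fa / (z_k + z_m)
}

.z_eval <- function(model_id, v, freq) {
  switch(model_id,
         cole = .z_cole(v, freq),
         double_cole = .z_double_cole(v, freq),
         double_shell = .z_double_shell(v, freq),
         stem = .z_stem(v, freq),
         simplified_stem = .z_simplified_stem(v, freq),
         stop("unknown model_id: ", model_id, call. = FALSE))
}

# ---------------------------------------------------------------------------
# Validated user-facing evaluators.

.check_orders <- function(v, idx, names) {
  bad <- v[idx] <= 0 | v[idx] > 1
  if (any(bad)) {
    stop("dispersion orders must lie in (0, 1]: ",
         paste(names[bad], collapse = ", "), call. = FALSE)
  }
}

.check_positive <- function(v, idx, names, strict = TRUE) {
  bad <- if (strict) v[idx] <= 0 else v[idx] < 0
  if (any(bad)) {
    stop(if (strict) "parameters must be positive: " else
      "parameters must be non-negative: ",
      paste(names[bad], collapse = ", "), call. = FALSE)
  }
}

#' Single-dispersion Cole impedance
#'
#' `Z(s) = R_inf + (R_o - R_inf) / (1 + s^alpha * C_alpha * (R_o - R_inf))`,
#' the canonical tissue model: a high-frequency resistance `R_inf` in series
#' with the parallel combination of the relaxation resistance `R_o - R_inf`
#' and a CPE.  `R_o` is the zero-frequency resistance.
#'
#' @param params A [param_vector()] for `cole`, or numeric values in the
#'   order `alpha, R_inf, R_o, C_alpha`.
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()].
#' @export
cole_impedance <- function(params, grid) {
  v <- .param_values(params, "cole")
  nm <- .model_registry$cole$param_names
  .check_orders(v, 1L, nm)
  .check_positive(v, 2L, nm, strict = FALSE)
  .check_positive(v, 4L, nm)
  if (v[3L] <= v[2L]) {
    stop("cole model requires R_o > R_inf (positive relaxation strength)",
         call. = FALSE)
  }
  impedance_spectrum(grid, .z_cole(v, grid$frequencies))
}

#' Double-dispersion Cole impedance
#'
#' `Z(s) = R_inf + R_1/(1 + s^alpha R_1 C_alpha) + R_2/(1 + s^beta R_2 C_beta)`:
#' two relaxation sections in series, capturing tissues with two distinct
#' dispersion regions.
#'
#' @param params A [param_vector()] for `double_cole`, or numeric values in
#'   the order `alpha, beta, R_inf, R_1, R_2, C_alpha, C_beta`.
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()].
#' @export
double_cole_impedance <- function(params, grid) {
  v <- .param_values(params, "double_cole")
  nm <- .model_registry$double_cole$param_names
  .check_orders(v, 1:2, nm)
  .check_positive(v, 3L, nm, strict = FALSE)
  .check_positive(v, 4:7, nm[4:7])
  impedance_spectrum(grid, .z_double_cole(v, grid$frequencies))
}

#' Fractional-order double-shell impedance
#'
#' Cell-level plant tissue model: extracellular resistance `R_1` in parallel
#' with the intracellular path (plasma-membrane CPE `C_alpha` in series with
#' cytoplasm resistance `R_2` shunted by the vacuole branch `C_beta + R_3`).
#'
#' @param params A [param_vector()] for `double_shell`, or numeric values in
#'   the order `alpha, beta, R_1, R_2, R_3, C_alpha, C_beta`.
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()].
#' @export
double_shell_impedance <- function(params, grid) {
  v <- .param_values(params, "double_shell")
  nm <- .model_registry$double_shell$param_names
  .check_orders(v, 1:2, nm)
  .check_positive(v, 3L, nm)
  .check_positive(v, 4:5, nm[4:5], strict = FALSE)
  .check_positive(v, 6:7, nm[6:7])
  impedance_spectrum(grid, .z_double_shell(v, grid$frequencies))
}

#' Plant stem impedance (full anatomical model)
#'
#' Six parallel branches mirroring the stem cross-section: the epidermis as
#' a plain resistor `R_o`; cortex, vascular cambium, phloem, and xylem each
#' as a series resistor + CPE branch (`R_1..R_4` with `C_alpha..C_zeta`);
#' and the spongy pith as a bare CPE `C_lambda`.  Evaluated via the closed
#' rational form with all factors in `(1 + s^a R C)` shape.
#'
#' @param params A [param_vector()] for `stem`, or numeric values in the
#'   order `alpha..lambda, R_o, R_1..R_4, C_alpha..C_lambda`.
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()].
#' @export
stem_impedance <- function(params, grid) {
  v <- .param_values(params, "stem")
  nm <- .model_registry$stem$param_names
  .check_orders(v, 1:5, nm)
  .check_positive(v, 6L, nm)
  .check_positive(v, 7:10, nm[7:10], strict = FALSE)
  .check_positive(v, 11:15, nm[11:15])
  impedance_spectrum(grid, .z_stem(v, grid$frequencies))
}

#' Simplified plant stem impedance
#'
#' The stem model with the vascular bundle collapsed to a single series
#' R + CPE branch: epidermis resistor `R_o` in series with the parallel
#' combination of the cortex branch (`R_1 + C_alpha`), the bundle branch
#' (`R_2 + C_beta`), and the pith CPE `C_gamma`.
#'
#' @param params A [param_vector()] for `simplified_stem`, or numeric values
#'   in the order `alpha, beta, gamma, R_o, R_1, R_2, C_alpha, C_beta,
#'   C_gamma`.
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()].
#' @export
simplified_stem_impedance <- function(params, grid) {
  v <- .param_values(params, "simplified_stem")
  nm <- .model_registry$simplified_stem$param_names
  .check_orders(v, 1:3, nm)
  .check_positive(v, 4:6, nm[4:6], strict = FALSE)
  .check_positive(v, 7:9, nm[7:9])
  impedance_spectrum(grid, .z_simplified_stem(v, grid$frequencies))
}

#' Evaluate any registered model
#'
#' Dispatches to the validated evaluator for `model_id`.
#'
#' @param model_id One of [model_ids()].
#' @param params Parameters (see the per-model evaluators).
#' @param grid A [freq_grid()].
#' @return An [impedance_spectrum()].
#' @export
model_impedance <- function(model_id, params, grid) {
  model_id <- match.arg(model_id, model_ids())
  switch(model_id,
         cole = cole_impedance(params, grid),
         double_cole = double_cole_impedance(params, grid),
         double_shell = double_shell_impedance(params, grid),
         stem = stem_impedance(params, grid),
         simplified_stem = simplified_stem_impedance(params, grid))
}
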