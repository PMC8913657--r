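# Reference parameter sets.  The cole / double_cole / double_shell entries
# are WCA-extracted values reported for stem segments of three Lamiaceae
# species (Marjoram, Salvia officinalis L., Lavandula) measured at 5 cm and
# 10 cm electrode spacing.  The reported tables for the two stem models
# contain typographic ambiguities, so no measured presets are provided for
# them; instead each stem model carries one synthetic reference set
# (sample "synthetic_a") with dispersions placed inside the 100 Hz-100 kHz
# band, used by the simulation examples and the recovery benchmarks.
.preset_registry <- list(
  cole = list(
    # alpha, R_inf, R_o, C_alpha
    marjoram_5cm   = c(0.6647, 5.6834e3, 202.28e3, 4.2952e-9),
    marjoram_10cm  = c(0.7300, 4.9567e3, 558.89e3, 1.1493e-9),
    salvia_5cm     = c(0.7035, 23.987e3, 441.99e3, 2.7149e-9),
    salvia_10cm    = c(0.7159, 25.565e3, 991.37e3, 1.4455e-9),
    lavandula_5cm  = c(0.5016, 9.4741e3, 384.92e3, 65.825e-9),
    lavandula_10cm = c(0.5562, 2.1391e3, 604.51e3, 12.135e-9)
  ),
  double_cole = list(
    # alpha, beta, R_inf, R_1, R_2, C_alpha, C_beta
    marjoram_5cm   = c(1, 0.6828, 8.6531e3, 31.628e3, 194.20e3,
                       67.170e-9, 3.6101e-9),
    marjoram_10cm  = c(1, 0.7156, 0, 38.239e3, 523.00e3,
                       1.6952e-9, 1.3449e-9),
    salvia_5cm     = c(0.5117, 0.7908, 0, 143.71e3, 316.41e3,
                       27.943e-9, 1.8190e-9),
    salvia_10cm    = c(0.8128, 0.5932, 0, 757.92e3, 213.18e3,
                       0.8319e-9, 8.0292e-9),
    lavandula_5cm  = c(1, 0.3935, 0, 23.009e3, 551.16e3,
                       5.9543e-9, 199.55e-9),
    lavandula_10cm = c(0.5271, 1, 0, 585.57e3, 9.7282e3,
                       24.989e-9, 0.4826e-9)
  ),
  double_shell = list(
    # alpha, beta, R_1, R_2, R_3, C_alpha, C_beta
    marjoram_5cm   = c(0.5649, 0.9855, 284.85e3, 239.40e3, 0,
                       15.354e-9, 0.9762e-9),
    marjoram_10cm  = c(0.7813, 0.7044, 1.6228e6, 1.8514e6, 94.061e3,
                       7.9913e-9, 1.5936e-9),
    salvia_5cm     = c(0.7524, 0.6209, 456.63e3, 50.052e3, 369.52,
                       1.5692e-9, 7.9199e-9),
    salvia_10cm    = c(0.8041, 0.6305, 966.94e3, 120.13e3, 7.4007e3,
                       0.6215e-9, 6.2827e-9),
    lavandula_5cm  = c(0.3885, 1, 666.78e3, 35.951e3, 0,
                       214.87e-9, 5.2109e-9),
    lavandula_10cm = c(0.5316, 1, 590.17e3, 10.33e3, 0,
                       23.165e-9, 0.5557e-9)
  ),
  stem = list(
    # synthetic reference set (not a measured extraction): orders, then
    # R_o, R_1..R_4, then C_alpha..C_lambda
    synthetic_a = c(0.90, 0.80, 0.75, 0.70, 0.85,
                    50e3, 20e3, 80e3, 300e3, 1e6,
                    200e-9, 50e-9, 20e-9, 10e-9, 1e-9)
  ),
  simplified_stem = list(
    # synthetic reference set (not a measured extraction): dispersions of
    # the cortex and bundle branches near 50 Hz and 300 Hz, pith CPE
    # becoming conductive near the top of the band
    synthetic_a = c(0.85, 0.70, 0.60, 10e3, 150e3, 500e3,
                    50e-9, 10e-9, 2e-9)
  )
)

#' Reference parameter sets for examples and recovery studies
#'
#' For the three classical models these are WCA-extracted parameters for
#' Lamiaceae stem samples (`marjoram`, `salvia`, `lavandula` at `5cm` or
#' `10cm` electrode spacing).  The two stem models carry a synthetic
#' reference set each (`synthetic_a`) because no unambiguous measured
#' extraction is available for them.
#'
#' @param model_id One of [model_ids()].
#' @param sample Sample name; see [preset_names()].
#' @return A [param_vector()].
#' @examples
#' reference_params("cole", "marjoram_5cm")
#' @export
reference_params <- function(model_id, sample) {
  model_id <- match.arg(model_id, model_ids())
  entry <- .preset_registry[[model_id]]
  if (is.null(entry) || is.null(entry[[sample]])) {
    stop(sprintf("no preset '%s' for model '%s' (available: %s)",
                 sample, model_id, paste(names(entry), collapse = ", ")),
         call. = FALSE)
  }
  param_vector(model_spec(model_id), entry[[sample]])
}

#' Names of the available reference parameter sets
#'
#' @param model_id One of [model_ids()].
#' @return Character vector of sample names accepted by
#'   [reference_params()].
#' @export
preset_names <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  names(.preset_registry[[model_id]])
}
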