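#' Proportional complex noise model
#'
#' Synthetic stand-in for instrument noise on an impedance sweep: each
#' impedance value is perturbed multiplicatively,
#' `z_noisy = z * (1 + eps)`, with
#' `eps = sigma_rel * (g1 + 1i*g2) / sqrt(2)` and `g1`, `g2` independent
#' standard normal draws.  The modulus of `eps` then has mean
#' `sigma_rel * sqrt(pi)/2` and root-mean-square `sigma_rel`.
#' `sigma_rel = 0` reproduces the noiseless spectrum bit-for-bit.
#'
#' @param sigma_rel Non-negative proportional noise scale.
#' @param seed Optional integer seed for reproducible draws.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sigma_rel = 0, seed = NULL) {
  if (!is.numeric(sigma_rel) || length(sigma_rel) != 1L ||
      !is.finite(sigma_rel) || sigma_rel < 0) {
    stop("sigma_rel must be a non-negative number", call. = FALSE)
  }
  structure(list(sigma_rel = sigma_rel, seed = seed), class = "noise_model")
}

#' Simulate a (possibly noisy) impedance spectrum from a model
#'
#' Evaluates the model at every grid frequency and applies the proportional
#' complex noise of [noise_model()].  With `sigma_rel = 0` the output equals
#' the validated model evaluation exactly.
#'
#' @param params A [param_vector()] or numeric parameter values.
#' @param grid A [freq_grid()].
#' @param noise A [noise_model()]; default is noiseless.
#' @param model_id Model identifier; defaults to the `param_vector`'s model.
#' @return An [impedance_spectrum()].
#' @export
simulate_spectrum <- function(params, grid, noise = noise_model(0),
                              model_id = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(model_id)) {
    if (!inherits(params, "param_vector")) {
      stop("model_id is required when params is not a param_vector",
           call. = FALSE)
    }
    model_id <- params$spec$model_id
  }
  clean <- model_impedance(model_id, params, grid)
  if (noise$sigma_rel == 0) return(clean)
  n <- length(clean$z)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  g1 <- stats::rnorm(n)
  g2 <- stats::rnorm(n)
  eps <- noise$sigma_rel * complex(real = g1, imaginary = g2) / sqrt(2)
  impedance_spectrum(grid, clean$z * (1 + eps))
}

#' Draw a random in-bounds parameter vector
#'
#' Uniform draw within the model's search boundaries, used for property
#' testing and for seeding recovery studies.  Dispersion orders are drawn in
#' \[0.05, 1\] (the order-0 limit degenerates a CPE into a resistor, which
#' the closed rational forms do not model); all other parameters are drawn
#' over their full \[lower, upper\] range.  For the Cole model the draw is
#' repeated until `R_o > R_inf`, as its relaxation strength must be
#' positive.
#'
#' @param spec A `model_spec` or model id string.
#' @param seed Optional integer seed.
#' @param min_order Lower truncation for the dispersion orders (default 0.05).
#' @return A [param_vector()].
#' @export
sample_params <- function(spec, seed = NULL, min_order = 0.05) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  is_order <- spec$units == "-"
  lo <- spec$lower
  lo[is_order] <- pmax(lo[is_order], min_order)
  repeat {
    v <- stats::runif(length(lo), min = lo, max = spec$upper)
    names(v) <- spec$param_names
    if (spec$model_id != "cole" || v[["R_o"]] > v[["R_inf"]]) break
  }
  param_vector(spec, v)
}
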