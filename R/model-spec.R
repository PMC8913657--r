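# Model registry: canonical parameter order and search bounds for the five
# equivalent-circuit models.  Resistances in ohm, pseudo-capacitances in
# F.s^(order-1), dispersion orders dimensionless in [0, 1].
.model_registry <- list(
  cole = list(
    param_names = c("alpha", "R_inf", "R_o", "C_alpha"),
    lower = c(0, 0, 0, 0),
    upper = c(1, 100e3, 80e6, 3e-6),
    units = c("-", "ohm", "ohm", "F.s^(alpha-1)")
  ),
  double_cole = list(
    param_names = c("alpha", "beta", "R_inf", "R_1", "R_2",
                    "C_alpha", "C_beta"),
    lower = rep(0, 7),
    upper = c(1, 1, 1e6, 1e6, 1e6, 4e-6, 4e-6),
    units = c("-", "-", "ohm", "ohm", "ohm",
              "F.s^(alpha-1)", "F.s^(beta-1)")
  ),
  double_shell = list(
    param_names = c("alpha", "beta", "R_1", "R_2", "R_3",
                    "C_alpha", "C_beta"),
    lower = rep(0, 7),
    upper = c(1, 1, 10e6, 10e6, 10e6, 3e-6, 3e-6),
    units = c("-", "-", "ohm", "ohm", "ohm",
              "F.s^(alpha-1)", "F.s^(beta-1)")
  ),
  stem = list(
    param_names = c("alpha", "beta", "gamma", "zeta", "lambda",
                    "R_o", "R_1", "R_2", "R_3", "R_4",
                    "C_alpha", "C_beta", "C_gamma", "C_zeta", "C_lambda"),
    lower = rep(0, 15),
    upper = c(rep(1, 5), rep(1e9, 5), rep(100e-6, 5)),
    units = c(rep("-", 5), rep("ohm", 5),
              "F.s^(alpha-1)", "F.s^(beta-1)", "F.s^(gamma-1)",
              "F.s^(zeta-1)", "F.s^(lambda-1)")
  ),
  simplified_stem = list(
    param_names = c("alpha", "beta", "gamma", "R_o", "R_1", "R_2",
                    "C_alpha", "C_beta", "C_gamma"),
    lower = rep(0, 9),
    upper = c(1, 1, 1, 100e6, 100e6, 100e6, 10e-6, 10e-6, 10e-6),
    units = c("-", "-", "-", "ohm", "ohm", "ohm",
              "F.s^(alpha-1)", "F.s^(beta-1)", "F.s^(gamma-1)")
  )
)

#' Available model identifiers
#'
#' @return Character vector: `cole`, `double_cole`, `double_shell`, `stem`,
#'   `simplified_stem`.
#' @export
model_ids <- function() names(.model_registry)

#' Model specification: parameter names, units, and search bounds
#'
#' Each model carries a canonical parameter ordering (dispersion orders
#' first, then resistances, then pseudo-capacitances) and per-parameter
#' lower/upper search boundaries.  The boundaries are the published search
#' regions for plant-stem parameter extraction: all orders in \[0, 1\];
#' Cole `R_o` up to 80 Mohm and `R_inf` up to 100 kohm; double-Cole
#' resistances up to 1 Mohm; double-shell resistances up to 10 Mohm; stem
#' resistances up to 1 Gohm; simplified-stem resistances up to 100 Mohm;
#' capacitance ceilings of 3, 4, 3, 100, and 10 uF respectively.
#'
#' @param model_id One of [model_ids()].
#' @return A `model_spec` object with fields `model_id`, `param_names`,
#'   `lower`, `upper`, `units`.
#' @examples
#' model_spec("cole")$param_names
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  entry <- .model_registry[[model_id]]
  structure(
    list(model_id = model_id,
         param_names = entry$param_names,
         lower = stats::setNames(entry$lower, entry$param_names),
         upper = stats::setNames(entry$upper, entry$param_names),
         units = stats::setNames(entry$units, entry$param_names)),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d parameters)\n", x$model_id,
              length(x$param_names)))
  print(data.frame(parameter = x$param_names, unit = unname(x$units),
                   lower = unname(x$lower), upper = unname(x$upper),
                   row.names = NULL))
  invisible(x)
}

#' Concrete parameter assignment for a model
#'
#' Binds numeric values to a model specification, enforcing the bound
#' constraints elementwise.  Values may be given in the canonical order or
#' named (names are reordered to the canonical order).
#'
#' @param spec A `model_spec` or a model id string.
#' @param values Numeric vector, one entry per parameter.
#' @return A `param_vector` with fields `spec` and `values` (named).
#' @examples
#' param_vector("cole", c(alpha = 0.7, R_inf = 5e3, R_o = 2e5, C_alpha = 4e-9))
#' @export
param_vector <- function(spec, values) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  values <- stats::setNames(as.numeric(values), names(values))
  if (length(values) != length(spec$param_names)) {
    stop(sprintf("%s expects %d parameters, got %d", spec$model_id,
                 length(spec$param_names), length(values)), call. = FALSE)
  }
  if (!is.null(names(values)) && all(nzchar(names(values)))) {
    missing <- setdiff(spec$param_names, names(values))
    if (length(missing)) {
      stop("missing parameters: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    values <- values[spec$param_names]
  } else {
    names(values) <- spec$param_names
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("parameter values must be finite", call. = FALSE)
  }
  bad <- values < spec$lower | values > spec$upper
  if (any(bad)) {
    stop("parameters outside bounds: ",
         paste(spec$param_names[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(spec = spec, values = values), class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  cat(sprintf("<param_vector> %s\n", x$spec$model_id))
  print(x$values)
  invisible(x)
}

# Coerce a param_vector or named/plain numeric to a plain numeric vector in
# the canonical order for `model_id`.
.param_values <- function(params, model_id) {
  if (inherits(params, "param_vector")) {
    if (params$spec$model_id != model_id) {
      stop(sprintf("parameter vector is for '%s', not '%s'",
                   params$spec$model_id, model_id), call. = FALSE)
    }
    return(unname(params$values))
  }
  spec <- model_spec(model_id)
  v <- as.numeric(params)
  if (length(v) != length(spec$param_names)) {
    stop(sprintf("%s expects %d parameters", model_id,
                 length(spec$param_names)), call. = FALSE)
  }
  if (!is.null(names(params)) && all(nzchar(names(params)))) {
    v <- v[match(spec$param_names, names(params))]
    if (anyNA(v)) stop("parameter names do not match model", call. = FALSE)
  }
  v
}
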