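# Independent verification path for the closed-form model impedances: each
# model is described as a tree of circuit elements and evaluated by
# recursive series addition of impedances and parallel addition of
# admittances.  Numerically this is the safer reference (no high-order
# polynomial products), and structurally it encodes the published circuit
# diagrams rather than the rational equations.

.el_res <- function(label, value) {
  # value: function(named param values) -> resistance in ohm
  list(kind = "resistor", label = label, value = value)
}
.el_cpe <- function(c_name, order_name) {
  list(kind = "cpe", label = sprintf("CPE(%s,%s)", c_name, order_name),
       c_name = c_name, order_name = order_name)
}
.el_series <- function(...) list(kind = "series", children = list(...))
.el_parallel <- function(...) list(kind = "parallel", children = list(...))

#' Circuit topology of a model
#'
#' Returns the element tree behind each model's circuit diagram:
#' \describe{
#'   \item{cole}{`R_inf` in series with \[`(R_o - R_inf)` parallel `CPE_alpha`\].}
#'   \item{double_cole}{`R_inf` + \[`R_1` par `CPE_alpha`\] + \[`R_2` par `CPE_beta`\].}
#'   \item{double_shell}{`R_1` parallel \[`CPE_alpha` series (`R_2` parallel
#'     (`CPE_beta` series `R_3`))\].}
#'   \item{stem}{six parallel branches: `R_o`; `R_1 + CPE_alpha`;
#'     `R_2 + CPE_beta`; `R_3 + CPE_gamma`; `R_4 + CPE_zeta`; `CPE_lambda`.}
#'   \item{simplified_stem}{`R_o` in series with the parallel of
#'     `R_1 + CPE_alpha`, `R_2 + CPE_beta`, and `CPE_gamma`.}
#' }
#'
#' @param model_id One of [model_ids()].
#' @return A `circuit_topology` object (nested element tree).
#' @export
circuit_topology <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  val <- function(name) function(p) unname(p[[name]])
  tree <- switch(
    model_id,
    cole = .el_series(
      .el_res("R_inf", val("R_inf")),
      .el_parallel(
        .el_res("R_o - R_inf", function(p) unname(p[["R_o"]] - p[["R_inf"]])),
        .el_cpe("C_alpha", "alpha"))),
    double_cole = .el_series(
      .el_res("R_inf", val("R_inf")),
      .el_parallel(.el_res("R_1", val("R_1")), .el_cpe("C_alpha", "alpha")),
      .el_parallel(.el_res("R_2", val("R_2")), .el_cpe("C_beta", "beta"))),
    double_shell = .el_parallel(
      .el_res("R_1", val("R_1")),
      .el_series(
        .el_cpe("C_alpha", "alpha"),
        .el_parallel(
          .el_res("R_2", val("R_2")),
          .el_series(.el_cpe("C_beta", "beta"),
                     .el_res("R_3", val("R_3")))))),
    stem = .el_parallel(
      .el_res("R_o", val("R_o")),
      .el_series(.el_res("R_1", val("R_1")), .el_cpe("C_alpha", "alpha")),
      .el_series(.el_res("R_2", val("R_2")), .el_cpe("C_beta", "beta")),
      .el_series(.el_res("R_3", val("R_3")), .el_cpe("C_gamma", "gamma")),
      .el_series(.el_res("R_4", val("R_4")), .el_cpe("C_zeta", "zeta")),
      .el_cpe("C_lambda", "lambda")),
    simplified_stem = .el_series(
      .el_res("R_o", val("R_o")),
      .el_parallel(
        .el_series(.el_res("R_1", val("R_1")), .el_cpe("C_alpha", "alpha")),
        .el_series(.el_res("R_2", val("R_2")), .el_cpe("C_beta", "beta")),
        .el_cpe("C_gamma", "gamma"))))
  structure(list(model_id = model_id, tree = tree),
            class = "circuit_topology")
}

# Recursive evaluation.  A node result is list(open = flag, z = complex
# vector valid when !open).  A CPE with c = 0 is an open branch (admittance
# zero); an order-0 CPE is the resistor 1/c.  A resistor of 0 ohm is a
# short, not an open.
.eval_node <- function(node, p, freq) {
  switch(
    node$kind,
    resistor = {
      r <- node$value(p)
      list(open = FALSE, z = rep(complex(real = r), length(freq)))
    },
    cpe = {
      cval <- unname(p[[node$c_name]])
      if (cval == 0) return(list(open = TRUE, z = NULL))
      ord <- unname(p[[node$order_name]])
      list(open = FALSE, z = 1 / (cval * .s_pow(freq, ord)))
    },
    series = {
      z <- complex(real = rep(0, length(freq)))
      for (child in node$children) {
        res <- .eval_node(child, p, freq)
        if (res$open) return(list(open = TRUE, z = NULL))
        z <- z + res$z
      }
      list(open = FALSE, z = z)
    },
    parallel = {
      y <- complex(real = rep(0, length(freq)))
      any_branch <- FALSE
      for (child in node$children) {
        res <- .eval_node(child, p, freq)
        if (res$open) next
        if (all(res$z == 0)) {  # short-circuit branch dominates
          return(list(open = FALSE, z = complex(real = rep(0, length(freq)))))
        }
        any_branch <- TRUE
        y <- y + 1 / res$z
      }
      if (!any_branch) return(list(open = TRUE, z = NULL))
      list(open = FALSE, z = 1 / y)
    },
    stop("unknown circuit node kind: ", node$kind, call. = FALSE))
}

#' Impedance via the circuit-topology oracle
#'
#' Evaluates a model by walking its circuit tree ([circuit_topology()])
#' instead of the closed rational form: impedances add in series, admittances
#' add in parallel.  Conventions differ from the rational forms in two
#' deliberate ways: a CPE with `c = 0` is an open branch (admittance 0), and
#' an order of exactly 0 is allowed (the CPE degenerates to a resistor
#' `1/c`).  Used throughout the test suite as the independent cross-check of
#' the five model equations.
#'
#' @param params A [param_vector()] or named numeric vector of parameters.
#' @param grid A [freq_grid()].
#' @param model_id Model identifier; defaults to the `param_vector`'s model.
#' @return An [impedance_spectrum()].
#' @examples
#' g <- make_grid(100, 100e3, 10)
#' pv <- param_vector("cole", c(0.8, 1e3, 1e5, 5e-9))
#' oracle <- circuit_oracle_impedance(pv, g)
#' closed <- cole_impedance(pv, g)
#' max(Mod(oracle$z - closed$z) / Mod(oracle$z))
#' @export
circuit_oracle_impedance <- function(params, grid, model_id = NULL) {
  if (inherits(params, "param_vector")) {
    if (is.null(model_id)) model_id <- params$spec$model_id
    p <- as.list(params$values)
  } else {
    if (is.null(model_id)) {
      stop("model_id is required when params is not a param_vector",
           call. = FALSE)
    }
    spec <- model_spec(model_id)
    v <- .param_values(params, model_id)
    p <- as.list(stats::setNames(v, spec$param_names))
  }
  topo <- circuit_topology(model_id)
  res <- .eval_node(topo$tree, p, grid$frequencies)
  if (res$open) {
    stop("circuit is fully open (no conducting branch); impedance undefined",
         call. = FALSE)
  }
  impedance_spectrum(grid, res$z)
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(sprintf("<circuit_topology> %s\n", x$model_id))
  describe <- function(node) {
    switch(node$kind,
           resistor = node$label,
           cpe = node$label,
           series = paste0("(", paste(vapply(node$children, describe, ""),
                                      collapse = " + "), ")"),
           parallel = paste0("(", paste(vapply(node$children, describe, ""),
                                        collapse = " || "), ")"))
  }
  cat(" ", describe(x$tree), "\n")
  invisible(x)
}
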