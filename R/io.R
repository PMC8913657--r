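# Plain-text exchange formats.  Spectra travel as CSV with header
# freq_hz,z_real_ohm,z_imag_ohm ('#' lines are comments); fit results as a
# versioned key/value document.  All writers emit full double precision so
# read/write round trips are lossless.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write an impedance spectrum to CSV
#'
#' Columns `freq_hz`, `z_real_ohm`, `z_imag_ohm`, full double precision.
#' Optional `comments` are emitted as leading `#` lines (used by the CLI to
#' record provenance).
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path Output file path.
#' @param comments Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, comments = character(0)) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    "freq_hz,z_real_ohm,z_imag_ohm",
    sprintf("%s,%s,%s",
            .fmt_num(spectrum$grid$frequencies),
            .fmt_num(Re(spectrum$z)),
            .fmt_num(Im(spectrum$z))))
  writeLines(lines, path)
  invisible(path)
}

#' Read an impedance spectrum from CSV
#'
#' Expects a header `freq_hz,z_real_ohm,z_imag_ohm` (comma separated, `.`
#' decimal); `#` lines are skipped.  Rows are sorted by frequency after
#' loading.  Missing columns, non-numeric cells, non-positive or duplicate
#' frequencies raise an error naming the offending row.
#'
#' @param path Input file path.
#' @return An [impedance_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  rows <- raw[keep]
  if (length(rows) < 2L) {
    stop("spectrum file has no data rows: ", path, call. = FALSE)
  }
  header <- trimws(strsplit(rows[1L], ",", fixed = TRUE)[[1L]])
  wanted <- c("freq_hz", "z_real_ohm", "z_imag_ohm")
  idx <- match(wanted, header)
  if (anyNA(idx)) {
    stop("missing column(s): ", paste(wanted[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  body <- rows[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  n <- length(body)
  freq <- zre <- zim <- numeric(n)
  for (i in seq_len(n)) {
    cells <- trimws(parts[[i]])
    if (length(cells) < length(header)) {
      stop(sprintf("row %d: expected %d cells, found %d", i, length(header),
                   length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells[idx]))
    if (anyNA(vals)) {
      stop(sprintf("row %d: non-numeric cell in '%s'", i, body[i]),
           call. = FALSE)
    }
    freq[i] <- vals[1L]; zre[i] <- vals[2L]; zim[i] <- vals[3L]
  }
  bad <- which(freq <= 0)
  if (length(bad)) {
    stop(sprintf("row %d: non-positive frequency %g", bad[1L], freq[bad[1L]]),
         call. = FALSE)
  }
  dup <- which(duplicated(freq))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate frequency %g", dup[1L], freq[dup[1L]]),
         call. = FALSE)
  }
  ord <- order(freq)
  impedance_spectrum(freq_grid(freq[ord]),
                     complex(real = zre[ord], imaginary = zim[ord]))
}

#' Write a model fit to a key/value result document
#'
#' Serializes the selected best run of a fit: model id, named parameters
#' (full precision, canonical order), objective value, and the protocol
#' echo (algorithm, agents, iterations, runs, seed, run index).  The format
#' is versioned (`schema_version: 1`) and reloadable losslessly with
#' [read_fit_result()].
#'
#' @param path Output file path.
#' @param result A `fit_result` (from [minimize()]/[multi_run()]) or a
#'   `model_fit` (from [fit_model()]).
#' @param spec The `model_spec` naming the parameters (taken from a
#'   `model_fit` automatically).
#' @param convergence_csv Optional path (recorded verbatim) of the
#'   convergence-history CSV that accompanies the result.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(path, result, spec = NULL,
                             convergence_csv = "") {
  if (inherits(result, "model_fit")) {
    spec <- result$best_params$spec
    run <- result$best_run
    values <- result$best_params$values
  } else if (inherits(result, "fit_result")) {
    if (is.null(spec)) stop("spec is required for a raw fit_result",
                            call. = FALSE)
    if (is.character(spec)) spec <- model_spec(spec)
    run <- result
    values <- stats::setNames(result$best_params, spec$param_names)
  } else {
    stop("result must be a fit_result or model_fit", call. = FALSE)
  }
  cfg <- run$config
  lines <- c(
    "schema_version: 1",
    paste0("model_id: ", spec$model_id),
    paste0("n_params: ", length(values)),
    sprintf("param_%s: %s", spec$param_names, .fmt_num(unname(values))),
    paste0("objective: ", .fmt_num(run$best_objective)),
    paste0("algorithm: ", cfg$algorithm),
    paste0("n_agents: ", cfg$n_agents),
    paste0("n_iterations: ", cfg$n_iterations),
    paste0("n_runs: ", cfg$n_runs),
    paste0("base_seed: ", cfg$seed - run$run_index),
    paste0("run_seed: ", run$seed),
    paste0("run_index: ", run$run_index),
    paste0("convergence_csv: ", convergence_csv))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write fit result to ", path, call. = FALSE)
  invisible(path)
}

#' Read a fit-result document
#'
#' @param path Path written by [write_fit_result()].
#' @return A list with `model_id`, `params` (named, canonical order),
#'   `objective`, `algorithm`, `n_agents`, `n_iterations`, `n_runs`,
#'   `base_seed`, `run_seed`, `run_index`, `convergence_csv`.
#' @export
read_fit_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  m <- regmatches(raw, regexec("^([^:]+):\\s*(.*)$", raw))
  keys <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_,
                 "")
  vals <- vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_,
                 "")
  if (anyNA(keys)) stop("malformed fit-result file: ", path, call. = FALSE)
  kv <- stats::setNames(as.list(vals), keys)
  if (is.null(kv$schema_version) || kv$schema_version != "1") {
    stop("unsupported fit-result schema in ", path, call. = FALSE)
  }
  spec <- model_spec(kv$model_id)
  pkeys <- paste0("param_", spec$param_names)
  missing <- setdiff(pkeys, keys)
  if (length(missing)) {
    stop("fit-result file missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- stats::setNames(as.numeric(unlist(kv[pkeys])), spec$param_names)
  list(model_id = kv$model_id,
       params = params,
       objective = as.numeric(kv$objective),
       algorithm = kv$algorithm,
       n_agents = as.integer(kv$n_agents),
       n_iterations = as.integer(kv$n_iterations),
       n_runs = as.integer(kv$n_runs),
       base_seed = as.integer(kv$base_seed),
       run_seed = as.integer(kv$run_seed),
       run_index = as.integer(kv$run_index),
       convergence_csv = kv$convergence_csv)
}

#' Write a convergence history to CSV
#'
#' Columns `iteration`, `best_objective` — one row per iteration of a
#' single optimizer run, reproducing published convergence-curve data.
#'
#' @param path Output file path.
#' @param convergence Numeric vector of per-iteration best objectives.
#' @return `path`, invisibly.
#' @export
write_convergence_csv <- function(path, convergence) {
  lines <- c("iteration,best_objective",
             sprintf("%d,%s", seq_along(convergence), .fmt_num(convergence)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-frequency error curve to CSV
#'
#' Columns `freq_hz`, `rel_err_percent`.
#'
#' @param path Output file path.
#' @param curve An `error_curve` from [error_curve()].
#' @return `path`, invisibly.
#' @export
write_error_curve_csv <- function(path, curve) {
  stopifnot(inherits(curve, "error_curve"))
  lines <- c("freq_hz,rel_err_percent",
             sprintf("%s,%s", .fmt_num(curve$grid$frequencies),
                     .fmt_num(curve$rel_err_percent)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a Nyquist table to CSV
#'
#' Columns `freq_hz`, `z_real_ohm`, `neg_z_imag_ohm` (see
#' [nyquist_table()]).
#'
#' @param path Output file path.
#' @param spectrum An [impedance_spectrum()].
#' @return `path`, invisibly.
#' @export
write_nyquist_csv <- function(path, spectrum) {
  tab <- nyquist_table(spectrum)
  lines <- c("freq_hz,z_real_ohm,neg_z_imag_ohm",
             sprintf("%s,%s,%s", .fmt_num(tab$freq_hz),
                     .fmt_num(tab$z_real_ohm), .fmt_num(tab$neg_z_imag_ohm)))
  writeLines(lines, path)
  invisible(path)
}
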