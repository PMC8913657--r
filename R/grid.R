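#' Logarithmically spaced frequency grid
#'
#' Builds the measurement grid used by impedance analyzers for swept-sine
#' spectroscopy: frequencies spaced uniformly in log10 at a fixed number of
#' points per decade, with both endpoints included.  The default sweep
#' (100 Hz to 100 kHz at 80 points per decade) matches the excitation
#' protocol of a typical electrochemical workstation run on plant tissue;
#' a wider 10 Hz start is selectable for low-frequency work.
#'
#' The number of points is `round(log10(f_max / f_min) * points_per_decade) + 1`,
#' so a whole-decade sweep has an exactly constant ratio of
#' `10^(1 / points_per_decade)` between consecutive frequencies.
#'
#' @param f_min Lowest frequency in Hz, must be positive.
#' @param f_max Highest frequency in Hz, must exceed `f_min`.
#' @param points_per_decade Grid density; positive integer.
#' @return A `freq_grid` object with fields `frequencies` (Hz, strictly
#'   increasing) and `points_per_decade`.
#' @examples
#' g <- make_grid(100, 100e3, 80)
#' length(g$frequencies)  # 241
#' @export
make_grid <- function(f_min, f_max, points_per_decade = 80) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || length(f_min) != 1L ||
      length(f_max) != 1L || !is.finite(f_min) || !is.finite(f_max) ||
      f_min <= 0 || f_max <= f_min) {
    stop("invalid frequency range: need 0 < f_min < f_max", call. = FALSE)
  }
  ppd <- as.integer(points_per_decade)
  if (is.na(ppd) || ppd < 1L) {
    stop("points_per_decade must be a positive integer", call. = FALSE)
  }
  n <- round(log10(f_max / f_min) * ppd) + 1L
  freqs <- 10^seq(log10(f_min), log10(f_max), length.out = n)
  freqs[1L] <- f_min   # guard endpoint round-off
  freqs[n] <- f_max
  freq_grid(freqs, points_per_decade = ppd)
}

#' Construct a frequency grid from explicit frequencies
#'
#' Validates positivity and strict monotonicity.  When the frequencies are
#' log-uniform, `points_per_decade` is checked (or inferred) against the
#' constant consecutive ratio; irregular grids (e.g. loaded from measured
#' data) are permitted with `points_per_decade = NA`.
#'
#' @param frequencies Numeric vector of frequencies in Hz.
#' @param points_per_decade Integer or `NULL` to infer from the spacing.
#' @return A `freq_grid` object.
#' @export
freq_grid <- function(frequencies, points_per_decade = NULL) {
  f <- as.numeric(frequencies)
  if (length(f) < 1L || anyNA(f) || any(!is.finite(f))) {
    stop("frequencies must be finite and non-missing", call. = FALSE)
  }
  if (any(f <= 0)) stop("all frequencies must be positive", call. = FALSE)
  if (length(f) > 1L && any(diff(f) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  ppd <- NA_integer_
  if (length(f) > 1L) {
    ratios <- f[-1L] / f[-length(f)]
    spread <- (max(ratios) - min(ratios)) / min(ratios)
    if (spread < 1e-9) {  # log-uniform
      ppd_est <- 1 / log10(mean(ratios))
      ppd <- as.integer(round(ppd_est))
    }
  }
  if (!is.null(points_per_decade)) {
    given <- as.integer(points_per_decade)
    if (!is.na(ppd) && !is.na(given) && given != ppd) {
      stop("points_per_decade does not match the grid spacing", call. = FALSE)
    }
    ppd <- given
  }
  structure(list(frequencies = f, points_per_decade = ppd),
            class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %d points, %.6g Hz .. %.6g Hz",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  if (!is.na(x$points_per_decade)) {
    cat(sprintf(", %d points/decade", x$points_per_decade))
  }
  cat("\n")
  invisible(x)
}

#' Impedance spectrum container
#'
#' Pairs a frequency grid with one complex impedance value (in ohms) per
#' frequency.  This is the exchange type between the model evaluators, the
#' fitting objective, and the CSV readers/writers.
#'
#' @param grid A `freq_grid`.
#' @param z Complex vector of impedances (ohms), same length as the grid.
#' @return An `impedance_spectrum` object with fields `grid` and `z`.
#' @export
impedance_spectrum <- function(grid, z) {
  stopifnot(inherits(grid, "freq_grid"))
  z <- as.complex(z)
  if (length(z) != length(grid$frequencies)) {
    stop("z must have one value per grid frequency", call. = FALSE)
  }
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z)))) {
    stop("impedance values must be finite", call. = FALSE)
  }
  structure(list(grid = grid, z = z), class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  n <- length(x$z)
  cat(sprintf("<impedance_spectrum> %d points, %.6g Hz .. %.6g Hz\n",
              n, min(x$grid$frequencies), max(x$grid$frequencies)))
  cat(sprintf("  |Z|: %.6g .. %.6g ohm\n", min(Mod(x$z)), max(Mod(x$z))))
  invisible(x)
}
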