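# Shared fixtures and small utilities for the suite.

# max relative deviation between two complex vectors
rel_dev <- function(a, b) max(Mod(a - b) / Mod(b))

# standard measurement grid (3 decades x 80/decade = 241 points)
std_grid <- function() make_grid(100, 100e3, 80)

# a coarse grid for cheap checks
coarse_grid <- function() make_grid(100, 100e3, 10)

# single-frequency grid
f1 <- function(f) freq_grid(f)

# the ideal-RC Debye fixture: alpha = 1, R_inf = 0, R_o = 100 kohm,
# C = 1 nF; at omega = 1/(R_o C) the impedance is (50 - 50i) kohm
debye_params <- function() c(alpha = 1, R_inf = 0, R_o = 1e5, C_alpha = 1e-9)
debye_freq <- function() 1 / (2 * pi * 1e5 * 1e-9)

# simplified_stem fixture whose high-frequency asymptote is reached at the
# 1e12 Hz surrogate (gamma high enough that the pith CPE shorts cleanly)
sstem_limit_params <- function() {
  c(alpha = 0.9, beta = 0.8, gamma = 0.9, R_o = 1e4, R_1 = 1.5e5,
    R_2 = 5e5, C_alpha = 5e-8, C_beta = 1e-8, C_gamma = 1e-8)
}

expect_spectrum <- function(x, n = NULL) {
  expect_s3_class(x, "impedance_spectrum")
  if (!is.null(n)) expect_length(x$z, n)
}
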