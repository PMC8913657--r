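---
title: "Fractional-order stem impedance models and their extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order stem impedance models and their extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemfit)
```

## The modeling problem

Bioimpedance spectroscopy excites a tissue with a small sinusoidal voltage
and records the complex impedance $Z(f)$ across a frequency sweep.  At low
frequency, current is confined to extracellular paths; as frequency rises,
cell membranes — which behave as imperfect, "fractional" capacitors —
progressively conduct, and $|Z|$ relaxes between plateaus.  Each such
relaxation is a *dispersion*.  Equivalent-circuit modeling compresses the
whole sweep into a handful of interpretable parameters: resistances of
anatomical current paths and the pseudo-capacitance/exponent pairs of
membrane interfaces.

The building block is the **constant phase element** (CPE) with impedance
$$Z_{\mathrm{CPE}}(s) = \frac{1}{C\,s^{\alpha}}, \qquad s = j\,2\pi f,$$
evaluated on the principal branch, so $|Z| = 1/(C\,\omega^{\alpha})$ and
the phase is constant at $-\alpha\pi/2$.  $\alpha = 1$ is an ideal
capacitor; $\alpha = 0$ a resistor $1/C$.  We adopt the angular-frequency
convention $s = j\,2\pi f$ (the EIS standard) and carry the
pseudo-capacitance in $\mathrm{F\,s^{\alpha-1}}$, so tabulated nF/µF
values are used verbatim.

## The five models

Three classical models and two anatomically motivated stem models are
implemented (`model_ids()`), each in two independent forms:

1. the closed rational expression, with every factor kept in
   $(1 + s^{\alpha} R C)$ shape so the high-order products of the stem
   model (total fractional degree $\alpha+\beta+\gamma+\zeta+\lambda$)
   do not overflow in double precision;
2. a **circuit-topology oracle** (`circuit_oracle_impedance()`) that walks
   the element tree of the published circuit diagram, adding impedances in
   series and admittances in parallel.

The oracle is the numerically safer reference (no polynomial expansion)
and is structurally independent of the algebra, so agreement between the
two — better than $10^{-9}$ relative, enforced over random in-bounds
parameters in the test suite — validates both.  The two paths deliberately
differ on degenerate inputs: the rational forms reject $C = 0$ and orders
outside $(0, 1]$, while the oracle treats $C = 0$ as an open branch and
allows order $0$ (CPE $\equiv$ resistor), which is what makes "all
capacitances open $\Rightarrow$ stem model $= R_o$" checkable.

The full stem model maps the stem cross-section onto six parallel
branches: the epidermis (a protective layer, plain resistor $R_o$), the
cortex, vascular cambium, phloem, and xylem (tube-like transport tissues,
each a series $R$–CPE branch), and the spongy pith (a bare CPE).  The
simplified variant merges the three vascular-bundle branches into one,
leaving $R_o$ in series with three parallel branches.  Consequences worth
noting: at DC every stem branch containing a CPE is open, so
$Z \to R_o$; at high frequency the pith CPE shorts the full stem model
($|Z| \to 0$) but only the parallel section of the simplified model
($Z \to R_o$).

## Search boundaries and reference parameters

`model_spec()` carries the published per-model search boxes (orders in
$[0,1]$; resistance ceilings of 80 MΩ for the Cole zero-frequency
resistance, 1 MΩ/10 MΩ for the double-Cole/double-shell resistances, 1 GΩ
for stem and 100 MΩ for simplified-stem resistances; capacitance ceilings
of 3, 4, 3, 100, and 10 µF).  `reference_params()` ships WCA-extracted
parameter sets for Marjoram, Salvia, and Lavandula stem segments (5 cm and
10 cm electrode spacing) for the three classical models.  The published
parameter rows for the two stem models contain typographic ambiguities
(e.g. a capacitance printed with two decimal points), so no measured stem
presets are shipped; instead each stem model carries one clearly labelled
*synthetic* reference set (`synthetic_a`) whose dispersions fall inside
the measured band — these are this package's own choices, not published
extractions.

## The objective and error curves

Fits minimize
$$J(x) = \sum_{i=1}^{n} \left| \frac{Z_{\mathrm{model}}(f_i; x) -
Z_{\mathrm{measured}}(f_i)}{Z_{\mathrm{measured}}(f_i)} \right|,$$
with $|\cdot|$ the complex modulus — the modulus of the complex relative
error, not separate real/imaginary terms, because the fit must track both
Nyquist components.  The per-frequency error curve is the same quantity in
percent; the objective equals the sum of the curve divided by 100, an
identity the tests assert.  $J = 0$ exactly on a noiseless self-generated
spectrum, and measurements containing an exactly zero impedance are
rejected (relative error undefined).

## Optimizers

Four population metaheuristics sit behind `minimize()` / `multi_run()`:
water cycle (WCA), flower pollination (FPA), cuckoo search (CS), and
chicken swarm (CSO).  Hyperparameters default to the original
publications' values (WCA: 4 rivers+sea, evaporation threshold
$d_{\max} = 10^{-16}$ decreased linearly; FPA: switch probability 0.8,
Lévy exponent 1.5; CS: discovery probability 0.25, Lévy step scale 0.01;
CSO: rooster/hen fractions 0.15/0.7, half the hens mothering, hierarchy
rebuilt every 10 iterations) and can be overridden per call.

Shared contracts: populations initialize uniformly within the bounds from
the run's seed; every candidate is clipped to the box before evaluation;
an objective value that is not finite is treated as $+\infty$ and never
returned as a best; the running best is recorded each iteration, so
convergence histories are non-increasing; run $k$ (0-based) of a
multi-run uses seed $\texttt{seed} + k$, and the selected result is the
minimum-objective run with ties broken by the lowest run index.
Identical configuration and seed reproduce results bit-for-bit.

Two implementation choices deserve a note:

* **Coordinate frames.** WCA, FPA, and CS search an internal $[0,1]$
  affine normalization of the box, because their absolute step constants
  (the $\sqrt{0.1}$ raining kick, the 0.01 Lévy scale) presuppose an
  $O(1)$ domain.  CSO searches in natural units: its rooster move is
  multiplicative, $x \leftarrow x\,(1 + \mathcal{N}(0, \sigma^2))$, i.e.
  scale-invariant about the natural origin, which is precisely what suits
  positive circuit parameters spanning decades; normalizing translates
  the optimum away from the origin and demonstrably cripples it.  Both
  frames are linear maps of the same box, so the search remains linear in
  the natural parameters.
* **CS acceptance.** The Lévy-flight candidate is compared greedily with
  its own nest (the behaviour of Yang and Deb's reference implementation
  of cuckoo search) rather than with a randomly chosen nest (their 2009
  article's prose); the former converges markedly faster and is what the
  field actually runs.

### Linear versus log-scale search

The published protocol searches the natural (linear) boxes, and that is
`fit_model()`'s default.  But the resistance/capacitance boxes span up to
nine decades while realistic parameters occupy a sliver of them (a 4 nF
capacitance inside a 3 µF box is 0.1% of the range), which makes the
linear-scale landscape brutally multimodal at small evaluation budgets.
`fit_model(..., log_scale = TRUE)` therefore searches $\log_{10}$ of the
R/C dimensions (orders stay linear), clamping each log-scaled lower bound
to $10^{-12}$ of its upper bound.  The model-ranking acceptance test uses
log-scale search *uniformly for every model*: measurements showed that at
the reduced protocol (30 agents × 300 iterations × 5 runs) linear-scale
fits of *all* models — including the generating one — stall an order of
magnitude above the noise floor, so the ranking would reflect optimizer
luck rather than model structure.  With log-scale search the generating
model reaches the noise floor and the comparison tests what it is meant
to test.

## Synthetic data

`simulate_spectrum()` evaluates a model on a log-spaced grid
(`make_grid()`; default 100 Hz–100 kHz at 80 points/decade, the measured
band — a 10 Hz start is equally supported since the source protocol is
ambiguous between the two) and applies proportional complex Gaussian
noise:
$$z_i^{\mathrm{noisy}} = z_i\,(1 + \varepsilon_i), \qquad
\varepsilon_i = \frac{\sigma_{\mathrm{rel}}}{\sqrt{2}}(g_{1i} + j g_{2i}),$$
so $\mathrm{E}|\varepsilon| = \sigma_{\mathrm{rel}}\sqrt{\pi}/2$ and
$\mathrm{RMS}(\varepsilon) = \sigma_{\mathrm{rel}}$, verified against a
Monte-Carlo oracle in the tests.  This emulates the roughly
magnitude-proportional error of an impedance analyzer; it does **not**
emulate electrode polarization, drift during a sweep, temperature effects,
or frequency-dependent noise floors.  A green recovery test therefore
establishes identifiability of the model from clean or mildly noisy data —
not robustness to the systematic artefacts of real electrode contact.

`sample_params()` draws uniformly within the boxes for property tests,
truncating orders to $[0.05, 1]$ (the order-0 limit degenerates a CPE
into a resistor, which the rational forms deliberately do not model) and
re-drawing Cole parameters until $R_o > R_\infty$.

## Numerical conventions and degenerate inputs

* Principal fractional power: $s^{\alpha} = (2\pi f)^{\alpha}
  e^{j\alpha\pi/2}$.
* Limit checks use surrogate frequencies $10^{-9}$ and $10^{12}$ Hz with
  relative tolerance $10^{-4}$; fixtures for these checks are chosen so
  the asymptote is actually reached at the surrogate (a low-order,
  low-capacitance pith CPE may legitimately not have shorted by
  $10^{12}$ Hz).
* Passivity holds by construction — every branch admittance has phase in
  $[0, \pi/2)$ for orders in $(0, 1]$, so $\mathrm{Re}\,Z > 0$ and
  $\mathrm{Im}\,Z \le 0$ — and is asserted over random draws.
* The objective and error-curve evaluators accept boundary parameter
  vectors (e.g. a fitted capacitance clipped to 0) through the rational
  forms, which degrade gracefully there; the strict per-model evaluators
  reject such inputs, because a user calling `stem_impedance()` with
  $C = 0$ almost certainly holds a unit error.

## Known limitations

* No measured plant spectra are bundled (none were published); all
  end-to-end evidence is synthetic-data based.
* The multi-run protocol is embarrassingly parallel but runs serially.
* CSO inherits the original algorithm's unbounded hen step factor
  $S_2 = e^{f_{r2} - f_i}$; the exponent is clamped at 50 to avoid
  overflow, and greedy acceptance discards the resulting wild candidates.
* Weighted/modulus-only objectives, Kramers–Kronig validation, and
  electrode-polarization correction are out of scope.
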