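---
title: "Methods: 13C tracer mass balance for sediment incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 13C tracer mass balance for sediment incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedprime)
```

# The measurement problem

When a 13C-labelled substrate (an algal lipid extract, a crude protein) is
added to an anoxic sediment slurry and the bottle is followed for months,
three processes shape the carbon budget at once:

* **mineralization** of the added substrate to dissolved inorganic carbon
  (DIC),
* **priming** — accelerated mineralization of the indigenous organic matter
  that was already in the sediment, and
* **secondary production** — synthesis of new microbial biomass from the
  consumed substrate.

None of these is observed directly. What is measured, per destructively
harvested bottle, is the amount of DIC and its δ¹³C, and (for biomass) the
concentrations and δ¹³C of hydrolyzable amino acids. `sedprime` implements
the bookkeeping that turns those measurements into process quantities, plus
a forward simulator of the whole experiment so the chain can be validated
by parameter recovery.

# Isotope bookkeeping

All mass balance is done on **atom fractions**, not δ values. With
$R = (\delta/1000 + 1)\,R_\mathrm{std}$ the atom fraction is
$x = R/(1+R)$; the default standard ratio is the VPDB consensus value
$R_\mathrm{std} = 0.0111802$, pinned as a package constant for
reproducibility and overridable everywhere. δ values are only a reporting
convention; averaging replicates, mixing pools and subtracting backgrounds
all happen on the $x$ scale.

The label added with a substrate (mass $m$ μg, carbon mass fraction $w$,
enrichment $x_s$) is quantified with the abundance-weighted mean atomic
mass $\bar M = x_s\,13.00335 + (1-x_s)\,12.000$ g mol⁻¹:
$n = m\,w/\bar M$ μmol. By the accounting convention usual in
highly enriched tracer work, this total substrate carbon is reported as the
micromoles of ¹³C — at 99 atom % the strict atom count differs by exactly
the factor $x_s$ (about 1 %), and `label_quantity(exact_atoms = TRUE)`
provides it for users who want the literal count.

# Partitioning the DIC pool

Each labelled bottle's DIC at time $t$ is treated as a two-end-member
mixture of substrate-derived carbon (at $x_\mathrm{sub}$, e.g. 0.99) and
everything else (at the background atom fraction $x_\mathrm{bg}(t)$):

$$f(t) = \frac{x_\mathrm{DIC}(t) - x_\mathrm{bg}(t)}
              {x_\mathrm{sub} - x_\mathrm{bg}(t)}.$$

Key choices, each of which matters on real data:

* **The background is the time-matched control**, not a fixed
  natural-abundance constant: the control's δ¹³C drifts as indigenous
  organic matter mineralizes, and using its replicate-mean atom fraction at
  each day removes that drift from the attribution. When control bottles
  were harvested on slightly different days (destructive harvests make
  exact matching impossible), the control curve is interpolated linearly in
  time, holding the endpoints flat; if no control exists for a depth the
  bottle's own day-0 value is used, with a warning.
* **Production since day 0** is reported per bottle: cumulative
  substrate-derived carbon is $\mathrm{DIC}(t)f(t)$ minus its day-0 value,
  and `di13c_umol` is that times $x_\mathrm{sub}$; indigenous production is
  the complementary difference. The two components add up to total DIC
  production exactly (before any clipping) — this mass-balance identity is
  tested to 1 part in 10⁹.
* **Negative values are kept.** Real control series are non-monotonic, so
  noise can make indigenous production negative. The per-replicate table
  retains such values and warns; nothing is silently coerced.
* **Mixing fractions are clipped to [0, 1]**, with a warning once the raw
  value leaves the interval by more than `noise_tol` (default 0.05); an
  excursion larger than that indicates a background mismatch rather than
  measurement noise.
* **"¹²C" units.** Indigenous carbon scaled by $(1 - x_\mathrm{bg})$ gives
  literal micromoles of ¹²C; this differs from total carbon by about 1.1 %
  at natural abundance. The default reports the scaled value
  (`units_12c = "12c"`); `"total_c"` reports total carbon, which is the
  natural scale when comparing against simulator truth.

Priming is then simply the difference in indigenous production between
amended and unamended bottles, and the priming factor their ratio
(undefined, and marked `NA`, when control production is not positive).

# Secondary production, CUE, and the equal-CUE estimate

Label incorporation into biomass is measured through hydrolyzable amino
acids. Concentrations are first normalised to carbon units with fixed
stoichiometric carbon counts (Gly 2 … Trp 11, shipped as a plain-text
table), because amino acids differ three-fold in carbon number. For each
acid, excess ¹³C above a baseline profile is
$n_\mathrm{C}\,(x_t - x_\mathrm{bg})$, summed over acids and converted to
per-bottle micromoles through the sample dry mass. The baseline is the
day-0 profile of the same treatment by default (`aa_background = "day0"`);
a time-matched control profile is available as an alternative, since which
baseline the experimenter prefers depends on whether the natural amino-acid
pool is expected to drift.

Protein ¹³C becomes biomass ¹³C ($^{13}C_B$) by division through the
protein share of biomass carbon, 0.6 by default and configurable — it is an
assumption about microbial composition, not a measurement.

Carbon use efficiency at time $t$ is
$\mathrm{CUE} = {}^{13}C_B / ({}^{13}C_B + \mathrm{DI}^{13}\mathrm{C})$:
the share of consumed substrate carbon that ended up in biomass rather than
DIC. Assuming indigenous and added substrates are used with the same
efficiency, biomass built from indigenous organic matter follows from its
observed mineralization:
$${}^{12}C_B = \frac{\mathrm{CUE}}{1-\mathrm{CUE}}\,
  \mathrm{DI}^{12}\mathrm{C}_\mathrm{total},$$
where the total is priming plus control production. The algebraic identity
${}^{12}C_B/({}^{12}C_B + \mathrm{DI}^{12}\mathrm{C}_\mathrm{total}) =
\mathrm{CUE}$ is tested to 1 part in 10¹².

# Degradation kinetics

Two routes are provided, because endpoint arithmetic and curve fitting
answer slightly different questions:

* `first_order_k()` is the closed form $k = -\ln(1-F)/t$ from a single
  endpoint fraction $F$; time is converted at 365.25 days per year (the
  choice moves $k$ by well under 0.1 %).
* `fit_two_g()` fits $F(t) = g_1(1-e^{-k_1 t}) + g_2(1-e^{-k_2 t})$ by
  bounded Levenberg–Marquardt least squares. Such fits are multimodal on
  sparse five-point harvest curves, so 8 deterministic starts on a
  log-spaced $k_1$ grid are tried ($k \in [0, 100]$ yr⁻¹, $g$ in a box via
  the `(k_1, k_2, g_\mathrm{tot}, \mathrm{split})` parameterisation) and
  the best residual wins, ties to the smaller $k_1$. A nested single-pool
  candidate from the same grid replaces the two-pool solution when it ties
  it, so data with no evidence for a second pool return $g_2 = 0$ rather
  than two duplicated pools.

A caveat worth stating: on a harvest design with one early time point, the
reactive pool's $k_1$ hangs almost entirely on that point. The package's
Monte-Carlo tests show the median relative error of $k_1$ at a cumulative-
fraction noise of 0.01 is roughly 20 % on such a design — noiseless
recovery is exact to $10^{-3}$, but sparse designs simply do not constrain
fast pools tightly.

# The forward simulator

`simulate_incubation()` generates the whole experiment from known
parameters so every analysis stage can be checked by inversion:

* substrate carbon sits in two first-order pools ($g_1, k_1, g_2, k_2$);
* a time-decaying fraction
  $\mathrm{cue}(t) = \mathrm{cue}_\mathrm{min} +
  (\mathrm{cue}_0 - \mathrm{cue}_\mathrm{min})e^{-t/\tau}$ of the uptake
  becomes biomass, the rest DIC — three parameters reproduce the observed
  qualitative pattern of efficiency falling from ~0.6 toward ~0.1;
* biomass respires at $k_B$, returning its carbon (at its own atom
  fraction) to DIC — necromass re-entering the substrate pool is
  deliberately not modelled;
* indigenous organic matter mineralizes at a constant baseline rate plus a
  priming flux $\alpha$ times the instantaneous substrate uptake — the
  simplest mechanism by which priming starts immediately and persists;
* biomass protein (60 % of biomass carbon) is spread over a fixed
  amino-acid composition to emit hydrolyzable amino-acid profiles;
* measurement noise (relative on DIC amounts, absolute in ‰ on δ¹³C) is
  drawn per bottle from streams derived deterministically from one root
  seed, so equal seeds give bit-identical tables.

**Integration.** The state advances on a fixed daily grid, but within each
step the substrate pools decay analytically, CUE is evaluated at the step
midpoint, and biomass relaxes exponentially with the step's uptake treated
as constant influx. Every unit of carbon leaving one ledger enters another,
so carbon and ¹³C conservation hold to rounding at any step size, and
halving the step changes harvest-day outputs by under 0.1 % (both are
tested).

**Truth conventions.** The truth table records exactly the estimands the
pipeline measures: `di13c_true` is $x_\mathrm{sub}$ times the cumulative
substrate-derived DIC carbon, and `b13_true` is biomass carbon times
$(x_\mathrm{sub} - x_\mathrm{nat})$ — the *excess* above natural abundance,
which is what amino-acid quantification against a baseline returns. With
the initial DIC δ¹³C equal to the indigenous-organic-matter δ¹³C (the
default), the time-matched control is an exact background end-member and
the pipeline run on noise-free output recovers DI¹³C, indigenous
production, $^{13}C_B$ and CUE to better than $10^{-6}$ relative — the
package's central validation property.

## The calibrated default scenario

`default_paper_scenario()` freezes a parameter set calibrated by least
squares so that its noise-free run, analysed by the pipeline, lands on the
reference harvest-day summary of a 400-day shallow-sediment lipid
amendment: about 63 % of the 16.5 μmol label mineralized by day 400, CUE
falling from 0.58 (day 8) to 0.09 (day 400), day-400 priming factor 2.5,
and control production of 21 μmol. Two calibration limits are worth
knowing. First, the reference priming series is non-monotonic in time
(small at day 180, large at day 400), which a monotone flux
$\alpha\,U(t)$ cannot represent; the scenario therefore matches the
endpoint priming, not the mid-course values. Second, the mid-course
(day 46) mineralization runs ~25 % below the reference value for the same
reason — the reference uptake curve stalls and then re-accelerates, which
no two-pool model with smooth CUE can do. Both deviations are visible, not
hidden: the scenario's full trajectory is what the tests assert.

## What the simulator does not emulate

Replicate δ¹³C scatter in real measurements is strongly
heteroscedastic (per-mil deviations grow enormously at high label uptake);
the simulator's Gaussian noise with constant standard deviation is a
simplification. Carbonate-system speciation, headspace/liquid
partitioning, CH₄, electron-acceptor budgets, community composition
dynamics and isotope fractionation during mineralization (negligible
against a 99 atom % label) are all outside the model. Passing
parameter-recovery tests therefore shows the *bookkeeping* is right, not
that the kinetic model is a complete description of sediment biogeochemistry.

# Degradation index

The amino-acid degradation index is the standardized linear score
$\mathrm{DI} = \sum_i \frac{\mathrm{mol\%}_i - \mu_i}{\sigma_i}\,\ell_i$
over a reference model of means, standard deviations and factor loadings.
Sample mole-% is expressed on the model's reference total (the shipped
reference means sum to slightly under 100 because the source statistics
cover a wider amino-acid set), which makes a sample exactly at the
reference composition score 0 by construction and keeps the score invariant
to total concentration. The packaged coefficient table is a transcription
of the classic reference set — its file header carries the provenance note
and users can supply any coefficient table through `di_model()`. The
default scores on molar mole-%; `basis = "carbon"` scores on mole-C
fractions instead.

# Problem sizes and determinism in the test suite

The shipped tests run the full chain at the scale of the experiment they
emulate: five harvest days, triplicate bottles, 400 simulated days at a
daily step. The Monte-Carlo checks use 100 simulated campaigns for the
noise-accuracy bound (median absolute relative error of day-400 DI¹³C
under 2 % DIC noise and 5 ‰ δ noise must stay below 5 %), 20 randomized
parameter sets for the conservation suite, and fixed seeds throughout; the
whole suite completes in well under a minute.

# Known limitations

* The equal-CUE estimate of ¹²C-biomass inherits every limitation of the
  CUE measurement and of the assumption itself; it is an extrapolation, not
  a measurement.
* Priming quantification is only as good as the control: with three control
  bottles per harvest the background atom fraction carries real
  uncertainty that is propagated only through replicate SDs, not formally.
* The 2G fit reports no parameter uncertainties; on five-point curves they
  would be large and strongly correlated. Use the Monte-Carlo pattern from
  the test suite if uncertainties are needed.
* The packaged degradation-index coefficients should be verified against
  the original publication before cross-study comparisons.
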