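# sedprime

Carbon-13 tracer mass balance for anoxic sediment incubations: organic-matter
mineralization, priming, carbon use efficiency (CUE) and microbial secondary
production, computed from tidy per-bottle measurement tables — plus a forward
simulator of the whole experiment for validation by parameter recovery.

## Who this is for

Biogeochemists and microbial ecologists running (or re-analysing)
stable-isotope labelling incubations: sediment slurries amended with a
¹³C-labelled substrate, followed alongside unamended controls, with dissolved
inorganic carbon (DIC) amount and δ¹³C measured at destructive harvests, and
optionally compound-specific δ¹³C of hydrolyzable amino acids for biomass
tracing.

## The model in brief

All bookkeeping runs on atom fractions, `x = R/(1+R)` with
`R = (δ/1000 + 1)·R_VPDB`. Evolved DIC in a labelled bottle is decomposed by
two-end-member mixing against the time-matched control background:

    f(t)      = (x_DIC(t) − x_bg(t)) / (x_sub − x_bg(t))
    DI13C(t)  = x_sub · [DIC(t)·f(t) − DIC(0)·f(0)]        substrate mineralized
    DI12C(t)  = indigenous production, the complement       indigenous OM mineralized
    priming   = DI12C(treatment) − DI12C(control)

Biomass label comes from amino acids: per-acid excess ¹³C above a baseline
profile, summed, divided by the protein share of biomass carbon (0.6):

    13C_B = Σ_i n_C,i (x_i − x_bg,i) / 0.6
    CUE   = 13C_B / (13C_B + DI13C)
    12C_B = CUE/(1−CUE) · (priming + control production)    equal-CUE estimate

Degradation kinetics: closed-form `k = −ln(1−F)/t` from endpoint fractions,
and a two-pool fit `F(t) = g1(1−e^(−k1 t)) + g2(1−e^(−k2 t))` with
deterministic multistarts. A degradation index over amino-acid mole-%
composition scores organic-matter freshness.

## Worked example

Simulate the calibrated default scenario (a 400-day shallow-sediment
incubation with 16.5 µmol ¹³C of algal lipids) and analyse it with the full
pipeline:

```r
library(sedprime)

lipid <- substrate_spec(500, 0.431, 99, "algal lipid mixture")
lipid
#> <substrate_spec> algal lipid mixture: 500 ug, 43.1% C, 99.00 atom% 13C (16.59 umol 13C)

sim <- simulate_incubation(default_paper_scenario())
report <- run_pipeline(list(
  incubation_csv = sim$incubation,
  amino_acid_csv = sim$amino_acids,
  substrate = list(mass_ug = 500, carbon_content = 0.431,
                   atom_percent_13c = 99, label = "algal lipid mixture")
))
dplyr::select(report$summary_display, day, di13c_umol_mean, priming_umol,
              di12c_control_umol, b13_umol, b12_umol, cue)
#>     day di13c_umol_mean priming_umol di12c_control_umol b13_umol b12_umol   cue
#>   <dbl>           <dbl>        <dbl>              <dbl>    <dbl>    <dbl> <dbl>
#> 1     0            0            0                  0        0       NA    NA
#> 2     8            0.7          4.43               0.42     0.96     6.65  0.58
#> 3    46            4.47        16.3                2.42     1.61     6.74  0.27
#> 4   180            8.11        25.4                9.45     1.39     5.99  0.15
#> 5   400           10.4         30.6               21        1.08     5.35  0.09
```

Reading the day-400 row: 10.4 µmol ¹³C of the 16.5 µmol added label was
mineralized to DIC (63 %); the amendment drove 30.6 µmol of extra
indigenous-OM mineralization on top of the 21 µmol in the control (priming
factor 2.5); 1.08 µmol ¹³C sits in new microbial biomass, giving a carbon use
efficiency of 0.09 — down from 0.58 at day 8 — and an equal-CUE estimate of
5.35 µmol of biomass built from indigenous carbon.

```r
report$kinetics
#>   depth_zone treatment model       k1_per_yr k2_per_yr    g1     g2      rms
#> 1 20-45      lipid     first_order     0.900    NA     1     NA     NA
#> 2 20-45      lipid     two_g           7.43      0.476 0.370  0.630  0.00982
```

The endpoint first-order constant for the lipids is 0.9 yr⁻¹; the two-pool
fit splits the substrate into a reactive pool (7.4 yr⁻¹) and a slow pool
(0.48 yr⁻¹).

Because the simulator's truth tables carry the same estimands, the entire
chain is validated by parameter recovery — `recovery_experiment()` runs
simulate → analyse → compare across seeds.

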