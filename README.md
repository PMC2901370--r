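# washhook

Post-hybridization washing is part of every microarray protocol, yet most
calibration methods treat the scanned intensities as equilibrium quantities.
On GeneChip-type PM/MM arrays that assumption bends the adsorption isotherm:
stringent washing removes ~90 % of the non-specifically bound background,
30–50 % of the specific targets on mismatch (MM) probes, but under 10 % of
those on perfect-match (PM) probes, so expression estimates that ignore
washing are biased — most strongly at low and high expression.

`washhook` is an R package for probe-level analysis of wash-series data
(and for washing-aware calibration of ordinary single-scan chips). It is
aimed at people working with probe-level PM/MM intensity tables who want to
quantify, model and correct the washing step. Its core is the washed
two-species Langmuir model

    Theta^P(t) = (X^{P,N} w^{P,N}(t) + X^{P,S} w^{P,S}(t)) / (1 + X^{P,N} + X^{P,S}),
    I^P(t)     = M * Theta^P(t),

with survival functions `w` driven by a power law of the binding constant,
`k = (K0/K)^gamma`, which makes the survival a sigmoidal function of the
initial intensity with limiting levels `w_min < w_max`, and by ensemble
power-law kinetics `log10 w^{P,h}(t) = -eta^{P,h} log10 t`. Around that
core the package provides:

* a **synthetic chip simulator** with planted physical truth (three washing
  drivers that cross-validate the analysis paths);
* **probe-level washing kinetics**: `w_inf = I(17)/I(0)`,
  `tau = -2/ln(I(2)/I(0))`, moving-average trends, sigmoid fits;
* the **hook analysis** (Delta-vs-Sigma) with explicit washing terms:
  curve construction, theory fits, regime classification, per-set S/N
  ratios, and the "washing hook" of asymptotic survival levels;
* **kinetics of the hook parameters** and their inversion into the
  per-mode washing exponents `eta^N`, `eta^{PM,S}`, `eta^{MM,S}` and the
  extrapolated cycle counts `t* = 0.1^(-1/eta)`;
* **positional nucleotide sensitivity profiles** (single-base and
  nearest-neighbour) and their washing difference profiles;
* **washing-corrected calibration** of intensities into specific binding
  strengths, with the Langmuir bias quantified.

## Worked example

Simulate a washed chip with planted per-mode power-law washing, run the
hook analysis at every scan, and invert the slopes into the washing
exponents:

```r
library(washhook)

ser <- generate_chip_series(chip_config(
  n_sets = 5000, noise_cv = 0.15,
  washing = list(driver = "powerlaw",
                 eta = c(N = 0.5, PM_S = 0.05, MM_S = 0.175)),
  seed = 42))

hs <- hook_at_timepoints(ser)
hs$fits[["t0"]]
#> hook_fit (standard): Sigma_start = 1.936, Delta_start = 0.033, alpha = 0.980,
#>   beta = 2.510, logM = 4.445, Delta_end = 0.415, rms = 0.0344
hs$fits[["t17"]]
#> hook_fit (standard): Sigma_start = 1.353, Delta_start = 0.022, alpha = 1.169,
#>   beta = 3.031, logM = 4.384, Delta_end = 0.574, rms = 0.0305

ks <- hook_param_kinetics(hs, O = ser$O)
we <- invert_washing_exponents(ks)
#> Warning: washing-exponent consistency residual 0.216 exceeds 0.100; ...
we
#> washing exponents: eta_N = 0.462, eta_PM_S = 0.078, eta_MM_S = 0.214 (residual 0.216)
#> t* (cycles to 10% survival): N 146, PM_S 7.75e+12, MM_S 4.6e+04
```

Reading the output: washing widens (`beta` 2.51 → 3.03) and heightens
(`alpha` 0.98 → 1.17) the hook — non-specific background is stripped while
PM-bound specific targets persist — and the recovered exponents sit within
±0.08 of the planted 0.5 / 0.05 / 0.175 despite 15 % scan noise. The `t*`
extrapolations say the non-specific background could be washed tenfold in
~10^2 cycles while PM-bound specific targets are effectively unwashable.
The consistency residual flags the (known, saturation-induced) bias of the
S/N-slope route; the least-squares solution reconciles it with the anchor
slopes.

The two-round staining arithmetic:

```r
e <- enrichment_two_rounds(w = 0.9, label_increment = 1)
sprintf("bright after round 2: %.0f%%, enrichment %.1f", 100 * e$bright_round2, e$enrichment)
#> "bright after round 2: 171%, enrichment 1.9"
```

A command-line front end over the same functions lives in
`inst/cli/washhook.R` (subcommands `simulate`, `hook`, `kinetics`,
`sensitivity`, `calibrate`; exit codes 0/2/3 for ok/validation/convergence).

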