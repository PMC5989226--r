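# hemebind

Quantitative UV-Vis spectroscopy for heme-protein interaction studies:
tight-binding titration fitting, dual-wavelength protein/heme
quantification, and absorption-spectrum coordination-state calls, with
a synthetic-data generator for validating all of it.

## Who this is for

Anyone characterizing a heme-binding protein at the bench: you titrate
hemin into an apo-protein, watch the Soret band grow, and want a
dissociation constant; you purify a partially heme-loaded preparation
and want to know what fraction carries heme; you record a 250-800 nm
spectrum and want to know whether the iron is hexacoordinate low-spin
or pentacoordinate high-spin.

## The model

Good heme proteins bind with K_d in the tens-of-nanomolar range while
titrations run at micromolar protein, so the free-ligand approximation
fails and the bound complex must come from the mass-action quadratic.
With an *active hemin fraction* x (the monomeric, binding-competent
share of the stock; the rest is aggregated):

    [DH]  = (S - sqrt(S^2 - 4 x [H]_tot [D]_tot)) / 2,
    S     = [D]_tot + x [H]_tot + K_d,
    A_obs = L (eps_DH [DH] + eps_H [H]_f),    [H]_f = [H]_tot - [DH]

The four parameters (K_d, eps_DH, eps_H, x) are fitted by multi-start
Levenberg-Marquardt least squares with K_d on a log scale. Companion
routines quantify protein content from paired A280/Soret readings via
the Reinheitszahl (A_Soret/A280 = 1.43 for the fully bound wild-type
complex), standardize hemin stocks (eps = 58,440 M^-1 cm^-1 at
385 nm), estimate eps280 from sequence, and classify heme coordination
from band positions (Soret 415-430 nm without a ~645 nm band: low
spin; Soret 385-400 nm with the 645 nm charge-transfer band: high
spin).

## Worked example

Simulate a bench-realistic titration (20 x 1 uL additions of 1 mM
hemin into 1 mL of 9.4 uM apo-protein, 0.002 AU photometric noise) and
fit it:

```r
library(hemebind)
truth <- binding_params(kd = 59e-9, eps_dh = 79400, eps_h = 27400, x = 0.81)
ser <- simulate_titration(titration_protocol(n_additions = 20),
                          d_total_initial = 9.4e-6, params = truth,
                          noise_sd = 0.002, seed = 42)
fit <- fit_titration(ser)
fit
#> Tight-binding titration fit
#> 1:1 tight-binding model parameters
#>   K_d    : 52.42 nM
#>   eps_DH : 78.85 mM-1 cm-1
#>   eps_H  : 27.75 mM-1 cm-1
#>   x      : 0.8206 (active hemin fraction)
#>   RSS 9.76e-05 over 21 points; converged: TRUE; 8 starts
```

At this noise level a single titration pins the coefficients to about
1% and K_d to within its sampling spread of the true 59 nM; the
bootstrap shows that spread directly:

```r
bootstrap_ci(fit, n_boot = 500, seed = 1)$ci
#>               lower        upper
#> kd     3.383330e-08 7.891772e-08
#> eps_dh 7.778980e+04 8.023682e+04
#> eps_h  2.659507e+04 2.879769e+04
#> x      8.094047e-01 8.322359e-01
```

Quantify heme content of a purified preparation from two absorbance
readings, and call the coordination state of a simulated spectrum:

```r
cfg <- quant_config(eps_dh_soret = 79400, eps_d280 = 30000)
quantify_heme_protein(a280 = 0.519, a_soret = 0.611, cfg)
#> Dual-wavelength heme-protein quantification
#>   [DH] 7.695 uM, [D]_f 3.058 uM, [D]_total 10.75 uM
#>   heme-bound fraction: 71.6%

classify_coordination(simulate_spectrum(c(low_spin_heme = 1e-5)))
#> Heme coordination call: hexacoordinate_low_spin
#>   Soret maximum at 425.0 nm; 645 nm CT band: FALSE
#>   peaks (nm): 280.0, 360.0, 425.0, 543.8
```

The bound fraction (71.6%) is [DH]/([DH]+[D]_f): the Soret reading
fixes the bound complex, and the 280 nm reading, after subtracting the
complex's own 280 nm contribution (eps_DH(Soret)/1.43), fixes the free
protein.

## Command line

A thin wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hemebind", package = "hemebind"))')
$CLI simulate titration --d-total-uM 9.4 --n-additions 20 --out titr.csv
$CLI fit --input titr.csv --out fit.json
$CLI hemin-stock --a385 0.58440
$CLI classify --input spectrum.csv
```

Data formats are plain delimited text: titrations as
`h_total_uM,a_obs` CSV with `#key=value` metadata lines, spectra as
`wavelength_nm,absorbance`, sequences as FASTA. Reports are JSON.

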