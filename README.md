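# isletins

Insulin acts back on the pancreatic β-cells that secrete it, but the
concentration of *receptor-active* insulin in the extracellular space of an
intact islet cannot be measured directly. Insulin leaves the β-cell as
zinc-stabilized hexamer crystals that must dissolve to dimers and then to
monomers before they can bind the insulin receptor, and most of the monomeric
insulin bathing an islet is not fresh secretion at all — it is peripheral
insulin returning with arterial blood after hepatic first-pass extraction.
`isletins` estimates this intra-islet monomeric insulin microenvironment with
a four-state kinetic model, for researchers studying autocrine/paracrine
insulin signaling, β-cell survival and the picomolar dose window in which
insulin acts on its own receptor.

## The model

Four concentrations (pM) are tracked in a single islet under a clamped
glucose concentration G (mM): hexamers *h*, dimers *d*, newly secreted local
monomer *m*, and returned peripheral monomer *I<sub>p</sub>*:

```
dh/dt  = s(G)/6 − p (h − q d³)
dd/dt  = 3 p (h − q d³) − p̂ (d − q̂ m²)
dm/dt  = 2 p̂ (d − q̂ m²) − (c + dᵢ) m
dIp/dt = k m − dᵢ Ip
```

Secretion enters as hexamers (hence `s(G)/6`); one hexamer yields three
dimers and one dimer two monomers. The secretion rate follows a Hill dose
response `s(G) = σ Gᵞ/(αᵞ + Gᵞ)` fitted by multi-start bounded least squares
to seven in vivo (glucose, secretion-rate) measurements. The remaining rates
come from physiological anchors: the degradation rate `dᵢ = ln 2 / 6 min`
from the circulating insulin half-life, the return coefficient `k = 3 dᵢ`
from the equilibrium observation that ~75% of intra-islet monomer is
returned peripheral insulin, and the transfer rate `c` from a total local
monomer clearance `c + dᵢ = 0.5 /min`. The system is cooperative with a
unique globally stable equilibrium, available in closed form:

```
m* = s(G)/(c + dᵢ),  Ip* = (k/dᵢ) m*,  d* = s(G)/(2p̂) + q̂ m*²,  h* = s(G)/(6p) + q d*³
```

## Worked example

```r
library(isletins)

fit <- fit_hill(secretion_table())
fit
#> Hill secretion fit (unweighted least squares)
#> <hill_params> sigma = 112 pM/min, alpha = 9.405 mM, gamma = 3.147
#>   SSE = 102.9 (pM/min)^2 on 7 points; 36/36 starts converged

params <- default_params()
islet_equilibrium(params, c(4, 5, 7, 16.5))
#> # A tibble: 4 × 6
#>   glucose_mM  h_pM  d_pM  m_pM Ip_pM total_monomer_pM
#>        <dbl> <dbl> <dbl> <dbl> <dbl>            <dbl>
#> 1        4    2.37  3.56  14.2  42.7             56.9
#> 2        5    4.50  6.74  27.0  80.9            108.
#> 3        7   10.6  15.8   63.4 190.             254.
#> 4       16.5 31.9  47.8  191.  574.             765.
```

The fitted maximum secretion rate is 112 pM/min with half-saturation near
9.4 mM glucose. Total monomeric insulin (`m_pM + Ip_pM`) stays in the
~50–300 pM window over the physiological glucose range (4–7 mM) — the
picomolar doses at which insulin acts most potently on β-cells — and
returned peripheral insulin (`Ip_pM`) is three quarters of it at every
glucose level.

Predictions validate against an observed peripheral-insulin dose response:

```r
validate_peripheral(params)
#> # A tibble: 3 × 4
#>   glucose_mM predicted_pM observed_pM rel_error
#>        <dbl>        <dbl>       <dbl>     <dbl>
#> 1        5           80.9         57     0.420
#> 2        7          190.         167.    0.136
#> 3       16.5        574.         567.    0.0115

step_response(params, glucose = 10, t_end = 120)
#> Glucose step 0 -> 10 mM from the empty islet
#>   equilibrium Ip* = 368.2 pM, total monomer = 491 pM
#>   Ip within 10% of equilibrium at t = 25.5 min
```

Agreement is tightest at the hyperglycemic clamp (1.2%) and loosest at
fasting glucose, where secretion is small and hardest to pin down. After a
step to 10 mM glucose the peripheral pool settles within 10% of equilibrium
in about 25 minutes.

`autoplot()` methods exist for fits, traces, step responses and validation
reports; `plot_dose_sweep()` shows the new-vs-returned monomer
decomposition across glucose.

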