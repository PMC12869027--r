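# qpat — quantitative photoacoustic tomography with integrated spectral and depth compensation

Multispectral photoacoustic tomography (PAT) images optical absorbers at
ultrasound resolution; from images at several near-infrared wavelengths
one can estimate oxygen saturation (%sO2) and total hemoglobin (THb) —
functional markers used, among other applications, to characterize
ovarian lesions. The catch is the fluence: the measured pressure is

    p0(R, λ) = Γ(R) · φ(R, λ) · μa(R, λ),

and the local fluence φ is neither flat in wavelength (spectral
coloring by overlying tissue) nor constant in depth. Conventional
linear unmixing (LU), which fits the pressure spectrum directly against
the oxy-/deoxy-hemoglobin extinction spectra under a non-negativity
constraint, therefore biases %sO2 systematically and lets THb decay
artificially with depth.

`qpat` implements the estimators and corrections around this problem,
for researchers developing or validating quantitative PAT pipelines:

* **LU** — non-negative least-squares unmixing (`lu_unmix()`,
  `lu_maps()`),
* **CC** — convex-cone estimation: fluence eigenspectra
  {φ1..φn} from Monte-Carlo simulation span a cone of realizable
  fluences; %sO2 is the candidate saturation minimizing the angle
  between the measured spectrum and the cone of
  φi(λ)·μa(λ; s) generators (`cc_estimate()`),
* **CLU** — compensated linear unmixing: LU applied to
  p(λ)/φave(λ), with φave the ensemble mean of the normalized
  eigenspectra, normalized to 1 at 800 nm (`clu_unmix()`),
* **ISDC** — integrated spectral and depth compensation: CLU for the
  saturation map plus depth-wise correction
  p·exp[(μf+μb)·z] for the total map (`isdc_maps()`,
  `compensate_depth()`), with μf fitted from simulated fluence decay
  (`fit_depth_attenuation()`).

A seedable 2-D voxel Monte-Carlo photon transport engine
(`simulate_fluence()`, C++ core), digital-phantom builders with exact
ground truth (`tube_phantom_spec()`, `sphere_phantom_spec()`,
`clinical_phantom_spec()`, `build_phantom()`), a forward pressure model
with controlled noise (`forward_pressure()`), cluster-wise evaluation
(`cluster_cross_sections()`, `uniformity_std()`, `thb_ratio()`,
`rank_compensators()`) and logistic-regression ROC classification
(`classify_lesions()`) make every stage testable without external data.
Sulfate phantom analogs (NiSO4/CuSO4 with the 14.28 concentration
scaling; `sni_from_concentrations()`) are supported throughout via the
`ox_scale` argument.

## Worked example

Simulate a depth-varying sulfate tube phantom (true nickel saturation
80%, uniform total sulfate), build the matched compensation model, and
compare the estimators cluster by cluster:

```r
library(qpat)
tab <- extinction_table()
wl <- seq(730, 830, by = 10)

bp <- build_phantom(tube_phantom_spec(sni = 80), tab, wl)

# matched digital-phantom simulation -> compensating spectrum + mu_f
sim <- simulate_fluence(bp$phantom, pa_source(), n_photons = 1e5, seed = 7)
eig <- extract_eigenspectra(sim, absorber_mask(bp$phantom))
dm  <- fit_depth_attenuation(sim, 800, fit_range = c(0.4, 2.2), mu_b = 0.5)
dm
#> Depth model: mu_f = 0.8397 cm^-1, mu_b = 0.5 cm^-1 (fit over 0.4-2.2 cm, R^2 = 0.9971)

# synthetic measurement at 30 dB SNR, then cluster-wise estimation
meas <- simulate_fluence(bp$phantom, pa_source(), n_photons = 1e5, seed = 8)
m  <- forward_pressure(bp$phantom, meas, noise_snr_db = 30, mu_b = 0.5, seed = 9)
cl <- cluster_cross_sections(m, 0.985, 8)
keep <- cl$summary$mean_depth_cm > 0.3   # drop near-field background sheet
cl$clusters <- cl$clusters[keep]; cl$summary <- cl$summary[keep, ]

sulf <- c("NiSO4", "CuSO4")
lu   <- unmix_clusters(cl, "lu",  table = tab, species = sulf, ox_scale = 14.28)
clu  <- unmix_clusters(cl, "clu", phi_ave = eig$phi_ave, table = tab,
                       species = sulf, ox_scale = 14.28)
isdc <- unmix_clusters(cluster_mean_spectra(cl, compensate_depth(m, dm)),
                       "clu", phi_ave = eig$phi_ave, table = tab,
                       species = sulf, ox_scale = 14.28)
```

With the near-field background clusters excluded (depth > 0.3 cm), this
run prints:

```
LU   mean %sNi 72.1 (truth 80), MAE 8.2, TSf spread 0.118
CLU  mean %sNi 80.8,           MAE 2.7
ISDC TSf spread 0.035 (LU 0.118): depth uniformity x3.4 better
```

Reading: LU underestimates the saturation by ~8 points because the
fluence reaching the tubes is colored by the scattering background;
dividing by the simulated φave removes most of that bias (CLU mean
80.8 vs truth 80, MAE 8.2 → 2.7). For the total-sulfate analog, the
per-cluster spread across depth (population SD of a quantity that
should be constant) drops from 0.118 to 0.035 once the
exp[(μf+μb)z] depth compensation is applied — the ISDC pipeline.

The methods vignette (`vignettes/isdc-methods.Rmd`) documents the
model, the synthetic-data generator and its deliberate simplifications,
and all numerical choices.

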