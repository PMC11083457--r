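# tifret

FRET efficiency estimation from time-resolved (TCSPC/FLIM) fluorescence
image stacks, including **time-integrated FRET (tiFRET)** — computing the
efficiency from the area under each pixel's decay curve instead of fitting a
preset number of exponential components — plus the FRET-spectrometry
post-processing chain and the kinetic theory of FRET in oligomers.

## Who this is for

FLIM users who want pixel-level Förster resonance energy transfer (FRET)
efficiencies without committing, in advance, to the number of donor
lifetimes in their sample. Classical FLIM-FRET fits each pixel's decay
histogram with `p` exponentials and computes

```
E = 1 − τ_DA / τ_D                        (single lifetime)
E = 1 − (Σ aᵢ τᵢ / Σ aᵢ) / τ_D            (amplitude-weighted mixture)
```

but choosing `p` requires knowing the oligomer's quaternary structure —
which is exactly what FRET spectrometry sets out to measure. tiFRET breaks
the circle by integrating the background-subtracted decay `p(t)` and
normalising by its amplitude:

```
E = 1 − (∫ p(t) dt / p₀) / τ_D
```

No component count is needed. The package implements all three estimators
on image stacks, the segmentation → per-segment histogram peak →
meta-histogram → single-Gaussian-fit chain that turns maps into a sample's
most probable efficiency, inverse-variance combination across experiments
(`E = Σ E_k/σ_k² / Σ 1/σ_k²`, `SEM = (Σ 1/σ_k²)^(-1/2)`), the kinetic
theory of FRET for donor/acceptor configurations (rate additivity:
`x = E/(1−E)`, `E = Σx/(1+Σx)`), and a TCSPC simulator with Poisson
counting noise, expression heterogeneity and optional acceptor
photobleaching that provides ground truth for every analysis step.

## Worked example

Simulate a 64×64 acquisition of a cell expressing a one-donor/one-acceptor
construct with relative transfer rate x = 1 (true E = 0.50), 3.0 ns donor,
1e4 photons/pixel, then run the full tiFRET pipeline:

```r
library(tifret)

spec <- sim_spec(
  regions = list(list(shape = "rect", corners = c(4, 59, 4, 59),
                      config = oligomer_config("NDA", rel_rates = 1.0),
                      label = "cell")),
  image_shape = c(64, 64), tau_D = 3.0, photons_per_pixel = 1e4, seed = 42)
sim <- simulate_flim_stack(spec)

map <- compute_fret_map(sim$stack, 3.0, method = "tifret")
map
#> FRET map (tifret): 64 x 64 pixels, 3168 valid (77.3%)
#>   E median 0.485, IQR [0.468, 0.498]

sp <- fret_spectrogram(map, sim$truth$masks[[1]])
sp
#> FRET spectrogram: 25 segments from 1 ROI(s)
#> Gaussian 1: mean 0.4960, sd 0.0100, amplitude 20.00
```

The spectrogram mean (0.496) recovers the ground truth within the
estimator's documented discretisation bias (the literal integral reads
≈0.008 low on a 256-bin, 12.5 ns axis; `correction = "geometric"` removes
it for mono-exponential decays). Combining repeated experiments:

```r
combine_experiments(c(sp$mean, 0.493, 0.505), c(sp$sd, 0.02, 0.03))
#> Combined efficiency over 3 experiment(s): E = 0.4962 +/- 0.0086 (SEM)
```

The kinetic theory predicts the two-acceptor construct's efficiency from
the two single-acceptor measurements:

```r
predict_two_acceptor_E(0.33, 0.32)  # -> 0.4906 (prints 0.49 at 2 d.p.)
```

A command line covering simulate / donor-lifetime / fret-map / spectrogram
/ combine / predict-ada lives at `inst/cli/tifret.R`:

```sh
Rscript inst/cli/tifret.R predict-ada --e1 0.33 --e2 0.32
#> 0.49
```

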