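---
title: "Estimating FRET efficiencies from time-resolved decays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FRET efficiencies from time-resolved decays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tifret)
```

## The estimation problem

A TCSPC/FLIM acquisition delivers, for every image pixel, a histogram of
photon arrival times relative to the excitation pulse. When a donor
fluorophore can transfer energy to nearby acceptors, its excited-state
lifetime shortens, and the FRET efficiency follows from comparing the
donor-in-sample decay against a donor-only reference lifetime $\tau_D$.
Three per-pixel estimators are implemented:

* **Single-lifetime**: fit one exponential, $E = 1 - \tau_{DA}/\tau_D$.
* **Mixture**: fit $p$ exponentials and use the amplitude-weighted mean,
  $E = 1 - \frac{1}{\tau_D}\,\frac{\sum_i a_i \tau_i}{\sum_i a_i}$.
* **Time-integrated (tiFRET)**: integrate the background-subtracted decay
  $p(t)$ and normalise by its amplitude $p_0$,
  $E = 1 - \frac{1}{\tau_D}\,\frac{\int p\,dt}{p_0}$.

The mixture estimator needs the component count $p$, which in oligomer
studies is set by the very quaternary structure one is trying to infer. The
integral estimator sidesteps that choice — this is its entire point — at
the cost of its own, well-characterised numerical behaviour (below).

A mathematical note the implementation leans on: for an exact
multi-exponential $p(t) = \sum_i a_i e^{-t/\tau_i}$,
$\int_0^\infty p\,dt / p(0) = \sum a_i\tau_i / \sum a_i$ — identical to the
amplitude-weighted mean of the mixture formula. The two estimators are
therefore equivalent on exact curves with exactly known amplitude; they
differ only through estimation error in $p_0$, background, and the discrete
bin sum. The test suite asserts this equivalence rather than any intrinsic
ordering between them.

### Assumptions

* Tail fitting, no deconvolution: fitting and integration start at the
  argmax bin; the instrument response is assumed narrow relative to the bin
  width. The simulator can generate IRF-blurred data to probe the
  assumption, but the analysis chain never deconvolves.
* The decay window (repetition period 12.5 ns at 80 MHz) truncates slow
  tails. For $\tau = 3$ ns the untruncated fraction beyond a 12 ns window
  is $\sim 2\%$; wrapped (incomplete-decay) acquisitions can be simulated
  to quantify the effect but are ignored by the estimators.
* Background is flat in time and estimated per pixel from the pre-pulse
  bins (the window before the excitation pulse).

## Per-pixel operations and their numerical choices

**Background** — mean of the first `pre_bins` bins, default
`max(4, rise_bin/2)`. With no pre-pulse window (`rise_bin = 0`) the caller
must pass a background explicitly.

**Amplitude $p_0$** — default `"headfit"`: a least-squares line through
$\log(\text{counts} - b)$ over the 10 bins from the argmax bin, evaluated
at the argmax time. The alternative `"peak"` (max bin minus background) is
kept for parity with naive implementations, but the maximum of Poisson
variates is biased high, which deflates $E$; the test suite demonstrates
the ordering. Non-positive values inside the head window are dropped;
fewer than 3 usable bins is an error.

**Integration** — $\sum_k \max(c_k - b, 0)\,\Delta t$ from the rise bin to
the end of the window. Clamping at zero prevents noise in empty tail bins
from producing negative area. `tail_mode = "monoexp"` fits a single
exponential to the last quarter of the window and adds the analytic
geometric-series continuation beyond it. In the per-pixel map pipeline the
default is `tail_mode = "none"`: at $10^4$ photons/pixel the last-quarter
bins hold $\lesssim 1$ count and the tail fit is noise-dominated, while the
truncation it would correct is $\le 0.1\%$ of the area for
$\tau \le 1.6$ ns.

**Discretisation** — the bin sum of a mono-exponential equals
$p_0\,\Delta t/(1 - e^{-\Delta t/\tau})$, so the literal
$\tau_\mathrm{eff} = \mathrm{area}/p_0$ overestimates $\tau$ by
$\approx \Delta t/2$ (+0.024 ns at 256 bins over 12.5 ns; $-0.008$ in $E$
at $\tau_D = 3$ ns). The default implements the integral formula literally;
`correction = "geometric"` inverts the series,
$\tau = -\Delta t / \log(1 - p_0 \Delta t/\mathrm{area})$, exact for
mono-exponentials.

**Exponential fitting** — Levenberg–Marquardt (minpack.lm) on
$b + \sum_i a_i e^{-(t - t_\mathrm{rise})/\tau_i}$ from the argmax bin,
with $b$ fixed at the measured background. Weights: first pass
$1/\max(c_k, 1)$, then one reweighting pass with $1/\max(\hat c_k, 1)$
from the fitted model. The reweighting matters: weighting by observed
counts overweights downward fluctuations and biases $\tau$ low by several
percent at $10^4$ photons/pixel; weighting by the model restores
unbiasedness (the property test runs 200 seeded replicates). Lifetimes are
bounded to $[0.05, 20]$ ns; initialisation is $\tau_0 = \mathrm{area}/p_0$
(for $p=2$: $\tau_0/2$ and $2\tau_0$ with equal amplitudes); up to 3
jittered restarts with fixed sub-seeds precede a failure. Two fitted
lifetimes closer than 5% of their mean collapse to a flagged
single-component fit.

**Map assembly** — pixels with fewer than `min_photons`
(default 100) background-subtracted photons, failed fits, or $E$ outside
$[-0.5, 1]$ are invalid; failures never abort a map. The negative-$E$
allowance down to $-0.5$ keeps counting noise at the null from truncating
the accepted distribution and biasing donor-only samples upward.

## From maps to a sample efficiency

Regions of interest are partitioned into 100-pixel squares by a
deterministic greedy sweep: anchors scan the ROI bounding box row-major and
a $10\times10$ square is placed wherever all its pixels are in-ROI and
unassigned, otherwise the anchor advances one pixel. (The published
moving-square algorithm this emulates is not specified at this level of
detail; the greedy row-major order is this package's deterministic
dialect.) Segments with under 50% valid pixels are skipped.

Each segment contributes the modal bin centre of its value histogram; the
peaks across all segments form the meta-histogram; a single Gaussian fitted
to it (unweighted least squares; initialised at the count-weighted moments)
gives the sample's most probable efficiency and its sd. Histogram bins are
fixed-width with *centres* on integer multiples of the bin width (half-up
edge rule). Centre alignment was chosen over edge alignment so that
degenerate data — a constant map — reproduce their value exactly instead of
acquiring a half-bin offset. Ties between modal bins break toward the bin
containing the median, then toward the lower bin, making peaks
deterministic. Defaults: segment-level $E$ bin 0.01, meta-histogram $E$ bin
0.02, lifetime bins 0.05 ns — all configurable; none is stated by the
measurement protocol this emulates, so they were fixed once at values that
resolve the simulated distributions without emptying bins.

When per-segment peaks quantise into fewer than 4 occupied meta-histogram
bins, a 3-parameter Gaussian is undetermined; the chain then falls back to
the count-weighted mean with sd floored at half a bin and flags the result
(`degenerate = TRUE`). Donor-lifetime extraction uses the same chain on
single-exponential lifetime maps and returns the Gaussian mean as $\tau_D$.

Experiments combine by inverse-variance weighting,
$E = \sum_k E_k/\sigma_k^2 \big/ \sum_k 1/\sigma_k^2$ and
$\mathrm{SEM} = (\sum_k 1/\sigma_k^2)^{-1/2}$.

## Kinetic theory of FRET in oligomers

A donor that can transfer to several acceptors adds transfer rates:
with relative rates $x_{da} = \Gamma_\mathrm{FRET}(d\to a)/\Gamma_D$, its
efficiency is $E_d = \sum_a x_{da} / (1 + \sum_a x_{da})$ and its lifetime
$\tau_d = \tau_D/(1 + \sum_a x_{da})$. A configuration's apparent
efficiency $E_\mathrm{app}$ is the mean over donors; its decay is one
exponential per *distinct* donor lifetime (relative tolerance $10^{-9}$,
configurable), amplitude proportional to multiplicity. Composing two
single-acceptor efficiencies predicts the two-acceptor arrangement:
$E_{ADA} = (E_1 + E_2 - 2E_1E_2)/(1 - E_1E_2)$, symmetric and never below
$\max(E_1, E_2)$.

For a parallelogram-shaped tetramer, all donor/acceptor assignments with at
least one of each number $2^4 - 2 = 14$; the $180^\circ$ rotation (opposite
-site swap) reduces them to $(14 + 2)/2 = 8$ orbits by Burnside's lemma.
Both enumerations are exposed (`symmetry = "none"` / `"c2"`); no figure's
configuration count is hard-coded, since published groupings may merge
cases under equivalences (e.g. mirror symmetry) that the text does not pin
down.

## What the simulator emulates — and what it does not

`simulate_flim_stack` draws, per pixel, Poisson counts around the exact
per-bin integral of the region's decay mixture (so closed-form oracles hold
to machine precision), with:

* acquisition defaults matching a typical two-photon FLIM setup: 256×256
  pixels, 256 bins over a 12.5 ns period (80 MHz), $\tau_D = 3.0$ ns, 60
  summed 1-s frame scans;
* log-normal pixel-to-pixel photon budgets (sd 0.3 in $\log_{10}$, mean
  $10^4$ photons/pixel) emulating expression heterogeneity — without it,
  segment histograms degenerate;
* flat background (default 0.5 counts/bin), optional Gaussian IRF blur
  (default off, since the analysis does not deconvolve), optional wrap
  modulo the period.

`simulate_with_bleaching` models acceptor photobleaching across the scan
series: after scan $s$ a fraction $(1-\beta)^s$ of oligomers still carry an
intact acceptor; bleached oligomers decay at $\tau_D$. The summed stack is
then a two-population mixture with FRET weight
$\overline{(1-\beta)^s}$, and every estimator reads below the pre-bleach
truth — the qualitative bias the model exists to demonstrate. This is the
simplest such model: binary FRET-on/off per oligomer, no donor bleaching,
no intra-scan kinetics, and $\beta$ is a free parameter, not a fit to any
instrument. Quantitative bleaching correction is out of scope.

Passing tests on this substrate shows the estimators and the post-
processing chain are correct *given* multi-exponential decays with Poisson
noise; it does not validate against detector afterpulsing, dead-time,
pile-up, autofluorescence, or cell-shaped spatial correlations, none of
which are simulated.

## Problem sizes and runtime

The test suite and acceptance checks use sizes chosen to exercise every
code path at comfortable statistical power: full-pipeline recovery on a
128×128 stack (144 segments), donor-lifetime recovery on a 64×64 stack,
bleaching bias on 32×32, 200 seeded replicates for the unbiasedness
property, and 8192-bin axes where closed-form agreement at $10^{-3}$ is
asserted. The whole suite runs in well under a minute on one core.

## Known limitations

* $p_0$ estimation on strongly multi-exponential decays inherits the head
  window's curvature; the headfit evaluates at the argmax bin, so the bias
  is second-order but not zero.
* The literal integral estimator carries the $+\Delta t/2$ discretisation
  offset on coarse axes (see above); enable the geometric correction or
  use finer binning when absolute accuracy at the $10^{-3}$ level matters.
* Two-exponential fits on decays whose lifetimes differ by less than
  roughly a factor of two are ill-conditioned at realistic per-pixel
  counts; the collapse rule reports them as effective single-lifetime
  pixels rather than returning unstable pairs.
* The donor reference is a single global $\tau_D$; spatial variation of
  the donor environment is not modelled.
* Proprietary raw TCSPC formats are not parsed; stacks enter as
  time-as-pages TIFF (with a JSON sidecar) or as the RDS container.
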