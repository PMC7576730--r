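---
title: "Elasticity spectra and the bilayer model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elasticity spectra and the bilayer model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastispec)
```

## The model

A spherical probe of radius $R$ indenting an elastic half-space of
Young's modulus $E$ and Poisson's ratio $\nu$ follows the Hertz relation
$F = \tfrac{4}{3}\,\tfrac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$. The
Oliver–Pharr generalisation links the *local* stiffness of the curve to
the modulus through the contact radius $a$:
$\mathrm{d}F/\mathrm{d}\delta = 2a\,E/(1-\nu^2)$, with $a=\sqrt{R\delta}$
for a sphere. Solving for $E$ gives the pointwise apparent modulus

$$E(\delta) \;=\; \frac{1-\nu^2}{2\sqrt{R\delta}}\,
  \frac{\mathrm{d}F}{\mathrm{d}\delta},$$

the **elasticity spectrum** of a curve. Two sanity properties anchor the
whole package and are enforced by tests: substituting the Hertz force
into this expression returns $E(\delta)\equiv E$ (a flat spectrum), and
the prefactor must scale as $\delta^{-1/2}$ — a $1/\delta$ prefactor is
dimensionally inconsistent with the $2a$ form and would make even a
Hertzian spectrum depth-dependent, so the $\delta^{-1/2}$ composition is
what we implement.

Cells are modelled as an elastic bilayer: a stiff surface layer
(stiffness $E_0$, thickness $d_0$ — the actin cortex) on a softer
half-space ($E_b$). No closed solution exists for layered spherical
contact; we adopt the phenomenological exponential decay in the contact
radius,

$$E(\delta) \;=\; E_b + (E_0-E_b)\,
  e^{-\Lambda\sqrt{R\delta}/d_0},$$

where $\Lambda$ is a dimensionless decay factor. Only the ratio
$\Lambda/d_0$ enters the model, so $\Lambda$ acts purely as a scale
factor on the fitted thickness: doubling it doubles $d_0$ and changes
nothing else (asserted numerically in the tests). Absolute thicknesses
therefore inherit the calibration of $\Lambda$; relative changes between
conditions do not. The default $\Lambda = 1.74$ is the value calibrated
against finite-element layered-contact data in the literature this
method follows.

## Pipeline parameters

| parameter | default | units | why |
|---|---|---|---|
| smoothing window | 25 | nm | noise reduction without flattening the contact kink |
| smoothing/derivative polynomial order | 3 | – | see "numerical choices" |
| RoV window | 300 (≤150 samples) | nm | long enough to estimate variances, short against curve scale |
| RoV prominence threshold | 10% of trace max | – | rejects noise peaks, keeps the method parameter-light |
| RoV absolute peak floor | 3 | – | a variance ratio that never exceeds 3 means no contact |
| refinement half-window | 100 | nm | see "contact point" |
| derivative step | 25 | nm | resolution/noise compromise of the spectrum derivative |
| resample step | derivative step / 5 | – | ≥3 samples per derivative window half |
| spectrum start | derivative step | nm | the $\delta^{-1/2}$ prefactor diverges at 0 and the slope estimate has no support yet |
| working-range hard cap | 800 | nm | beyond this the rigid dish inflates the apparent modulus on real cells |
| Hertz fit range | min(800 nm, R/10) | – | small-indentation regime of contact mechanics |
| $\nu$ | 0.5 | – | incompressible limit, standard for cells |
| $\Lambda$ | 1.74 | – | literature calibration; overridable per run |

All window lengths are physical lengths, converted to odd sample counts
internally, so results do not depend on the sampling rate.

## Contact point

The contact point $z_0$ is located by the **ratio of variances**: for
every interior sample, the force variance in a window after the sample
divided by the variance in a window before it. The trace peaks where the
noise content changes — at contact — without assuming any polynomial
shape for the post-contact curve, and the *last* sufficiently prominent
peak is taken (peaks at larger $z$ win ties), so spurious variance
changes in the approach baseline cannot pre-empt the true contact.

The bare RoV peak, however, is intrinsically biased late by the depth at
which the force first clears the noise floor
($\delta \approx (\sigma_F/A)^{2/3}$ with $A$ the Hertz prefactor —
several nanometres under typical conditions), because $F \propto
\delta^{3/2}$ starts with zero slope. Since
$E(\delta)\propto\delta^{-1/2}$, even a one-sample contact error
distorts the shallow spectrum by percents. The detector therefore
refines the peak with a local two-regime least-squares fit over a
±100 nm window: flat baseline before contact, baseline plus
$A\,\delta^{3/2}$ onset after, with the *deflection-corrected*
indentation $\delta = (z - z_c) - F/k$. The deflection term matters:
omitting it makes the fit lean on the compliance mismatch at the deep
end of the window and land several samples early. The surviving
sub-sample offset is removed by parabolic interpolation of the residual
minimum. In Monte-Carlo runs at 20 pN noise the median error is well
below one sample and every curve lands within ±2 samples; the unrefined
peak remains available (`refine = FALSE`) together with the full RoV
trace for diagnostics.

The 100 nm refinement half-window is a bias/variance compromise: wider
windows average more noise but violate the pure-$\delta^{3/2}$
assumption on layered samples (the modulus already decays within the
window), which we measured as a nanometre-scale early bias growing with
window length.

## Numerical choices

* **Derivative filter order.** Savitzky–Golay first-derivative filters
  come in even/odd pairs; the quadratic pair leaves a bias
  $\mathcal{O}(h^2 F''')$ that is negligible for smooth curves but
  distorts $E(\delta)$ exactly where $F$ curves fastest — the shallow
  depths that determine $E_0$. The cubic/quartic pair cancels that term;
  its larger noise variance is recovered by batch averaging. With the
  cubic filter the noiseless bilayer round trip recovers
  $(E_0, E_b, d_0)$ to better than 0.1%.
* **Positivity by log-parameterisation.** The bilayer fit optimises
  $(\log E_0, \log E_b, \log d_0)$ with `minpack.lm::nlsLM`, so all
  parameters stay positive without constraints; standard errors map back
  by the delta method. Five deterministically jittered restarts precede
  a non-convergence error.
* **Initialisation.** $E_0$ from the first 10% of the spectrum, $E_b$
  from the last 20%, $d_0 = R/10$.
* **Degenerate fits.** When the amplitude $E_0-E_b$ vanishes (flat
  spectrum) any thickness fits equally well; the fit is flagged
  degenerate when the $d_0$ standard error exceeds $d_0$ or the
  amplitude is below $10^{-3}$ of the modulus scale. A fit with
  $E_0 < E_b$ (soft layer on stiff bulk) is allowed but flagged.
* **Hertz fit.** $F = C\delta^{3/2}$ is linear in $C$, so the
  single-modulus fit is closed-form; a non-positive optimum (no positive
  force trend) is a fit error, which enforces $E>0$ without iteration.
* **Population summary.** Per-curve moduli are histogrammed
  (Freedman–Diaconis) and a Gaussian is fitted to the bin counts; the
  summary is peak ± SEM, which a 5% contamination of 10× outliers moves
  by under 2% (tested), unlike the mean.
* **Working range.** The end of the trusted range is the first depth at
  which a running 100 nm linear fit of the mean spectrum turns
  persistently positive after having been non-positive — the onset of
  the substrate-induced rise; without a rise the range runs to the hard
  cap.
* **Averaging.** Spectra are averaged pointwise on the union grid with
  no extrapolation: the per-depth curve count `n` drops as shorter
  curves run out, and truncation to the working range happens *after*
  averaging.

## Synthetic data: what it emulates, what it does not

The generator produces force–distance batches with cantilever
compliance ($z = z_0 + \delta + F/k$), a flat (optionally tilted)
pre-contact baseline, Gaussian force noise, and per-curve randomised
contact points, deterministic under a seed and accompanied by a
ground-truth manifest. Three forward models are available:

* **homogeneous** — the Hertz force;
* **bilayer_exponential** — the integral of the Oliver–Pharr relation
  over the exponential profile, in closed form (substituting
  $u=\sqrt{t}$ makes the integral elementary; it is cross-checked
  against adaptive quadrature in the tests). This generator is exactly
  consistent with the spectrum computation, which makes it the reference
  for round-trip validation: it isolates numerical error from model
  error.
* **bilayer_fea_surrogate** — a *synthetic* stand-in for numerical
  layered-contact (finite-element type) data: a sharp-interface bilayer
  whose apparent modulus is the step profile averaged with the
  normalised Hertzian axial-stress decay $1/(1+(\zeta/a)^2)$, giving
  $E_\mathrm{eff} = E_b + (E_0-E_b)\,\tfrac{2}{\pi}\arctan(d_0/a)$. It
  reproduces both film limits exactly and decays algebraically rather
  than exponentially, so fitting it with the exponential model exercises
  genuine model mismatch. Calibrating $\Lambda$ against this surrogate
  yields $\simeq 0.68$ with under 10% spread across the physiological
  parameter sweep ($E_0/E_b \in [1.05, 2]$, $d_0 \in [200, 500]$ nm) —
  a different decay-law convention than the published finite-element
  calibration (1.74), and a concrete illustration that $\Lambda$ is a
  convention that rescales $d_0$ rather than a physical constant.

What the generator does **not** emulate: viscoelastic (rate-dependent)
response, adhesion, thermal drift, the rigid dish under thin samples,
and instrument-specific artefacts. Passing tests therefore demonstrate
the correctness and noise behaviour of the *analysis*, not the adequacy
of the elastic bilayer description for any particular real sample.

## Reference geometry and study sizes

The reference bilayer experiment uses $E_0 = 9.8$ kPa, $E_b = 8.4$ kPa,
$d_0 = 300$ nm with a **sharp probe, $R = 300$ nm**. The radius is the
one genuinely open design choice: the decay of the spectrum happens in
the contact radius $a=\sqrt{R\delta}$, so the depth scale of the decay
is $\delta^* = d_0^2/(\Lambda^2 R)$. With a micron-scale bead
$\delta^*\approx 10$ nm — the whole decay hides below the 25 nm
derivative step and the layer parameters become numerically
unrecoverable — while at $R = 300$ nm the contact radius sweeps through
$d_0$ across the 25–800 nm working range and the decay spans depths
comparable with the thickness itself. Probe choice is part of the
experiment design: resolving a layer of thickness $d_0$ requires
$R \sim d_0$, which is why sharp indenters highlight cortical layering
where large beads average over it.

Tests and the acceptance computation use these problem sizes, chosen as
representative rather than exhaustive: 97-curve homogeneous batches
(5.2 kPa gel analogue at 20 pN noise), 500 curves for contact-point
statistics, 20 replicates of 100-curve bilayer batches with 5%
multiplicative spectrum noise for parameter recovery. For the recovery
study the spectra are sampled to 1.5 µm depth — synthetic bilayers have
no dish underneath, and the exponential must be ≥98% decayed
(exponent ≈ 4) for the asymptote, and hence the thickness, to be
identifiable; on real cells the 800 nm cap applies instead and the
thickness uncertainty grows accordingly.

## Known limitations

* Elastic, time-independent analysis; approach curves only.
* Spherical probes; no conical/pyramidal geometry, no adhesion models.
* The exponential bilayer is phenomenological: it captures the decay of
  layered samples but its $\Lambda$ (and hence absolute $d_0$) is a
  calibration convention, not a measured constant.
* At instrument-level force noise the shallow spectrum carries the
  $\delta^{-1/2}$ amplification; surface-layer parameters from small
  batches have materially larger uncertainty than bulk parameters
  (the fit reports per-parameter standard errors for exactly this
  reason).
* Quality control excludes curves (as the analysis assumes a flat
  baseline); it never repairs them.
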