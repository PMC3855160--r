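---
title: "A position-shift binocular energy model for disparity estimation"
author: "StereoEnergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A position-shift binocular energy model for disparity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StereoEnergy)
```

## The model

Binocular disparity — the horizontal offset between corresponding features
in the two eyes' images — is the primary cue for stereoscopic depth. V1
complex cells are classically modelled by the *energy model*: a binocular
simple cell sums the outputs of a left-eye and a right-eye linear filter;
two simple cells with opposite receptive-field (RF) polarity form a
push-pull pair (so the half-wave rectified ON and OFF outputs, squared and
summed, recover the square of the bipolar signal exactly); and two
push-pull pairs in quadrature (a quarter-cycle phase shift apart) sum to
the phase-invariant complex-cell energy. `StereoEnergy` implements the
*position-shift* flavour of this model: the left and right RFs have
identical shapes but displaced centres, and the displacement that maximises
(or minimises — both are diagnostic) the energy at a pixel reveals the
local disparity.

Formally, for a disparity hypothesis $\Delta x$ the left filter centre is
displaced by $+\Delta x/2$ and the right by $-\Delta x/2$ (a symmetric
split; for a uniform stimulus shift only the difference matters), and

$$E(x, y; \Delta x) \;=\; \big(e_L + e_R\big)^2 + \big(o_L + o_R\big)^2,$$

where $e$ and $o$ are the even and odd (Hilbert-pair) filter responses.
Writing $c = e + i\,o$ for the complex (analytic) response, this is
$|c_L + c_R|^2$, which is how the package computes it.

### Log-Gabor filters

The RFs are log-Gabor filters built directly in the frequency domain as the
product of two factors on a polar grid (radius $\rho$ in cycles/pixel,
anticlockwise angle $\varphi$):

* a radial weight $\exp\!\big(-\ln^2(\rho/f_0) \,/\, 2\ln^2(\sigma_r/f_0)\big)$ —
  a Gaussian on a logarithmic frequency axis. With the bandwidth parameter
  $\sigma_r/f_0 = 0.65$ the half-amplitude bandwidth is about 1.5 octaves,
  matching the average bandwidth of cortical complex cells. Unlike a linear
  Gaussian (the classical Gabor), this transfer function is symmetric on a
  log axis and carries exactly zero DC at any bandwidth;
* an angular Gaussian $\exp(-\Delta\theta^2/2\sigma_\theta^2)$ of the
  wrapped angular distance to the channel's wave-vector direction.

Orientations are specified as RF *stripe* orientations; the wave vector
points at $\theta - 90^\circ$. Both filter families’ orientation sets contain
$90^\circ$ — the vertically striped RF that is maximally sensitive to
horizontal disparity — which is why we read the angles this way.

The odd filter is the exact Hilbert transform of the even one along the
filter direction. We represent the pair by its one-sided (analytic)
transfer function: the product above restricted to the forward frequency
half-plane ($\Delta\theta < \pi/2$). The real and imaginary parts of the
complex inverse transform are then the even and odd responses. Two details
make the pair *exactly* quadrature on a discrete grid, which the test suite
asserts at $10^{-12}$:

* the angular envelope is hard-truncated at $\Delta\theta = \pi/2$
  (at the default $\sigma_\theta$ the envelope has already fallen to
  $\approx 0.056$ there, so this removes almost nothing);
* Nyquist rows/columns are excluded from the passband, like the DC bin:
  a bin that aliases $+0.5$ and $-0.5$ cycles/pixel cannot be assigned a
  one-sided phase.

A consequence of one-sidedness worth stating: channels whose stripe
orientations differ by $180^\circ$ (e.g. $30^\circ$ and $210^\circ$) are
frequency-domain conjugates and yield *identical* energies. The bank
still reports one map per nominal channel, but the engine computes each
conjugate pair once (an exact algebraic identity, covered by a test).

### The Gabor baseline

For comparison under matched conditions the package also provides the
classical sine/cosine Gabor pair, represented one-sidedly by a single
anisotropic Gaussian bump at the channel's wave vector. Its Hermitian-even
part is the cosine Gabor — which retains a nonzero DC response at
bandwidths over one octave — and its anti-Hermitian part the sine Gabor;
the two have unequal amplitude spectra where the mirrored lobe overlaps
(the "phase imbalance" of sine/cosine quadrature). Both defects are real
properties of Gabor filters and are deliberately left in place; mean
luminance is subtracted from the images before filtering for both
families, which removes the DC bin but not the near-DC imbalance.

Two Gabor-specific parameters are not derivable from first principles and
were fixed once:

* the radial Gaussian width is chosen so the half-amplitude *octave*
  bandwidth equals the log-Gabor's at $\sigma_r/f_0 = 0.65$
  ($\approx 1.46$ octaves), and the cross width is
  $f_0 \cdot \sigma_\theta$ — the small-angle equivalent of the angular
  Gaussian. This makes the two families differ only in the properties
  under study (log-axis symmetry, DC behaviour, quadrature exactness);
* the degree-based Gabor frequencies (0.5, 1, 2, 4 cycles/degree) are
  converted at `pixelsPerDegree = 12`, i.e. wavelengths 24, 12, 6, 3 px.
  The conversion is not stated anywhere authoritative; we derive it from
  the requirement of *equivalent experimental conditions*: the comparison
  is only meaningful if both banks span the same spatial scales, so the
  finest Gabor frequency (4 c/deg) is matched to the smallest log-Gabor
  wavelength (3 px). Both the frequencies and the conversion are config
  values.

## Energy integration over the RF extent

The per-pixel energy of a single narrowband channel is speckle-limited:
the envelope of the filtered dot pattern has Rayleigh-distributed
amplitude, so at a substantial fraction of pixels the response sits in an
amplitude null and the energy profile over $\Delta x$ is dominated by
interference rather than by the true disparity. A complex cell is not a
point sample — it integrates over its RF extent — and without that
integration per-pixel extremum selection recovers a uniform disparity at
only ~60–70% of pixels, which no amount of pooling across 24 highly
correlated channel maps repairs.

Each energy map is therefore integrated locally before selection: three
iterated separable box passes of width one channel wavelength
(odd-rounded), a close approximation to Gaussian smoothing with
$\sigma = \lambda/2$, i.e. the scale of the channel's own RF envelope.
Windows shrink at the image border rather than wrapping, so
circular-convolution artifacts are not spread. With this integration,
uniform-disparity recovery is essentially complete (the acceptance suite
demands $\ge 90\%$ per disparity and seed, and $\ge 95\%$ at zero
disparity). The flag (`smooth`) accepts `FALSE` (raw energies) or an
explicit window width; it is *not* the cross-channel Gaussian spatial
pooling of hybrid phase-and-position models, which the package
deliberately omits.

## Coarse-to-fine selection

For each orientation, disparity is estimated first at the coarsest spatial
frequency: among the *interior* local extrema (maxima or minima) of the
per-pixel energy profile over the hypothesis set, the one with the biggest
absolute response is selected. Each finer scale then selects the extremum
whose disparity is nearest the previous scale's value. The theoretical
basis: for a stimulus of uniform disparity $d$ in the hypothesis range,
the profile $|c_L(x - a) + c_L(x + a - d)|^2$ is exactly stationary at
$2a = d$ at *every* pixel, for *any* stimulus — a maximum where the
envelope is strong, possibly a minimum in an envelope null, hence
"maximum or minimum".

Deterministic details (all tested against brute-force oracles):

* endpoints of the profile are never extrema (edge responses are range
  artifacts); plateaus count once, at their centre, rounded toward the
  smaller $|\Delta x|$;
* first scale: ties in $|$response$|$ resolve to the smaller
  $|\Delta x|$, then the lower hypothesis index; with no interior extremum
  the global maximum of the profile is used;
* refinement: equidistant extrema resolve to the smaller $|\Delta x|$,
  then the lower index; with no extremum the previous value is carried.

The default hypothesis set spans $-10\ldots+10$ px — the $\pm 5$ px
synthetic stimuli with a factor-two margin — at 1 px steps for the square
stimulus and 0.25 px elsewhere. Selected disparities always belong to the
hypothesis set; no sub-step interpolation is performed.

## Pooling

The final map is the iterative robust average of all channel maps,
independently at each pixel: repeatedly remove the value farthest from the
current mean until $\lceil n/2 \rceil$ survive, then average the
survivors. Ties remove the lowest-indexed channel's value. We read
"reduce the spatial positions by half" as acting per pixel across channel
maps — the only reading that yields a dense final map. With 24 channels
this tolerates up to 11 arbitrarily corrupted values when the remaining 13
agree (a constructive breakdown test in the suite). A per-pixel median is
available behind `poolMedian` as a baseline.

## Synthetic stereograms

`makeStereogram()` generates the three benchmark families at 200×200 px
with seeded binary dot fields (density 0.5, 1 px dots — unstated anywhere,
so chosen as the standard RDS convention and made configurable):

* **square**: centred 100×100 px region at $+5$ px, surround $-1$ px;
* **ramp**: centred 160×160 px region ramping linearly $-5\ldots+5$ px
  along x, zero surround;
* **gabor_surface**: a Gaussian-windowed cosine corrugation scaled to a
  peak of 5 px. Its parameters are not stated authoritatively; we fixed
  them once at 0.25 cycles/degree on a 40 px/degree display (carrier
  wavelength 160 px — within the 0.2–0.4 c/deg band where human
  sensitivity to disparity corrugations peaks), envelope
  $\sigma = 40$ px, vertical corrugation, cosine phase (so the centre
  pixel attains the full 5 px). The display scale of the *stimulus* is a
  property of the simulated display and is independent of the filter
  bank's `pixelsPerDegree`;
* **uniform**: constant disparity, for calibration and recovery tests.

The right image samples the dot field at $x - d(x, y)$ with linear
interpolation (sub-pixel disparities are required by the ramp and surface
families); source coordinates falling outside the image are refilled with
fresh seeded dots, never wrapped. This inverse warp does not model
occlusion geometry: near disparity discontinuities dots are compressed,
stretched or duplicated rather than hidden, which is exactly where the
estimation errors concentrate. Passing the synthetic benchmarks therefore
says nothing about photometric effects, perspective, or true
half-occlusions in real imagery.

## Evaluation

Two metrics over the valid interior, after excluding a border frame:
the percentage of pixels whose absolute error *strictly* exceeds a
threshold (0.25 px for synthetic runs, 1 px for real-world pairs), and the
RMSE. The synthetic border default is 13 px — the largest log-Gabor
wavelength, rounded up — and is used for *both* filter families so their
scores describe the same region (the Gabor bank's 24 px coarsest
wavelength would otherwise dictate an incomparable region). Real-world
runs use an 18 px border. `batchEvaluate()` runs seeds
$s, s+1, \ldots, s+n-1$ and reports per-replicate and mean scores.

Problem sizes used by the shipped acceptance machinery: 100 replicates per
condition at 200×200 px, hypothesis range $\pm 10$ px. On one CPU the
three log-Gabor families complete in roughly six minutes; the Gabor
baseline (24 distinct channels — its orientation set contains no
conjugate pairs) roughly doubles that.

## Known limitations

* The robust-average reading of the pooling step and the per-orientation
  chaining of the coarse-to-fine refinement are the most natural but not
  the only readings of their one-sentence descriptions.
* At disparity discontinuities the coarse anchor can lock onto an
  interference extremum several pixels off; the refinement then tracks a
  sharp but wrong value. The resulting rare large errors dominate the
  RMSE of the log-Gabor pipeline on the square and ramp families. The
  blurrier Gabor baseline degrades more gracefully there, so the expected
  RMSE ordering between the families does not reproduce at discontinuities
  under this implementation, while the bad-pixel ordering does.
* The $\sigma_\theta$ default (0.6545 rad) is a coverage convention for
  six orientations, not an authoritative value.
* Fractional positional shifts are exact (frequency-domain phase ramps),
  but energies are only examined on the hypothesis grid; no parabolic or
  other sub-step refinement is attempted.
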