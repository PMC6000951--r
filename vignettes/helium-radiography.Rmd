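---
title: "Single-ion helium radiography: the imaging model and its processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-ion helium radiography: the imaging model and its processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionrad)
```

## The imaging problem

Ion-beam radiography measures the water-equivalent thickness (WET) of an
object by sending ions through it and recording, ion by ion, where each one
went and how much energy it deposits in a thin detector behind the object.
The beam energy is chosen so that the ions exit the object on the *rising
flank of the Bragg curve*: there, the energy deposited in a thin silicon
layer is a steep, monotone function of the residual range, so a small WET
change inside the object (here, a 1 mm air gap in a 161 mm PMMA block —
a 0.6% WET difference) translates into a measurable change in the deposited
energy. Helium ions are attractive for this task because at the same range
their multiple-Coulomb-scattering (MCS) angle is about half that of protons,
which directly improves the achievable spatial resolution, while they are
less demanding than carbon ions in terms of fluence per image information.

`ionrad` implements both halves of the problem at desk scale:

* a **simulator** of a five-layer pixel-detector system (two front tracker
  layers, one energy-deposition layer, two rear tracker layers; 300 um
  silicon sensors, 55 um pixels, 256x256 channels, 1 ms frames) that
  transports single ions through a step phantom and renders realistic sparse
  pixel frames, including the artifact classes a real acquisition shows; and
* the **processing chain** that turns those frames into a quantitative
  radiograph: cluster finding, per-pixel calibration, cleaning cuts,
  alignment, single-ion tracking and matching, helium/hydrogen
  identification, mid-plane image formation, and CNR/MTF quality metrics.

## Transport physics

Energy loss uses the plain Bethe-Bloch stopping power (no shell or
density-effect corrections) with hard-coded material constants
(water I = 75 eV; PMMA I = 74 eV, rho = 1.19 g/cm^3; silicon I = 173 eV;
air), integrated into CSDA range tables on a log-spaced grid from a
0.5 MeV/u cutoff and inverted by monotone splines. The omitted corrections
matter at the percent level here; the model reproduces published proton
stopping powers at the therapy energies to well under that (e.g.
4.49 MeV cm^2/g for 200 MeV protons in water), and every physics routine is
cross-checked in the test suite against an independently coded fine-step
quadrature oracle to 2%.

Scattering uses the Highland parameterisation of the projected MCS angle.
One subtlety is composition: Highland's logarithmic term refers to the whole
traversed thickness, so when the transport splits the phantom into sub-slabs
(eight per half, to track the energy dependence and the lateral displacement
development), each sub-slab kick is rescaled to the whole-path logarithm.
Without this, the composed variance underestimates the full-thickness
formula by ~20%. Within each slab the standard correlated angle/offset pair
is sampled, and the slab drift uses the entry slope — the exit-position
variance is verified against an analytic composition oracle at the 10%
level. Energy-loss noise is Gaussian with Bohr's variance; Landau/Vavilov
tails are deliberately out of scope.

Nuclear interactions are reduced to the one channel that matters for the
image: a primary helium ion may fragment once, at a depth uniform in the
phantom, into a hydrogen fragment that keeps the energy per nucleon and
receives an extra angular kick of three Highland sigmas of the remaining
path. The default probability 0.13 reproduces the observed event taxonomy,
where hydrogen rejection removes 12-13% of otherwise usable events. This is
an imaging-level surrogate, not a nuclear model: fragment spectra, multiple
fragments per primary, and target fragmentation are not modelled.

## Detector response model

Each impact deposits its sensor energy in a 2-D Gaussian charge cloud whose
width grows with deposition (`sigma = sigma0(bias) + k sqrt(E)`,
sigma0 = 28 um at 10 V, 20 um at 40 V, k = 9.6 um/sqrt(MeV)); pixels above
an 8 keV threshold fire. With these constants a typical helium cluster
(~5 MeV) spans about 20 pixels and a hydrogen fragment (~1.3 MeV) about
half that, so the (cluster volume, cluster size) plane separates the two
species — the premise of the pattern-recognition identification.

The energy-mode response has two deliberate nonlinearities mirroring the
bias-voltage behaviour of the real sensor. At 40 V (full depletion) the
response is linear up to 2 MeV and then saturates, exceeding a 20% deficit
at 5 MeV (improper digitisation of large signals). At 10 V (partial
depletion, the default operating point, chosen for contrast) the response is
linear with slope 0.6; the package recovers the true deposition with a
monotone-spline recalibration fitted to a simulator-generated
(measured, true) scan and refined once with a residual-ratio pass. The
recalibrated deposition is verified to within 7% across 0.2-17 MeV. On top
of this, every pixel carries a multiplicative gain (log-normal, 5% sd) and
the standard linear-plus-hook electronics response
`counts = a E + b - c/(E - t)`; the calibration map stores the four
parameters per pixel and the analysis inverts them exactly (flat-field
response CV < 2% after calibration). Counters saturate at 11810 counts;
arrival times are quantised to 100 ns ticks within 1 ms frames.

Artifact classes and defaults:

* **Radiation background** — 1-2 pixel, low-count clusters, 30 per frame
  per layer.
* **Overshoot** — clusters containing a pixel above ~1 MeV may develop a
  distorted signal (probability 0.25): multiplied counts in energy mode, an
  anomalous arrival-tick spread in time mode.
* **Temporal cropping** — ions arriving within 65 us of a frame boundary
  are only partially digitised; their energy counts are scaled by a random
  factor. The 65 us guard makes the cropped fraction ~13%, consistent with
  the removal of cropped clusters costing 12-13% of usable events. (A guard
  tied directly to the full 260 us digitisation time would crop more than
  half of all ions, which contradicts that taxonomy; the cleaning cut uses
  the same 65 us guard so that the cut removes exactly the degraded
  population.)
* **Overlaps** — with probability 0.02 an ion's energy-layer cluster is
  merged with a companion deposit 3.2-4.2 pixels away, producing one
  connected region with two local maxima.

Geometry: phantom faces at z = +/-80.5 mm, front tracker at -100/-90 mm,
energy layer at +95 mm (the isocenter layer, < 4 cm from the phantom), rear
tracker at +105/+115 mm. Each layer budget is ~1 mm WET (0.3 mm silicon
sensor plus a 0.4 mm water-equivalent thinned readout). Straight CSDA
transport of the 168.3 MeV/u beam through this stack predicts ~5.3 MeV in
the energy layer, inside the 5.1 +/- 0.6 MeV operating window the system is
designed for.

## The processing chain

1. **Cluster analysis.** Connected-component labelling (8-connectivity by
   default, so round clusters with corner pixels do not fragment) across all
   frames at once; descriptors include the count-weighted sub-pixel
   centroid, arrival tick and tick spread, and the number of local maxima
   with strict-dominance candidates and plateau merging (so a flat-topped
   peak counts once). The partition is tested against a brute-force
   union-find oracle and is order-independent; volumes conserve the frame
   content exactly.
2. **Cleaning cuts.** Overlap = two or more local maxima; overshoot = tick
   spread above one tick, or any calibrated pixel above 1 MeV, or a
   non-invertible pixel; background = small low-volume clusters; cropping =
   arrival tick within the 65 us guard of the frame boundary. Cropping
   deteriorates only the energy information, so it rejects at the event
   level (the energy cluster inherits the matched tracker arrival time)
   rather than discarding tracker clusters.
3. **Alignment.** From a phantom-free narrow-beam run (4.9 mm FWHM at
   220.5 MeV/u), each layer's fluence maximum is estimated by a
   median-anchored, outlier-clipped mean; offsets are differences to the
   reference layer 3. Because every layer sees essentially the same ions,
   the beam's own randomness cancels in the differences, and injected
   offsets up to four pixels are recovered to well under half a pixel
   (a few um at 10^4 ions).
4. **Tracking and matching.** Clusters pair across the two layers of a
   tracker when their arrival ticks agree within one tick; ambiguity is
   broken by nearest position, and anything still ambiguous is dropped —
   purity over efficiency, since a mispositioned event biases the image
   while a lost one only costs dose efficiency. Front and rear segments
   match by the same rule; the rear segment extrapolates to the energy layer
   and adopts the nearest clean energy cluster within 220 um
   (four pixel pitches).
5. **Identification.** A linear discriminant in (recalibrated volume,
   cluster size), fitted on simulator truth and shipped as the default
   boundary (refittable with `fit_species_boundary()`), separates helium
   from hydrogen with >99% accuracy at the default settings.
6. **Image formation.** The front segment extrapolated to the upstream
   face and the rear segment back-extrapolated to the downstream face are
   joined by a straight connection line; the deposited energy is accumulated
   in the 220 um bin containing the line's crossing of the mid-phantom
   plane (whole-bin assignment, no splatting, so per-bin noise stays
   uncorrelated). Channels: ion count, mean and SD of deposited energy,
   mean front/rear angle change, mean cluster size. With more WET (the
   full-PMMA side) the ions sit deeper on the rising Bragg flank and deposit
   *more*; the air-step side deposits less. Bins never hit by an accepted
   ion are left undefined and excluded from all metrics.

## Image quality

CNR is the difference of the two ROI means over the pooled per-bin standard
deviation, `|mu_step - mu_ref| / sqrt((sd_step^2 + sd_ref^2)/2)`; no
standard form exists in the field, so this symmetric choice is used
consistently for every stage-ratio statement. Default ROIs are two
4.4 x 4.4 mm squares centred 3 mm either side of the edge, echoing the
4.4 mm profile-averaging span.

Spatial resolution uses the oversampling technique: event distances to the
edge are pooled across a 4.4 mm span into 22 um bins (a tenth of the image
pixel), the edge-spread function is differentiated with a 5-point
Savitzky-Golay filter, and the MTF is the normalised Fourier modulus of the
line-spread function; `f10` is the 10% modulation frequency by linear
interpolation, and the LSF FWHM is read off the profile. Because raw 22 um
derivatives are noise-dominated on low-contrast profiles, a weighted
error-function fit of the ESF is carried alongside (two-pass: plateau levels
from the outer regions first, then centre and width), and its
`f10 = 0.3412/sigma` is the robust figure used for stage and species
comparisons. On clean Gaussian edges both routes agree with the closed form
to 5%.

## What the generator does and does not emulate

The generator reproduces the features the processing chain is built to
handle: Poisson frame occupancy below 1%, charge-sharing clusters with
realistic size/volume distributions, bias-dependent nonlinear response,
per-pixel gain structure, hydrogen contamination, detector-edge losses of a
10.6 mm FWHM beam on a 14 x 14 mm sensor, and the four artifact classes.
It does not emulate Landau straggling tails, delta rays, nuclear halos,
detector aging under high fluence, time-walk, or dead-time between frames;
its fragmentation is a single-channel surrogate. Passing the synthetic
acceptance checks therefore demonstrates that the *processing chain* behaves
as designed under controlled conditions — not that the simulator predicts an
individual physical detector's absolute performance.

## Problem sizes and determinism

Every simulation is seeded and byte-reproducible. The test suite uses a
~12k-primary run for module statistics; the stage-wise comparison runs at
the fluence delivering ~450 uGy mean phantom dose with the default beam
(~120k primaries), the dose at which the step should be clearly visible
(CNR >= 2); and the helium/proton comparison is run at a matched 150 uGy
each (protons need four times the fluence of helium at equal dose, which is
also why their image statistics are intrinsically poorer per ion). Alignment
recovery uses 10^4 ions. These sizes were chosen so that each quantity's
statistical error is small against the margin it is tested to.

## Known limitations

* The CSDA/Highland model carries no nuclear attenuation of the primary
  fluence beyond the fragmentation channel, so absolute fluence-to-dose
  bookkeeping at depth is a few percent optimistic.
* Near the end of range (protons behind this phantom) scattering is so
  strong that a single-Gaussian edge model is only an approximation; the
  erf fit then measures an effective core width.
* The recalibration curve is fitted on the same response model it inverts;
  on a real detector the scan would come from measured/Monte-Carlo pairs,
  and the quoted 7% envelope is the verified property of the procedure, not
  of any physical sensor.
* One-dimensional step edges only; curved-path (most-probable-path)
  reconstruction and tomography are out of scope.
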