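# ionrad

Single-ion helium radiography at desk scale: a simulator of a five-layer
silicon pixel-detector imaging system, and the full data-processing chain
that turns its sparse pixel frames into quantitative radiographs of a step
phantom.

## The problem

Ion radiography images the water-equivalent thickness (WET) of an object by
tracking single ions through it and measuring, behind the object, the energy
each ion deposits in a thin (300 um) silicon layer. The beam energy is tuned
so that the ions exit on the **rising flank of the Bragg curve**, where the
deposited energy `dE` in a thin layer is a steep monotone function of the
residual range: a small WET change `dWET` inside the object shifts the
deposition by roughly

    dE ≈ (d/dR)[A·(E(R) − E(R − t_Si))] · dWET,

so a 1 mm air gap in a 161 mm PMMA block — a 0.6% relative WET change —
becomes a visible contrast. Helium is a sweet spot among imaging ions: its
Highland multiple-scattering angle

    θ0 = 13.6 MeV/(β c p) · z · sqrt(x/X0) · (1 + 0.038 ln(x/X0))

is half the proton value at equal range (`z/p` halves at equal velocity),
which directly buys spatial resolution.

The package implements, as tested code:

* **Physics**: Bethe–Bloch stopping power, CSDA range tables and inversion,
  WET, Highland scattering, Bohr straggling, fluence→dose
  (`D = Φ · S/ρ · 1.602e-10 Gy·g/MeV`).
* **Simulator**: ion-by-ion transport through front tracker → step phantom →
  energy detector → rear tracker; Gaussian charge-sharing clusters with
  bias-voltage response models (40 V quenching, 10 V partial-depletion),
  per-pixel gain/hook electronics, counter saturation, 100 ns arrival
  ticks; artifact injection (background, overshoot, temporal cropping,
  overlaps); ground-truth table for every primary.
* **Analysis**: frame decoding, connected-component cluster analysis with
  sub-pixel centroids, per-pixel calibration and partial-depletion
  recalibration, cleaning cuts, beam-centroid alignment, tick-based track
  matching, 220 um energy-cluster association, LDA helium/hydrogen
  identification, mid-plane connection-line radiographs, and CNR /
  oversampled-edge MTF quality metrics.

## Worked example

```r
library(ionrad)

run <- simulate_run(acquisition = acquisition_spec(frames = 400, seed = 11))
run
#> <ionrad_run> 11805 primaries, 400 frames, 926737 pixel hits

ev <- build_events(run)                       # clusters -> accepted events
sum(ev$accepted)
#> [1] 3648

ev  <- event_midplane_position(ev[ev$accepted, ], run$phantom)
img <- accumulate_image(ev[ev$midplane_ok, ]) # 220 um multi-channel image
rois <- default_rois(0)
cnr(img, rois$step, rois$reference)
#> [1] 1.32

compute_dose(run$beam, run$phantom, n_ions = nrow(run$truth))
#> <dose_report> fluence 9.27e+03 /cm2 (11805 primaries), mean phantom dose 43.9 uGy

autoplot(img)                                 # ggplot raster of the step
```

11805 primaries at the default 168.3 MeV/u, 10.6 mm FWHM helium beam
deliver ~44 uGy; 3648 ions survive the full cleaning/matching/identification
chain, and the 1 mm air step already shows at CNR 1.3.

At the fluence delivering ~450 uGy (≈121k primaries) the cumulative
processing stages give, on the default synthetic run:

```r
d   <- compute_dose(dose = 450e-6)
run <- simulate_run(acquisition = acquisition_spec(
         frames = ceiling(d$n_ions / 30), seed = 5))
stage_comparison(run)
#>   stage       n_events   cnr  sr_f10_lp_mm  cnr_ratio
#> 1 raw           199545 0.875         0.307         NA
#> 2 cleaned        68816 1.188         0.220       1.36
#> 3 helium_only    56721 2.376         0.200       2.00
#> 4 tracking       36756 3.364         0.613       1.42
```

Artifact cleaning, hydrogen rejection and tracking-based mid-plane
positioning each raise the CNR (total 3.8x over raw data); the connection
line between the measured entry and exit points triples the spatial
resolution, to 0.61 lp/mm at 10% MTF with the 1 mm step clearly visible
(CNR 3.4) at the diagnostic-level dose.

A thin CLI over the same functions ships in `inst/cli/ionrad.R`
(`physics`, `simulate`, `clusters`, `events`, `image`, `qa` subcommands).

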