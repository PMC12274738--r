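# spiralscan

Trajectory design and in-silico validation for compound double-spiral
resonant scanning in photoacoustic endoscopy, with dual-wavelength
hemoglobin unmixing and vessel morphometry — all testable against
synthetic phantoms with exact ground truth.

## The problem

Capsule-sized photoacoustic endoscopes scan a pulsed laser focus over a
circular field of view with a resonant MEMS mirror, mapping hemoglobin
(and hence microvasculature) inside body cavities.  Spirals driven at
constant angular velocity with uniform angular pulse spacing keep the
mirror in its smooth resonant regime, but they sample space unevenly:

* Archimedes spiral (AS), `r = a·θ`: the fraction of pulses inside
  radius ρ is `ρ/R` — an oversampled (and over-heated) centre, a
  starved edge;
* Fermat spiral (FS), `r = a·√θ`: the fraction is `(ρ/R)²` — areally
  uniform, but the centre is rarely visited by the track.

The compound Archimedes–Fermat pattern (A-FS) joins an AS outward pass
to an FS inward pass in one continuous frame.  Each pass carries half
the pulses, so inside a central disk of area fraction `f`:

```
P_AS(f) = √f      P_FS(f) = f      P_AFS(f) = (√f + f) / 2
```

which at `f = 1/256` gives 6.25%, 0.39% and 3.32% — the compound
pattern roughly halves the central pulse load of AS while its edge
coverage improves.  `spiralscan` generates these trajectories, measures
their sampling homogeneity and energy deposition, and runs the full
simulated imaging chain: per-pulse dual-wavelength acquisition of a
vascular phantom, scattered-sample reconstruction, landmark-based rigid
stitching, two-wavelength unmixing into oxygen saturation (sO₂) and
relative total hemoglobin (C_HbT), and a morphometry suite — total
vessel length (VL), number of branch points (NBP), mean vessel diameter
(MVD), tortuosity (VT = arc/chord) and box-counting fractal dimension
(FD = slope of log N(r) vs log 1/r).

Intended users: imaging-systems researchers choosing scan patterns and
pulse budgets, and analysts who need a ground-truthed test bed for
vessel-morphometry pipelines.

## Worked example

```r
library(spiralscan)

p <- SpiralParams("AFS")            # 2 mm FOV, 200 kHz, 6 Hz frame rate
p
#> SpiralParams: AFS | FOV 2 mm | 33332 pulses, 16 turns/pass | PRF 2e+05 Hz -> 6 Hz frame rate
#>   composition: as_out_fs_in, pass offset 0.1963 rad

tr <- makeTrajectory(p)
centralPulseFraction(tr, 1/256)     # % of pulses in the central 1/256-area disk
#> [1] 3.324133
centralPulseFraction(tr, 1/64)
#> [1] 7.035281
```

3.32% and 7.04% are the compound pattern's central pulse shares; the
same calls with `SpiralParams("AS")` give 6.25% and 12.50%, so the
compound frame delivers about half the central dose at an identical
pulse budget.

A phantom with known ground truth, imaged and measured:

```r
ph <- makePhantom("grid", size = 512, seed = 3)
ph
#> VascularPhantom 'grid': 512x512 px (0.003906 mm/px), 6 vessels, 12.1% vessel pixels, seed 3

mask <- segmentVessels(absorptionMap(ph, 532), "fixed",
                       threshold = 1e-9, fillHoles = FALSE)
computeMetrics(skeletonizeGraph(mask, pixelSize(ph)), mask)
#> MorphometryReport: VL 10.72 mm | NBP 9 | MVD 0.0455 mm | VT 1 | FD 1.476

str(truthMetrics(ph))
#> List of 4
#>  $ VL : num 10.8
#>  $ NBP: int 9
#>  $ MVD: num 0.0457
#>  $ VT : num 1
```

The measured network recovers the generator's truth: VL within 1%, the
9 grid crossings exactly, MVD within a tenth of a pixel, VT exactly 1
for straight vessels.  `runPipeline(defaultRunConfig(seed = 1))` chains
every stage (phantom → trajectory → acquire → reconstruct → unmix →
morphometry) into a run directory with a JSON summary, reproducible
byte for byte from the seed.  A command-line front end for the
individual stages lives at `inst/scripts/spiralscan.R`.

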