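# hcsquant

Quantitation of cell birth, death and morphology from high-content
screening (HCS) images.

## The problem

Bulk viability assays (MTS and kin) collapse a drug response into a
single "percent viability" number and cannot tell a **cytostatic**
response (cells stop dividing) from a **cytotoxic** one (cells die) —
two outcomes with very different consequences for tumor evolution and
dosing. Image-based screening can: segmenting nuclei in a nuclear-stain
channel and marking dead cells with a membrane-impermeant stain gives
live and dead counts per well per time point, and those counts support
a full decomposition of population growth into birth and death rates.
The same images yield single-cell morphology and, with fluorescent
labels or a trained classifier, per-subpopulation composition of
heterogeneous co-cultures — all across dozens of microenvironmental
conditions (drug, oxygen, glucose, co-culture) in parallel.

`hcsquant` implements that pipeline end to end, for R, with a
ground-truthed synthetic-data generator so every stage is testable
without any real microscopy data:

1. **Segmentation** — nuclei by Otsu threshold + distance-transform
   watershed de-clumping; whole cells by seeded propagation on a
   cytoplasm-tracker channel (`segmentNuclei`, `segmentCells`).
2. **Viability** — dead iff nuclear dead-stain mean strictly exceeds an
   absolute threshold, or iff the nuclear-to-background intensity ratio
   strictly exceeds 1.2, the background taken in an annulus ~30 px
   outside the nucleus (`callDead`, `countLiveDead`).
3. **Rates** — the core model. Live counts follow exponential growth,
   `N(t) = N0 e^{rt}`; `r` is the slope of the OLS fit of `ln N` on `t`
   (replicates pooled). With a constant per-capita death hazard `d`,
   expected cumulative deaths are `D(T) = d N0 (e^{rT} - 1)/r`, so

   `d = D(T) r / (N0 (e^{rT} - 1))`, with the limit `d = D(T)/(N0 T)`
   as `r -> 0`, and the birth rate is the identity **`b = r + d`**
   (`fitNetGrowthRate`, `estimateDeathRate`, `estimateRates`,
   `rateGrid`).
4. **Morphology** — per-cell area, nuclear area, roundness
   `4 pi A / P^2` (chain-code perimeter), width-to-length from the
   second-moment ellipse (`computeMorphology`).
5. **Classification** — fluorescence gating, and a least-squares
   multiclass linear discriminant on standardized, separability-selected
   features, trained on 100 cells per class
   (`trainLinearClassifier`, `applyClassifier`, `concordance`).
6. **Population** — composition tables per (time, condition,
   subpopulation, live/dead) and dissociated-spheroid count scaling
   (`buildComposition`, `spheroidCounts`).

A stochastic birth-death simulator (`simulateBirthDeath`, exact
event-driven) realizes exactly the model the rate fit assumes and
serves as the oracle for parameter-recovery tests.

## Worked example

Render a synthetic co-culture field, count live/dead, decompose rates
from simulated wells, and train the 4-class subpopulation classifier:

```r
library(hcsquant)

# a 512x512 two-population field: 75 cells, 20% rendered dead
out <- renderField(synthImageSpec(seed = 42))
seg <- segmentNuclei(out$field, segmentationParams())
countLiveDead(seg$records, callDead(seg$records, viabilityParams()))
#>           live           dead unclassifiable
#>             60             13              0

# triplicate wells simulated at b = 0.04/h, d = 0.01/h, N0 = 2000
reps <- lapply(1:3, function(k)
  simulateBirthDeath(birthDeathParams(b = 0.04, d = 0.01, N0 = 2000),
                     seed = 42 + k))
estimateRates(reps)
#> RateEstimate: r=0.03006 d=0.00978 b=0.03984 (1/h), N0=1998.8, R2=0.9997
#>   exponential_ok=TRUE

# 4-class classifier (2 labels x live/dead) on pure controls
pop <- synthControlPopulations(200, seed = 42)
set.seed(42)
idx <- unlist(lapply(split(seq_len(nrow(pop)), pop$true_class),
                     sample, 100))
m <- trainLinearClassifier(pop[idx, ], pop$true_class[idx], seed = 42,
                           featureCols = setdiff(names(pop), "true_class"))
evaluateOnControls(m, pop[-idx, ], pop$true_class[-idx])
#> ClassifierModel: 4 classes (stroma_dead, stroma_live, tumor_dead, tumor_live)
#>   features: dead_ratio, rfp_mean, gfp_mean, width_to_length, roundness
#>   training accuracy 0.955 | control accuracy 0.983
```

The live/dead counts come straight off the rendered field (73 of 75
nuclei segmented; the 13 dead calls match the generator's ground
truth). The rate decomposition recovers the simulating parameters to
the third decimal, and `b = r + d` holds exactly by construction. The
classifier's control accuracy is the fraction of held-out pure-control
cells assigned to their true class — the gate for accepting a trained
model is 90%.

A thin CLI over the same functions is in `inst/scripts/hcsq.R`
(subcommands `synth-images`, `simulate`, `rates`, `run`).

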