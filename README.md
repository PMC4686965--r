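# jet2r — protein–protein interface prediction from single structures

`jet2r` predicts protein–protein interaction sites on the surface of a
single protein, given only its 3D structure (PDB) and a per-residue
conservation score. It is aimed at structural biologists who need putative
binding patches for proteins whose partners are unknown — for docking
constraints, mutagenesis planning, or annotating surfaces of therapeutic
targets.

## The model

Each surface residue (relative accessibility ≥ 5%, internal Shrake–Rupley
SASA with a 1.4 Å probe) is described by three scaled descriptors:

- **T<sub>JET</sub>** — conservation. A raw per-residue trace value
  *d<sub>j</sub>* ∈ [0,1] (e.g. an averaged phylogenetic tree trace) is
  smoothed over the spatial neighborhood *I* (residues with a heavy atom
  < 5 Å):

  T<sub>JET</sub>(j) = (w<sub>I</sub> · mean<sub>h∈I</sub> d<sub>h</sub> + w<sub>j</sub> · d<sub>j</sub>) / (w<sub>I</sub> + w<sub>j</sub>),  with w<sub>I</sub> = 3, w<sub>j</sub> = 4.

- **PC** — amino-acid interface propensity, from a 20-value scale.
- **CV** — circular variance, CV(i) = 1 − ‖Σ<sub>j≠i, r<sub>ij</sub><r<sub>c</sub></sub> r̂<sub>ij</sub>‖ / n<sub>i</sub>,
  the density of protein around an atom (≈0 protruding, ≈1 buried);
  residue CV is the mean over its atoms, at r<sub>c</sub> = 12 Å (local) or
  100 Å (global).

All descriptors are min–max scaled over the surface residues of the query,
so predictions are protein-specific. Three scoring schemes combine them by
unweighted means: **SC1** (seed = T<sub>JET</sub>; extension =
mean(T<sub>JET</sub>, PC); outer = mean(PC, 1−CV)) for generic conserved
interfaces, **SC2** (mean(T<sub>JET</sub>, 1−CV) for seed and extension)
for interfaces bordering small-ligand pockets, **SC3** (mean(PC, 1−CV)
everywhere) when the evolutionary signal is too weak. A decision cascade
picks the scheme automatically from the conservation statistics of the
surface.

Patches grow in three steps: **seed** detection (top scorers at the
quantile thresholds derived from the expected interface fraction
f<sub>intfrac</sub>(N) = 26.54/N + 0.03), gradient-constrained
**extension** (new residues must score below the previous batch maximum;
growth stops when the cluster mean reaches the extension threshold), and a
one-pass **outer layer** of protruding residues that keeps the mean score
from dropping. A second round with a complementary scheme can add patches,
fused when < 5 Å from the first site. The stochastic consensus mode
(`ijet2()`) repeats the run and keeps residues predicted in ≥ 2 of 10 runs.

For evaluation, experimental interfaces from complexes are defined by
relative-accessibility change and decomposed into **support / core / rim**
(rasa<sub>u</sub>/rasa<sub>b</sub> at the 0.25 threshold), and predictions
are scored with sensitivity/specificity/PPV/accuracy against their
random-prediction expectations.

## Worked example

Everything runs on synthetic fixtures with planted ground truth — no
downloads needed:

```r
library(jet2r)

fx  <- fixture_preset("conserved-patch", seed = 42)  # globule + planted site
fit <- jet2(fx$structure, fx$conservation, mode = "auto", rounds = 2, seed = 42)
fit
#> Interface prediction ( 2 round(s), steps = full )
#> Main scheme: SC1 (complementary: SC3)
#> 1 patch(es), 62 residues predicted of 97 surface residues
summary(fit)
#> Decision trace:
#>                                     predicate     value  threshold result
#>           prop(T_JET > 0.6) < 0.3 * f_intfrac 0.1340206 0.09108247  FALSE
#>                               SC1 seeds found 1.0000000 1.00000000   TRUE
#>  all seeds: sd/mean < (1/6) * surface sd/mean 0.1862466 0.10070669  FALSE
#> Patches:
#> Patch [SC1+SC3, round 1]: 30 seed / 25 extension / 7 outer
```

The trace reads: the conserved fraction (13.4%) is above the weak-signal
bound, SC1 found a seed, and the seed is heterogeneous — so SC1 is kept.
Consensus recovery of the planted conserved site (the conservation-driven
seed + extension layers; the outer layer adds geometric rim residues the
plant does not contain):

```r
cons <- ijet2(fx$structure, fx$conservation, n_runs = 10, cutoff = 2,
              seed = 42, rounds = 1, steps = "seed+ext")
desc  <- residue_descriptors(fx$structure, fx$conservation)
surf  <- desc$id[desc$is_surface]
truth <- intersect(fx$labels$id[fx$labels$label == "patch"], surf)
score_prediction(intersect(cons$members, surf), truth, surf)
#> TP 23  FP 13  FN 2  TN 59  (N = 97 surface residues)
#> Sens 0.920 (exp 0.371)  PPV 0.639 (exp 0.258)
#> Spe  0.819 (exp 0.629)  Acc 0.845 (exp 0.562)
```

23 of the 25 planted surface residues are recovered, at more than twice the
precision expected for a random prediction of the same size.

A command-line front end is available at `inst/cli/jet2.R`
(`run`, `eval`, `fixture` subcommands).

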