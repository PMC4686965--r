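---
title: "Predicting protein-protein interfaces from single structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interfaces from single structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jet2r)
```

## The problem and the model

Most proteins act through physical contacts with other proteins, yet for
the majority of structures the binding partners — and therefore the
interface locations — are unknown. `jet2r` predicts interaction sites on
a *single* protein structure, with no machine learning and no knowledge of
the partner, by exploiting three observations about experimental
interfaces: their buried center (*support*) is more conserved than the
rest of the surface, their intermediate ring (*core*) has a distinctive
amino-acid composition, and their exposed border (*rim*) consists largely
of protruding residues.

The predicted counterpart mirrors that architecture: a **seed** of
high-scoring residues, a concentric **extension**, and an **outer layer**
of protruding residues. Each layer is scored by an unweighted arithmetic
mean of scaled descriptors:

| scheme | seed | extension | outer | intended use |
|---|---|---|---|---|
| SC1 | T~JET~ | mean(T~JET~, PC) | mean(PC, 1−CV) | generic conserved interfaces |
| SC2 | mean(T~JET~, 1−CV) | same as seed | mean(PC, 1−CV) | interfaces near small-ligand pockets |
| SC3 | mean(PC, 1−CV) | same | same | weak or absent evolutionary signal |

T~JET~ is the raw conservation d~j~ smoothed over the < 5 Å residue
neighborhood with weights 3 (environment) and 4 (self); PC is a per-amino-
acid interface propensity; CV is the circular variance of the atomic
environment, averaged per residue. All three are min–max scaled over the
*surface residues of the query protein* (relative accessibility ≥ 0.05),
which makes every prediction protein-specific: a "highly conserved" residue
is one conserved relative to this protein's own surface.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| neighbor cutoff | 5 | Å | single proximity notion: smoothing, seeds, extension, merging (strict `<`) |
| probe radius | 1.4 | Å | water probe for accessibility |
| surface threshold | 0.05 | rasa | residues below are ignored (buried, usually conserved for stability) |
| r~c~ local / global | 12 / 100 | Å | circular-variance resolution; 10–14 Å behave similarly, 100 Å captures whole-protein protrusion |
| w~I~ : w~j~ | 3 : 4 | — | environment-vs-self weighting of conservation smoothing |
| f~intfrac~(N) | 26.54/N + 0.03 | fraction | expected interface size for an N-residue surface; sets all quantile cuts |
| min seed size | 3 | residues | smaller seed components are discarded |
| consensus | 2 of 10 | runs | membership cutoff of the iterative mode |
| jitter amplitude | 0.01 | score | uniform seed-score perturbation feeding the consensus |

The clustering thresholds are *quantiles* of the surface score
distribution: residues are admitted above the score at confidence
2·f~intfrac~ (`score_res_cut`), seed accretion stops when the running mean
reaches the score at confidence f~intfrac~/4, and extension stops at
f~intfrac~/2. Quantiles use linear interpolation between order statistics,
which keeps thresholds deterministic and continuous in the scores.

## Algorithmic choices worth knowing

**Seed detection.** Surface residues are visited in descending score
order (ties broken by the seeded RNG); accretion continues while the
running mean stays above the seed threshold and each residue clears the
admission cut (strict inequalities throughout). The selected set is then
split into connected components of the 5 Å graph and components smaller
than three residues are dropped. The running-mean construction means that
on a score distribution with a broad high tail the seed reaches deep into
the tail, while a tight plateau of equal scores yields a small homogeneous
seed — exactly the contrast the scheme-selection cascade measures.

**Extension.** At each iteration, the neighbors of the cluster scoring
strictly between the admission cut and the *maximum of the previous
batch* are added, and the batch maximum is reset. This enforces a
monotonically decreasing score front, mirroring the conservation gradient
from support to rim; the loop also terminates when no admissible neighbor
remains even if the cluster mean is still high (the pseudocode would
otherwise spin).

**Outer layer.** One single pass; a neighbor enters iff its outer score
(propensity + protrusion) is at least the cluster's mean outer score,
computed once over the pre-pass members. Updating the mean inside the pass
would make the result order-dependent; freezing it keeps the operation a
well-defined set filter.

**Scheme auto-selection.** (1) If fewer than 0.3·f~intfrac~ of surface
residues have scaled T~JET~ > 0.6, conservation cannot drive a prediction →
SC3. (2) Otherwise SC1 seeds are sought; none → SC3. (3) If every seed's
dispersion-to-mean score ratio is below one sixth of the surface-wide
ratio, the seed looks like an ultra-conserved ligand pocket → SC2.
(4) Otherwise SC1. Dispersion is the population standard deviation; the
trace of every evaluated predicate is stored in the fitted object
(`decision_trace`). If SC2's own seed detection comes up empty the run
keeps the empty first-round result and relies on the complementary SC3
round rather than falling back again — the cascade is evaluated once.

**Second round and fusion.** The complementary scheme (SC3 after SC1/SC2,
SC2 after SC3) runs the full three steps; its patches are fused into
first-round patches when closer than 5 Å and otherwise kept as separate
candidate sites (a protein may genuinely have several partners). When SC3
is the main scheme its scores use the global CV (r~c~ = 100 Å); as a
complementary scheme it uses the local CV, reading the main/complementary
distinction literally.

**Stochasticity.** Run-to-run variability in the original workflow comes
from heuristics upstream of this package (trace computation, seed
filtering). Since raw conservation is an *input* here, the consensus
mechanism is reproduced by a controlled uniform jitter (amplitude 0.01)
applied to seed scores, plus RNG tie-breaking; both derive from the run
seed, and consensus runs use seeds `base_seed + 0, 1, …`, so any consensus
is exactly reproducible.

**Degenerate inputs.** An atom with no neighbor inside r~c~ gets CV = 0
(zero surrounding density is the protrusion limit). A constant descriptor
vector scales to 0.5 (uninformative, avoids 0/0). Residues with an empty
smoothing neighborhood keep their raw conservation. Evaluation ratios with
zero denominators are reported as NA, never silently zero.

## The synthetic study system

The package ships a generator (`synthetic_globule()`, presets in
`fixture_preset()`) rather than depending on curated complex sets. A
fixture is a compact globule of alanine-like five-atom pseudo-residues on
concentric shells ~4 Å apart (150 residues by default, giving a ~95-residue
surface), with known planted features:

- a **conserved surface patch** of 25 residues — about the expected
  interface size f~intfrac~(N)·N for this surface — whose conservation
  decays from the patch center outward (`gradient` profile, contrast 0.5
  over a 0.3 background with truncated-normal noise σ = 0.1). The radial
  decay reproduces the support→rim conservation gradient of real
  interfaces and is what makes the planted seed *heterogeneous*;
- a **homogeneous pocket** (`constant` profile, the `ligand-pocket`
  preset) with a four-atom hetero group seated above it — the SC2 trigger;
- a **flat** preset with constant conservation — the SC3 trigger;
- a **protruding loop** marching radially outward — the lowest-CV residues
  in the structure, for testing the geometric descriptor;
- a two-chain **synthetic complex**: two globules interpenetrating by 4 Å
  along the contact axis, producing a contact disc whose residues lose
  accessibility upon "binding" and decompose into support/core/rim.

What the fixtures deliberately do *not* emulate: real backbone geometry
and side-chain packing, heterogeneous residue sizes, the spatial
correlation structure of real conservation, or rim regions that belong to
the true site. Consequently, passing tests demonstrate the correctness of
the descriptors, thresholds and clustering algorithm and the recovery of a
planted conservation signal — they do not certify benchmark-level accuracy
on real complexes, which depends on the quality of real conservation
traces. For the same reason, planted-patch *recovery* is assessed on the
conservation-driven layers (`steps = "seed+ext"`): the outer layer by
design adds protruding rim-like residues, and the conservation-only plant
contains none, so including it would measure the plant's construction
rather than the predictor.

Problem sizes used by the test-suite and the acceptance script — 150-residue
fixtures, 10-run consensus, 10–20 fixtures per estimate, 1000-draw
Monte-Carlo baselines — were chosen as the smallest sizes at which the
checked quantities are stable to well within the asserted margins.

## Known limitations

- The propensity scale shipped is a constructed stand-in spanning the
  published 0–2.21 range with the literature's ordering; users with a
  preferred published scale should supply it via `jet_propensities(path=)`.
- Conservation must be provided externally (any score in [0,1]); the
  phylogenetic tree-trace machinery that usually produces it is out of
  scope, and results inherit its quality.
- mmCIF files, biological-assembly generation and residue renumbering are
  not handled; only the first model of multi-model files is used by
  default, and altlocs resolve to the highest-occupancy conformer.
- The support/core/rim decomposition uses whole-residue accessibilities;
  side-chain-only variants would shift the 0.25 boundary cases.
- Distance-based steps are exact (no spatial indexing); structures of a
  few thousand atoms are the intended scale.

## A minimal run

```{r example, eval = FALSE}
fx  <- fixture_preset("conserved-patch", seed = 1)
fit <- jet2(fx$structure, fx$conservation, mode = "auto", rounds = 2, seed = 1)
summary(fit)
cons <- ijet2(fx$structure, fx$conservation, n_runs = 10, cutoff = 2, seed = 1)
cons
```
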