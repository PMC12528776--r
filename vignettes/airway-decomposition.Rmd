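---
title: "Distance-map airway-branch decomposition: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-map airway-branch decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtree)
```

## The problem

Traction bronchiectasis — airways held open and dilated by surrounding
fibrosis — is a strong mortality signal in fibrotic lung disease, but a
voxel-wise airway segmentation by itself says nothing about *which part* of
the tree is dilated. The clinically interesting signal sits distally: small
and terminal branches that should be invisible at CT resolution become
visible and voluminous when fibrosis tethers them open. `airtree` turns a
binary airway mask plus a lung mask into per-class branch volumes without
any intensity information, using only the geometry of the segmented tree.

## The model

The decomposition assumes an anatomically oriented volume (we normalise all
NIfTI input onto a fixed convention: axis 1 superior→inferior, axis 2
anterior→posterior, axis 3 patient-right→patient-left; a voxel is a point
sample at its centre) and proceeds:

1. **Trachea/carina.** Largest 26-connected component, scanned from the top
   slice. The carina slice is the first whose in-plane cross-section has
   ≥ 2 connected components *persistently* (default 3 consecutive slices).
   The carina point is the centroid of the last single cross-section.
2. **Transverse projection** `P_Z` of the airway-minus-trachea (binary max
   projection along z), partitioned into left and right lungs.
3. **Normalised distance maps.** Per lung, an adjusted central point = the
   centroid of that lung's airway pixels in `P_Z`; each pixel's in-plane
   Euclidean distance to its centre is divided by the per-lung maximum, so
   `D ∈ [0, 1]` with `max D = 1` in each lung.
4. **Percentile thresholds** 0.55 and 0.25 split pixels into terminal
   (`D ≥ 0.55`), small (`0.25 ≤ D < 0.55`) and medium (`D < 0.25`).
   Boundaries are closed on the left: a pixel exactly at a cut goes to the
   more distal class. This convention is arbitrary but fixed and tested.
5. **Back-projection**: every non-trachea airway voxel inherits its axial
   column's class; trachea voxels are labelled trachea.
6. **Vertical revision.** The tree height is the maximal depth of any
   non-trachea airway voxel below the carina; `H(v) ∈ [0, 1]` is a voxel's
   clamped depth fraction. In `vertical-max` mode the final class applies
   the same cuts to `S = max(D, H)`, and can only *promote* a voxel toward
   a more distal class.

The geometric intuition: in the axial projection, proximal (medium) airways
cluster around the hilum near each lung's centre, while distal branches fan
out toward the periphery; the vertical term catches distal branches that
project near the centre (e.g. basal segments running straight down).

Biomarkers are class volumes normalised to total lung volume, in percent:
`STermAV`, `SSmallAV`, `SMedAV`, their sum `STotalAV` (trachea excluded by
construction), and `SPAV = STermAV + SSmallAV` — the "primary airway
volume" combination motivated by the strong collinearity of the small and
terminal signals. For survival models, one covariate unit is a 0.1
percentage-point increment (`to_model_units()`).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `t_terminal`, `t_small` | 0.55, 0.25 | fraction of max distance | the published percentile cuts |
| `carina_persistence` | 3 | slices | skips single-slice loop artifacts; the source method states no rule |
| `threshold_mode` | `normalised` | — | "percentage distance map" read as max-normalised distance; `rank` applies the cuts to the within-lung empirical quantile rank instead, provided because the phrase is ambiguous |
| `revision` | `vertical-max` | — | stand-in for the frontal-plane revision step (below) |
| `min_trachea_area_mm2` | 4 | mm² | rejects masks whose top slice is too thin to be a trachea |

## Interpretation choices on genuinely open points

* **The frontal-plane revision step.** The source description defers the
  revision criteria to supplementary pseudo-code that is not available
  here. We implement the documented stand-in: promotion-only revision by
  the vertical depth fraction, behind the `revision` switch (`off` gives
  the pure 2D classification). Anyone holding the original pseudo-code can
  replace `revise_labels()` without touching the rest of the pipeline.
* **"Central point".** Per-lung adjusted centroids of the projected airway
  pixels (not the carina) drive the distance maps, matching the adjusted
  central points shown in the method's schematic.
* **Trachea exclusion.** `STotalAV` excludes the trachea; tree height is
  likewise estimated without it.
* **Debris and clutter.** Trachea/carina localisation, centres, distance
  normalisation and tree height are estimated from the largest 26-connected
  component only; disconnected voxels are still classified (distances
  clamped to 1), so segmentation debris perturbs volumes but cannot move
  the carina or re-normalise the maps.
* **Boundary pixels between lungs** take the side of the majority of their
  column's voxels, falling back to the carina's sagittal plane.

## The phantom: what it emulates and what it does not

`generate_tree()` builds a dichotomous tree of tapering capsules
(generation 0 = trachea): lengths shrink by `length_ratio` (default 0.78)
and radii by `radius_ratio` (default 0.75) per generation — Weibel-like
tapering at desk scale (default 128³ voxels at 1 mm, 30 mm trachea of
radius 5 mm, 35° branching half-angle, branching plane alternating 90° per
generation). Radii that taper below one voxel are clamped with a warning.
`generate_lung_mask()` wraps two lateral ellipsoids around the bronchial
tree with a guaranteed clearance margin; `add_honeycomb_clutter()` drops
small spheres into the *costal subpleural* band (within `rind_mm` of the
projected lateral pleural surface), disconnected from the airway — the
clinical distribution of honeycombing; an earlier draft used the full 3D
rind, which unrealistically placed cysts at the apical pole directly over
the tracheal axis.

A green phantom test therefore establishes that the geometry pipeline is
self-consistent (partition, symmetry, scale behaviour, oracle equivalence,
distal enrichment) — not that the biomarkers carry clinical signal. The
phantom has no intensity model, no segmentation noise along the airway
wall, no cartilage/mucus artifacts, no anatomic asymmetry between lungs,
and its "honeycombing" is disconnected clutter, whereas real honeycombing
often touches the segmented airway tree and breaks it.

## Morphometry

The comparison metrics mirror graph-based airway tools: topology-preserving
3D thinning (26,6 simple points, endpoints kept) → junction/endpoint nodes
→ branches → generations by edge depth from the tracheal root. Branch
classes use generation percentages (`100·gen / deepest descendant leaf
generation`; ≥ 70 terminal, ≥ 40 small), normalised per root-to-leaf path
so shallow side subtrees remain classifiable. Tortuosity is smoothed arc
length over chord. Direction vectors use 5 centerline samples taken *after
skipping 3 points adjacent to a node*: the skeleton of two merging tubes
stays fused for about one tube radius past the geometric junction, and
measuring from the node itself inflates a true 70° sibling angle to ~82°
on a thin-tube Y phantom (73° with the skip). Leaf twigs shorter than
`prune_mm` (default 3 mm) are pruned and pass-through chains merged — the
standard cleanup for thinning artifacts. "Change in angle" is reported as
the angle to the parent branch direction and flagged as such: the
distinction drawn by the reference tool is not defined in the available
description.

## Survival layer

Cox models maximise the partial likelihood with Efron tie handling
(`survival::coxph`; `ties = "breslow"` is exposed because exact invariance
under record duplication — a useful sanity property — holds only under
Breslow). Kaplan–Meier estimates carry Greenwood errors; tertile risk
strata (ties at a boundary go to the lower group) feed log-rank tests and
low-reference hazard ratios. Harrell's C counts usable pairs (shorter
observed time has the event) with half-credit score ties. The
time-dependent AUC is the cumulative-cases / dynamic-controls estimator
with inverse-probability-of-censoring weights from the Kaplan–Meier of the
censoring distribution (left limits for case weights). Progression at 12
months defaults to *relative* declines (FVC ≥ 10 % of baseline or DLCO
≥ 15 % of baseline), the IPF-trial convention; an absolute-points mode is
provided because the defining sentence is ambiguous, and missing DLCO
falls back to FVC alone with a flag. The simulator draws exponential event
times under a proportional-hazards model with uniform administrative
censoring; defaults (baseline rate 0.3, window 10 years) give ~30 %
censoring in the parameter-recovery experiment.

## Numerical notes and limitations

* Distances, centroids and heights are exact double arithmetic; the only
  tolerances in the pipeline are the 1e-9 capsule-rasterisation tie-break
  (ties go to the higher generation) and the float32 precision of NIfTI
  header spacings.
* Mirror symmetry of per-class counts is exact on symmetric phantoms
  because all side rules mirror; a voxel exactly on the carina's sagittal
  plane deterministically goes left.
* The carina rule assumes the superior-most airway structure is a single
  trachea; masks already split at the top slice are rejected.
* Thinning is sequential within directional sub-iterations, hence
  deterministic but mildly anisotropic; branch lengths are measured on
  smoothed polylines and overestimate true length by a small voxelisation
  term (quarter-circle tortuosity is reproduced within 0.05).
* No lobe-level parcellation, no DICOM input, no segmentation from
  intensities; the published registry hazard ratios and AUCs are not
  reproducible here because the patient data are not distributable — the
  test suite checks properties, not those numbers.
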