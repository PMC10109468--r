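---
title: "From tiled SEM montages to a palynomorph census: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tiled SEM montages to a palynomorph census: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palycensus)
```

## The problem

Some fossil deposits preserve pollen and spores that cannot be extracted
chemically: when the fossils and the surrounding matrix are compositionally
identical (for example, both iron-oxyhydroxide), acid digestion destroys
everything or nothing. The only way to survey such rocks for microfossils is
*in situ*: image the split rock surface at high resolution and find the
specimens on the images. At ~20 nm per pixel a square centimetre of rock is
tens of thousands of SEM frames — far beyond what one palynologist can
screen — so the screening is crowdsourced: each frame is shown to several
online volunteers who answer a fixed five-question template (image focus,
microfossil occurrence, count, position in the frame, type), a consensus
rule converts their answers into a per-image verdict, and only the small
subset of images the crowd could not clear goes to an expert. The expert's
verified detections, deduplicated across overlapping tiles, form the census:
per-taxon counts, relative abundance, and specimens per cm².

`palycensus` implements this pipeline as testable components plus a
synthetic specimen-field and volunteer simulator, so every stage — and the
pipeline end to end — can be validated against a known ground truth.

## Montage geometry

A montage is an `n_cols x n_rows` grid of tiles. The microscope's stated
quantities are the tile's pixel dimensions, its horizontal field of view
(FOV), the overlap fraction between neighbouring tiles, and the per-image
dwell time. Everything else is derived:

* pixel pitch = FOV / horizontal pixels (square pixels assumed);
* tile height = vertical pixels x pitch. The tile height is not usually
  stated by acquisition software; deriving it from the pixel aspect ratio is
  what reproduces the survey's reported 4.2 mm montage height and ~20 nm
  pitch;
* montage extent per axis = tile extent x (1 + (n − 1) x (1 − overlap));
* tile origins sit on a lattice with step = tile extent x (1 − overlap),
  which defines the local/global coordinate transforms and the
  `tiles_covering()` query used for overlap accounting.

Coordinates follow raster convention: origin at the top-left tile's top-left
corner, x rightward, y downward, micrometres, 0-based tile indices, closed
tile intervals (a point on a shared boundary belongs to both tiles).

**Reported-value rounding.** Published survey summaries round extents to
0.1 mm and then report the area of the *rounded* extents: 6.315 x 4.204 mm
becomes 6.3 x 4.2 mm = 0.2646 cm², printed as 0.265 cm², and seven such
montages sum to 1.852 → 1.85 cm². Fully unrounded arithmetic gives
1.858 → 1.86 cm², which does not match the published total; the package
therefore reports both conventions (`area_cm2` vs `area_cm2_exact`) and uses
the rounded convention only for reported summaries. All internal computation
(specimen placement, densities in the simulator) uses exact extents.

```{r geometry}
g <- tile_grid(60, 60, 6144, 4090, fov_width_um = 120,
               overlap_frac = 0.125, dwell_s_per_image = 8)
g
dataset_totals(rep(list(g), 7))[c("n_images", "total_area_cm2",
                                  "acquisition_hours_total")]
```

## The consensus decision tree

Each image is served sequentially to distinct volunteers, up to `max_views`
(default 4). The image **closes** at the first moment `quorum` (default 3)
responses are *pairwise identical on all five answer fields*; the verdict is
`AGREEMENT_FOSSIL` or `AGREEMENT_NO_FOSSIL` according to the agreeing
occurrence answer. If all `max_views` responses arrive with no
quorum-identical subset, the verdict is `NO_AGREEMENT`. An image validated
as fossil-free is flagged **disputed** when a dissenting fossil report
arrived before closure; disputed images keep their no-fossil label but join
the expert queue. The review queue is exactly the union of fossil
agreements, disputed images and no-agreements — an identity
(`n_review_queue = n_agreement_fossil + n_disputed + n_no_agreement`) that
holds structurally for any input and is asserted by `flow_report()`.

Two genuinely open design points, and the choices made:

* **What counts as "the same response"?** All five questionnaire fields must
  match exactly. The alternative — matching on occurrence only — is
  available via `match_fields = "occurrence"`, but full-field matching is
  the default because observed disagreement decompositions span every field
  (count, occurrence, position, name, focus), implying all fields
  participated in validation.
* **Dispute detection and order.** Under the serving model a fossil report
  cannot arrive after closure, so order-aware and order-free dispute
  flagging coincide on streams the simulator produces; both modes exist
  (`order_aware`, default `TRUE`) for replaying truncated or re-sorted
  exports.
* **Truncated streams.** A stream that has not closed and has not reached
  `max_views` is `PENDING` — a first-class verdict so the engine can run on
  partial expeditions — even when it already holds `quorum` non-identical
  responses. `build_review_queue()` refuses pending verdicts.

Counts are compared as exact integers; the drop-down's top category is
binned (`count_max`, default 10, and `"10+"` on ingestion).

The implementation closes images with a vectorised key-matching scan;
its contract is pinned by an exhaustive comparison (every response sequence
of length ≤ 4 over a reduced answer alphabet) against a literal brute-force
replay of the serving process that enumerates all quorum-sized subsets.

## The synthetic cohort

The simulator generates the study conditions the pipeline is meant to face,
not a convenient toy:

* **Specimen field.** A homogeneous Poisson point process over each
  montage's exact extent at 207 specimens/cm² (the density implied by 383
  unique specimens over 1.85 cm²), with taxa drawn from a mixture mirroring
  the observed relative abundances (44% southern-beech pollen, 20% fungal
  spores, 9% fern/moss spores among identifiable specimens; 83/383
  indeterminable). Clustered placement is deliberately not the default: the
  published data give only densities, and a homogeneous process is the
  assumption-minimal choice. Radii are log-normal with median 12 µm
  (pollen-grain scale); they are carried but not used by the detection
  model, which keys on specimen centres.
* **Overlap duplication.** Each specimen is annotated in every tile whose
  closed footprint contains its centre. A per-tile detection is classed
  `edge` when the centre lies in the tile's overlap band (width =
  overlap fraction x tile extent on each side that has a neighbour),
  `middle` otherwise; an image whose detections mix both classes answers the
  position question `middle_and_edge`. The published workflow never defines
  "edge"; the overlap band is the natural reading because it is exactly
  where duplication occurs.
* **Volunteers.** 271 profiles. Activity weights are Pareto with shape
  1.076, chosen in closed form so the top decile of volunteers performs
  ~85% of transcriptions, matching the observed engagement skew. Error
  rates were calibrated *analytically* against the observed flow
  accounting before any simulation was run: with
  a = P(in-focus, no-fossil answer), f the false-positive rate and b the
  out-of-focus error mass, an empty image is disputed with probability
  ≈ 3a³f and unresolved with probability ≈ 1 − a³ − 3a³(b + f). Solving
  for the observed disputed (~9.8% of images) and empty no-agreement
  (~5.3%) proportions gives `false_positive_rate = 0.042` and
  `focus_error_rate = 0.07`; `sensitivity = 0.9`,
  `count_error_rate = 0.3` and naming accuracy 0.65 (with 0.20 mass on
  "unknown") reproduce the observed fate of fossil-bearing images, most of
  which surface through disputes or no-agreement rather than clean fossil
  agreement. With these defaults a simulated 25,200-image survey routes
  ~16.8% of images to the expert queue against the observed 16.6%.
* **Serving.** Responses are independent of serving state, so the simulator
  pre-generates up to `max_views` candidate responses per image and
  truncates at the consensus closure point — distributionally identical to
  literal sequential serving, and orders of magnitude faster in R. Skips
  (optional, default off) produce no response and never count toward the
  quorum. How a real platform could accumulate fourth views on undisputed
  images is not modelled: the serving policy here is exactly
  stop-at-closure, with `max_views` exposed as configuration.

What the simulator does **not** emulate: image content (focus quality is a
coin flip, not a property of the frame), volunteer learning over time,
spatially clustered specimen beds, and correlated errors between volunteers
viewing the same hard specimen. Passing tests therefore demonstrate the
*bookkeeping* of the pipeline — geometry, consensus logic, queue routing,
deduplication, census arithmetic — under realistic load and error rates, not
the visual difficulty of real micrographs.

## Expert review and the census

`expert_verify()` reviews any image subset against the ground-truth store:
each true specimen footprint is found with probability `1 − miss_rate`, and
each detection is escalated to the palynologist with probability
`escalation_rate` (the detection keeps its true label — escalation models
who resolved it, not information loss). The same call is the audit mode used
to estimate what the whole pipeline overlooked
(`estimate_overlooked()` scales audit misses linearly with a binomial
standard error; 7 misses in a 1000-image audit extrapolate to 176.4 ± 66
over 25,200 images).

Deduplication maps detections to global coordinates and applies
single-linkage clustering with tolerance `epsilon_um` (default 10 µm, the
order of a pollen-grain radius; the published workflow merged overlap
duplicates by eye and states no tolerance). Single linkage is the right
primitive here because duplicate detections of one specimen are *chains* of
near-coincident points across tiles. It is computed with
`stats::hclust(method = "single")` cut at height `epsilon_um`, and checked in
the test suite against an independent all-pairs union-find oracle. With
`epsilon_um = 0` only exactly coincident detections merge. Cluster labels
are majority votes, ties to `indeterminable`. Numerical note: coordinates
re-mapped through the tile lattice agree to ~1e-13 µm, far below any
sensible tolerance, so boundary effects do not arise at the default.

`census_table()` reports counts, percentages (base: identifiable specimens;
a percent-of-all-specimens column is kept alongside, because published
percentages and densities can imply slightly different bases) and densities,
exactly reconcilable before rounding (`density_exact * area = count`).

## Problem sizes and reproducibility

All randomness flows from one master seed: `run_pipeline()` derives
per-stage substream seeds from it, records it in every JSON report header,
and writes byte-identical outputs on repeated runs. The test suite exercises
full 3600-image montages (single-seed runs take under a second) and uses
10-seed batteries on 900–3600-image montages for the calibration and recall
properties; the acceptance script simulates the full seven-montage,
25,200-image survey in a few seconds. The end-to-end identity — perfect
volunteers and a perfect expert recover the generated field *exactly*
(counts, taxa, densities) — is the pipeline's strongest invariant and is
asserted at multiple scales.

## Known limitations

* Taxa are opaque labels throughout; no morphology, imagery, or taxonomic
  knowledge is modelled, and nothing here supports biostratigraphic
  interpretation by itself.
* The volunteer error model is stationary and independent across views;
  real crowds improve with training and fail in correlated ways on hard
  images, so real review queues may be larger than the calibrated
  simulation suggests.
* The ingestion adapter for platform exports is a best-guess column/value
  mapping (`digivol_schema()`); real exports should ship their own
  `transcription_schema()` mapping file rather than rely on it.
* Reported-area rounding conventions are inferred from the published
  figures they reproduce, not from a stated protocol.
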