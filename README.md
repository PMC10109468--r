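# palycensus

Citizen-science consensus and census for in-situ microfossil imaging.

## The problem

Some fossil sites preserve pollen and spores inside rock that is chemically
identical to the fossils themselves (e.g. goethite-hosted deposits), so the
classical acid-extraction protocols of palynology are useless. The
alternative is to survey the split rock surface *in situ*: acquire the
surface as tiled, partially overlapping SEM montages (thousands of frames
per cm² at ~20 nm/pixel), have online volunteers screen every frame through
a five-question template (focus, microfossil occurrence, count, position,
type), validate images by volunteer consensus, send only the unresolved
residue to an expert, and turn the expert-verified detections into a
palynomorph census. `palycensus` is for the people running and evaluating
such surveys: it models the acquisition geometry and its time budget,
implements the consensus decision tree and expert-review queueing, computes
the overlap-aware census, and ships a synthetic specimen-field and volunteer
simulator so the whole pipeline can be validated end to end against known
ground truth.

## The method in brief

**Geometry.** A montage of `n x m` tiles with overlap fraction `v` has
extent per axis `t (1 + (n − 1)(1 − v))` for tile extent `t`; tile height
derives from the horizontal field of view and the pixel aspect ratio
(square pixels). Tile origins form a lattice with step `t (1 − v)`, which
yields local/global transforms and the set of tiles covering any point —
one in a tile core, two in an overlap strip, four at a corner.

**Consensus.** Each image is served to up to 4 distinct volunteers; it
closes as soon as 3 responses are identical on all five questionnaire
fields (`AGREEMENT_FOSSIL` / `AGREEMENT_NO_FOSSIL`), else `NO_AGREEMENT`. A
no-fossil validation preceded by a dissenting fossil report is *disputed*.
The expert-review queue is the union of fossil agreements, disputed images
and no-agreements:

    n_review_queue = n_agreement_fossil + n_disputed + n_no_agreement

**Census.** Expert detections are mapped to montage-global coordinates and
merged by single-linkage clustering within a tolerance ε (default 10 µm),
collapsing the duplicates created by tile overlap; per-taxon counts `c_k`
over imaged area `A` give densities `c_k / A` (specimens/cm²) and relative
abundances `c_k / n_identifiable`. Audit misses extrapolate linearly with a
binomial standard error.

## Worked example

Simulate the full survey layout — seven 60 x 60 montages of
6144 x 4090-pixel tiles (120 µm field of view, 12.5% overlap, 8 s dwell),
271 volunteers with the calibrated default error model, 207 specimens/cm² —
then aggregate, review and census it:

```r
library(palycensus)

grid <- tile_grid(60, 60, 6144, 4090, fov_width_um = 120,
                  overlap_frac = 0.125, dwell_s_per_image = 8)
grid
#> <tile_grid> 60 x 60 tiles (3600 images)
#>   tile: 6144 x 4090 px, 120 x 79.8828 um, pixel pitch 19.53 nm
#>   overlap: 0.125 per axis; dwell: 8 s/image
#>   montage: 6.3 x 4.2 mm (reported area 0.265 cm^2)

res <- run_pipeline(pipeline_config(n_montages = 7, master_seed = 1))
res$flow
#> <flow_report> 25200 closed images (0 pending)
#>   agreement: 23358
#>     no fossil: 23186 (disputed: 2209)
#>     fossil:    172 (pollen/spore: 117, unknown: 55)
#>   no agreement: 1842
#>   expert-review queue: 4223
res$census
#> <census_table> 414 unique specimens (330 identifiable, 84 indeterminable) over 1.858 cm^2
#>                    taxon count percent density_per_cm2
#>           Nothofagidites   129      39            69.4
#>             fungal_spore    75      23            40.4
#>  other_angiosperm_pollen    28       8            15.1
#>          fern_moss_spore    27       8            14.5
#>           saccate_pollen    27       8            14.5
#>         triporate_pollen    16       5             8.6
#>         myrtaceae_pollen    15       5             8.1
#>     araucariaceae_pollen    13       4             7.0
res$performance$recall
#> [1] 1
workload_hours(length(res$queue), 5)$hours
#> [1] 5.865278
```

Reading the output: the volunteer stage cleared 23,186 of 25,200 images as
undisputed fossil-free, routing 4223 images (~17%) to the expert — about
5.9 hours of review at 5 s/image instead of 35 hours for the full dataset.
Deduplication across tile overlaps collapsed the expert's detections to 414
unique specimens, every planted specimen was recovered (recall 1.0), and
the census columns give each taxon's count, share of identifiable
specimens, and areal density over the exact imaged area (1.858 cm²).

Real platform exports go through the same machinery via a schema adapter:

```r
parsed <- read_transcriptions("expedition.csv", digivol_schema())
flow_report(consensus_verdicts(parsed$responses))
```

A thin command-line front end with subcommands
`simulate | aggregate | review | census | run` is installed at
`system.file("cli", "palycensus", package = "palycensus")`.

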