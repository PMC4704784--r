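# bbenrich

Quantification of Balbiani body (Bb) precursor enrichment around the
centrosome in 3-D confocal stacks of early zebrafish oocytes.

## What it measures, and for whom

The Bb is the earliest known marker of oocyte polarity. Before it
matures, its components — *dazl* mRNA, Buc protein, DiOC6-stained
organelles — aggregate around the centrosome: in the cytoplasm apposing
the telomere cluster of zygotene-bouquet oocytes, and inside the nuclear
cleft of pachytene–early diplotene oocytes. `bbenrich` is for
developmental and cell biologists who need to turn multi-channel z-stacks
(experimental stain + γ-tubulin + DAPI) and hand-drawn ROIs into
per-oocyte or per-nest enrichment statistics.

Two analyses are implemented:

* **Cleft analysis** (single oocyte, 17–25 µm): one centrosome seeds
  spheres of 4.8 µm (centrosome-adjacent = in-cleft cytoplasm) and 6.0 µm
  (outside = noncleft cytoplasm).
* **Zygotene nest analysis** (bulk): every detected centrosome in the
  nest ROI seeds spheres of 1.2 / 2.4 µm; the nest cytoplasm is measured
  without separating cells.

In both, nuclei are removed by dual thresholds (DAPI high, γ-tubulin
background low), centrosomes are 3-D connected components of ≥ 8 voxels
above a γ-tubulin threshold with a distance-transform center, and the
reported statistic is the background-normalized fold enrichment

```
fold = (mean_adjacent − mean_nuclear) / (mean_nonadjacent − mean_nuclear)
```

with the annulus between the two radii assigned to neither region.
Supporting modules provide TIFF/ROI I/O (ImageJ ROI archives and a JSON
dialect), Pearson/Manders colocalization with a PSF-block scramble test,
group t tests and frequency tables, recomputation of summaries from
per-unit supplementary spreadsheets, and a synthetic ovary generator with
ground truth that the whole pipeline is validated against.

## Worked example

```r
library(bbenrich)

# a synthetic cleft-stage oocyte with a known 2-fold enrichment
spec <- synthetic_spec("oocyte_cleft", enrichment_factor = 2,
                       voxel_size = c(0.53, 0.4, 0.4))
g <- generate_oocyte(spec, seed = 7)

res <- analyze_cleft(g$stack, g$rois$units[[1]],
                     synthetic_default_config("cleft"))
res
#> enrichment_result 'oocyte_1' [cleft]
#>   centrosomes: 1 | means nuc/adj/nonadj: 99.58 / 1268.70 / 708.15 | fold: 1.921
```

Reading the output: the nuclear mean (99.6 counts) is the background
reference; in-cleft cytoplasm averages 1268.7 counts and noncleft
cytoplasm 708.2, so the background-subtracted ratio is
(1268.7 − 99.6)/(708.2 − 99.6) ≈ 1.92 — a few percent under the
generative factor because the soft edge of the rendered aggregate leaks
past the outer sphere.

Real data run through the same functions via a JSON run configuration:

```r
run_analysis("config.json")   # writes results.csv + manifest.json
```

where the configuration names the stack TIFF, the ROI file (ImageJ zip or
JSON dialect), the three thresholds, and the output directory. A thin
command-line wrapper with `simulate` / `analyze` / `coloc` / `compare`
subcommands is installed at `inst/scripts/bbenrich.R`.

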