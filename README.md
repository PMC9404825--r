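# fibroquant

Automated morphometry of tubulointerstitial kidney fibrosis in
Masson's-trichrome-stained photomicrographs.

Animal studies of chronic kidney disease score renal damage by the fraction
of the tissue occupied by fibrotic (collagen-rich) extracellular matrix.
Manual or image-by-image measurement of hundreds of trichrome-stained fields
is slow and subjective; `fibroquant` runs the whole measurement as an
unattended batch. For each RGB photomicrograph it:

1. separates stains by Beer–Lambert optical-density colour deconvolution
   (OD = −log₁₀ I; a stain is a unit-norm absorbance vector **s**, and each
   pixel's OD vector is decomposed by least squares onto the stain basis);
2. detects hematoxylin-rich **tubules** (Gaussian smoothing, Otsu threshold
   with correction factor, connected components, equivalent-diameter filter
   d = 2√(area/π)) and masks them out, along with optional file-declared
   manual exclusion polygons and small bright normal-interstitium areas;
3. unmixes **Methyl Blue** (collagen) against **Ponceau-fuchsin**
   (counterstain) on the remaining pixels and thresholds the collagen
   signal;
4. reports, per image,
   **%fibrosis = (area occupied by fibrosis / total area) × 100**,
   exported as CSV with the spreadsheet column names
   `AreaOccupied_AreaOccupied_ThresholdFibrosis` and
   `AreaOccupied_TotalArea_ThresholdFibrosis`.

A synthetic trichrome generator (`generate_synthetic_kidney`) renders
tubules, counterstained interstitium and collagen patches of *known* area
fraction through the same Beer–Lambert forward model, so every stage — and
the package's accuracy claims — can be tested without any external images.

## Worked example

```r
library(fibroquant)

# a synthetic 256 x 192 trichrome field with a known 30% fibrotic fraction
g <- generate_synthetic_kidney(synthetic_spec(fibrosis_target_fraction = 0.30,
                                              seed = 301))
res <- run_pipeline(g$image, image_id = "demo")
res
#> <fibrosis result 'demo': 30.52% (threshold 0.200, 5 tubule(s) excluded)>
res$measurement
#> <area measurement: 15003 / 49152 pixels = 30.52%>
100 * g$truth$true_fraction   # generator ground truth
#> [1] 30.00081
```

The pipeline reads back 30.52% against a true fibrotic fraction of 30% —
the ~0.6-point overshoot comes from partial-rim pixels at tubule borders.
Batch use mirrors this over a directory:

```r
cfg <- pipeline_config(output_dir = "results")
run_batch(list.files("images", full.names = TRUE), cfg)
# -> results/fibrosis_results.csv, one row per image, failures flagged
```

From a shell, the same via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/fibroquant.R", package="fibroquant"))') \
    run --input images/ --output results/
```

Every `threshold_spec()` (method, correction factor, bounds) and
`object_filter()` (diameter range, connectivity) is configurable per stage,
in R or through a YAML config file (`read_pipeline_config()`); the threshold
correction factors are the first knobs to adjust for a new staining lot.

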