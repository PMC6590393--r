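# cytofractal

Quantitative description and unsupervised classification of flattened
invertebrate immune cells (hemocytes, coelomocytes) from one-bit
silhouette images. Adherent immune cells spread into irregular shapes
without clear structural landmarks; `cytofractal` types them by combining
classical particle morphometry with quasi-fractal descriptors of boundary
complexity, then screening, reducing and clustering the resulting
parameter table with a fully auditable statistical chain.

The pipeline, end to end:

1. **Morphometry** — per cell, 12 linear descriptors (area, perimeter,
   circularity `4πA/P²`, hull circularity, roundness `4A/(π·major²)`,
   aspect ratio, hull-centroid and bounding-circle max/min radius ratios,
   two mass-partition symmetry ratios, outline-evaluated roundness and
   area) and 9 quasi-fractal descriptors built on a multi-grid box scan
   (mass fractal dimensions `MMFD`/`outMMFD`, contour box dimension
   `outMeanD`, local and local-connected contour dimensions
   `outMeanLFD`/`outMeanLCFD`, lacunarity `LF`, across-grid count variance
   `Var in Count`, prefactor lacunarities `LCFD PreLac`/`outLCFD PreLac`).
2. **Screening** — z-normalisation; Sarle's bimodality coefficient
   `b = (g₁²+1)/(g₂ + 3(n−1)²/((n−2)(n−3)))` ranks parameters by
   classification value; a greedy `|r| < 0.7` correlation filter keeps
   one representative per redundant group.
3. **Factor analysis** — principal-axis factoring with raw Varimax
   rotation on the full table; factors retained at explained variance > 3
   with at least one `|loading| ≥ 0.70`; per factor, the max-bimodality
   loading parameter is chosen.
4. **Clustering** — Ward's minimum-variance method over k = 2..7 on three
   candidate feature sets (factor scores, top-bimodality parameters,
   factor-loading parameters); every solution evaluated by squared
   Mahalanobis distances, pairwise F
   (`F = (nᵢnⱼ/(nᵢ+nⱼ))·((n−k−p+1)/(p(n−k)))·D²`), Wilks'/partial lambda
   with F-remove, and Tukey–Kramer comparisons; the winner is the
   solution with the highest average pairwise F.

A seeded generator of synthetic cell silhouettes (elliptical body, tapered
radial processes, two-scale boundary noise, three planted morphotype
presets) plus analytic reference fractals (disk, square, supercover line,
Sierpinski gasket, Koch curve, Bernoulli field) make everything testable
without micrographs.

## Worked example

```r
library(cytofractal)

# one synthetic cell and its 21 descriptors
cell <- generate_cell(morphotype_presets()$branched, seed = 7)
cell
#> <binary_shape_image silhouette: 512 x 512 px, 9991 foreground, pixel_size=1>
round(compute_cell_features(cell, sample_stride = 2), 4)
#>      Area       Per      Circ HullsCirc     Round ...      MMFD   outMeanD
#> 9991.0000  611.2102    0.3361    0.6840    0.3835 ...   -1.8614     1.0618
```

`Circ = 0.34` and `MMFD = −1.86` say this silhouette is far from a disk
but still a nearly space-filling planar region; `outMeanD = 1.06` says its
contour is only mildly convoluted.

```r
# the full study on a simulated population: 3 morphotypes x 50 cells
cfg <- run_config(input = list(type = "simulation", n_per_type = 50,
                               seed = 6),
                  out_dir = "run6")
res <- run_pipeline(cfg)
res$comparison$factor_selection
#> <factor_selection: 4 factors retained>
#>   Factor1: Round       (loaders: HullsCirc, Round, MM_HullsCM, AR)
#>   Factor2: outMeanLFD  (loaders: outMMFD, outMeanLCFD, outMeanLFD, outMeanD)
#>   Factor3: Area_out    (loaders: Area, Per, Area_out)
#>   Factor4: LF          (loaders: MMFD, LF, Round_out)
head(res$comparison$report, 3)
#>                strategy k F_average D2_average
#> 1 factor_loading_params 3  237.9240   40.44989
#> 2 factor_loading_params 4  194.6660   52.81646
#> 3 factor_loading_params 5  177.3840   54.05480
```

The four rotated factors bundle the shape, contour-texture, size and
silhouette-complexity parameter families; clustering on the four
parameters that load them wins at k = 3 with average pairwise
F = 237.9 on df (4, 144) and average inter-cluster D² = 40.4. Against the
generator's planted labels this solution scores an adjusted Rand index of
0.842. `run6/summary.md` holds the per-type feature means, the Tukey–Kramer
inter-type table and the full strategy ranking.

The same analysis, written out step by step with intermediate tables under
`results/`, lives in the numbered drivers:

```sh
Rscript analysis/01_validate_estimators.R   # estimator calibration table
Rscript analysis/02_simulate_cells.R        # population PNGs + labels
Rscript analysis/03_measure_features.R      # 21-parameter feature table
Rscript analysis/04_select_parameters.R     # bimodality + correlation filter
Rscript analysis/05_classify.R              # factors, Ward, discriminants
```

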