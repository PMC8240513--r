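# groundcover

Canopy ground cover (GC) — the fraction of soil covered by foliage — is a
key measure of crop establishment and early vigour, and a selection trait
in wheat breeding. Ground-based phenotyping platforms estimate it
concurrently from sensors with very different physics, and the practical
question for breeders is *reliability*: which method ranks genotypes
consistently across times of day, light levels, and dew on the leaves?

`groundcover` implements the four standard plot-level estimators

| method | rule |
|---|---|
| `GC_RGB` | fraction of image pixels with greenness index *(G − R)/(G + R) > 0*, averaged over the plot's images |
| `GC_LIDAR_RR` | fraction of LiDAR returns with red-reflectance intensity < 5 (0–255 scale) |
| `GC_LIDAR_HT` | fraction of LiDAR returns > 10 cm above local ground (5th-percentile reference) |
| `NDVI` | mean of the active sensor's NDVI readings (range 0–0.99) assigned to the plot |

together with plot segmentation (0.5 m end buffers, outer sown rows
excluded: a 6 m plot leaves a 5 m × 1.25 m sampling region), the
reliability statistics used in plant breeding — per-event REML variance
components for `value = μ + genotype + row + col + ε`, repeatability
(broad-sense heritability) *ρ = σ²g / (σ²g + σ²ε / nrep)*, BLUP genotype
means, intraclass correlations between sampling times and phenotypic
correlations between methods with significance stars — and a synthetic
field-trial simulator (partial-replicate design, 192 plots / 99 genotypes
by default) whose sensor models encode the known failure modes: RGB
contrast collapses at low light, LiDAR reflectance separation degrades
under dew, active NDVI is invariant to both by construction.

## Worked example

Simulate the default diurnal experiment (13 hourly events: 12:00–18:00,
then 07:00–12:00 next morning with dew at 07:00/08:00) and inspect three
events — midday (1), dusk (7, the darkest sampling) and the dewy early
morning (8):

```r
library(groundcover)
report <- run_experiment(master_seed = 1, fit_methods = c("NDVI", "GC_RGB"))
dplyr::filter(report$event_summary, event_id %in% c(1, 7, 8))
#>    event_id method        mean      sd     n n_missing
#>  1        1 GC_LIDAR_HT 0.134  0.0953    192         0
#>  2        1 GC_LIDAR_RR 0.422  0.113     192         0
#>  3        1 GC_RGB      0.440  0.114     192         0
#>  4        1 NDVI        0.451  0.0810    192         0
#>  5        7 GC_LIDAR_HT 0.134  0.0968    192         0
#>  6        7 GC_LIDAR_RR 0.421  0.113     192         0
#>  7        7 GC_RGB      0.487  0.0249    192         0
#>  8        7 NDVI        0.452  0.0808    192         0
#>  9        8 GC_LIDAR_HT 0.135  0.0975    192         0
#> 10        8 GC_LIDAR_RR 0.0102 0.00386   192         0
#> 11        8 GC_RGB      0.508  0.0344    192         0
#> 12        8 NDVI        0.452  0.0808    192         0
```

At midday all methods agree (mean GC ≈ 0.42–0.45; the height method reads
lower because much of an early canopy sits below 10 cm). At dusk the RGB
estimate loses its between-plot spread (sd drops from 0.114 to 0.025 — the
greenness signal has sunk below the pixel noise), and under dew the
reflectance method collapses from 0.42 to 0.01 while NDVI does not move.
The same story in repeatability and between-time correlation:

```r
dplyr::filter(report$repeatability_table, event_id %in% c(1, 7, 8))
#>   event_id method sigma2_g sigma2_eps   rho
#> 1        1 NDVI   0.00334    0.00264  0.711
#> 2        7 NDVI   0.00331    0.00263  0.709
#> 3        8 NDVI   0.00332    0.00267  0.707
#> 4        1 GC_RGB 0.00652    0.00520  0.709
#> 5        7 GC_RGB 0          0.000571 0
#> 6        8 GC_RGB 0.000347   0.000794 0.458

round(sapply(report$icc, mean_off_diagonal), 3)
#>        NDVI      GC_RGB GC_LIDAR_RR GC_LIDAR_HT
#>       0.999       0.812       0.877       0.989
```

NDVI discriminates genotypes equally well at every hour (ρ ≈ 0.71
throughout, intraclass correlations ≈ 1), whereas RGB repeatability falls
to 0 at the darkest event. `run_experiment(..., out_dir = "out")` writes
every product (GC table, event summaries, variance components, genotype
means, correlation and star matrices) as CSV, byte-identical across runs
with the same master seed. A thin command-line wrapper is included at
`inst/scripts/gc_pipeline.R` (`simulate` / `estimate` / `stats` / `all`),
and `estimate_from_files()` accepts PNG images, CSV/PLY point clouds and
CSV NDVI streams for data produced outside the simulator.

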