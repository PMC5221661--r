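# neuromastsym

Quantitative bilateral symmetry of cranial neuromast point patterns.

Superficial neuromasts — the skin-surface mechanosensory organs of the fish
lateral line — form left/right patterns whose mirror agreement is a readout
of developmental precision (fluctuating asymmetry). This package turns a
formerly manual overlay protocol into a seeded, testable pipeline, for
researchers comparing facial neuromast patterning across populations (e.g.
surface vs cave morphs of *Astyanax mexicanus*):

1. digitize or detect neuromast centres (LoG spot detection on fluorescence
   images, or point tables);
2. mirror the right side, register it onto the left by a closed-form rigid
   Procrustes fit on canal-neuromast landmarks, refine by a trust-region
   local search that maximizes mask overlap;
3. rasterize both sides as dot masks on a shared blank canvas and score the
   Pearson colocalization coefficient over all pixels,

   R = (p_AB − p_A p_B) / sqrt(p_A (1 − p_A) p_B (1 − p_B)),

   for on-fractions p_A, p_B and joint fraction p_AB; identical masks give
   R = 1;
4. repeat the alignment in seeded technical triplicate and average: the
   per-individual symmetry index;
5. compare populations with a one-way ANOVA on the indices plus post hoc
   pooled Student's t-tests; measure ROI areas (mm²), neuromast counts and
   bone-fragment tallies per side.

A fully seeded synthetic-data module generates paired bilateral patterns
with controllable asymmetry, rendered spot images with noise, and cohorts
calibrated to target score moments — every pipeline stage is testable
against known ground truth.

## Worked example

```r
library(neuromastsym)

# a synthetic individual: 25 superficial + 6 canal neuromasts per side,
# right side jittered by 4 px relative to the mirrored template
pat <- generate_bilateral_pattern(params = asymmetry_params(sigma = 4, seed = 6))
res <- symmetry_index(pat$left, pat$right,
                      reg_cfg = registration_config(seed = 3))
print(res)
#> <symmetry_result mean R = 0.2035 over 3 trials (0.2044, 0.2013, 0.2047); n_left=25 n_right=25>
```

The three trials are independent jittered re-alignments; their spread
reflects alignment (not biological) variability. A perfect mirror scores
exactly 1:

```r
pat0 <- generate_bilateral_pattern(params = asymmetry_params(sigma = 0, seed = 5))
symmetry_index(pat0$left, pat0$right, reg_cfg = registration_config(seed = 3))$mean_r
#> [1] 1
```

Population comparison from summary statistics (four groups of 30; the
one-way F depends only on per-group mean/SD/n):

```r
tab <- data.frame(population = c("surface", "pachon", "tinaja", "chica"),
                  mean_r = c(0.082, 0.059, 0.054, 0.047),
                  sd = c(0.024, 0.014, 0.015, 0.012), n = rep(30L, 4))
anova_summary(tab)
#> One-way ANOVA: F(3, 116) = 24.154, p = 5.3e-12
```

Low mean R values (~0.05-0.1) do not mean "no symmetry": the statistic is
computed over every canvas pixel, so even visually similar dot fields share
only a modest pixel-wise overlap. Values are comparable within a fixed
configuration (canvas rule, dot radius 3 px) — see the methods vignette,
`vignettes/neuromast-symmetry-methods.Rmd`.

## Command line

```sh
Rscript -e 'neuromastsym::nsym_main()' simulate --seed 4 --sigma 3 --id fish01 --out data/
Rscript -e 'neuromastsym::nsym_main()' score --seed 4 --points data/fish01.csv \
    --frame data/frame.json --id fish01 --out results/
Rscript -e 'neuromastsym::nsym_main()' cohort --seed 11 --dir cohort_dir/ --out results/
```

Formats are plain text: CSV point tables (`individual_id,side,type,x,y`),
JSON ROIs/frames/results, TSV tables, ASCII PGM (P2) images. Every result
file embeds the seed and a hash of the governing configuration.

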