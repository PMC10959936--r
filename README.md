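# tlsquant

Quantification of tertiary lymphoid structures (TLSs) on H&E histology
slides, and the survival statistics applied to the resulting biomarker.

TLSs are organized aggregates of CD3+ T cells and CD20+ B cells that
form in tumours and resemble lymph-node follicles; their burden is
prognostic in many solid cancers. `tlsquant` computes the **TLS ratio**
of a slide,

```
TLS ratio = Σ |TLS ∩ tissue|  /  Σ |tissue|      (over retained 512×512 tiles)
```

averaged per subject over slides, via a three-branch tile pipeline:

1. **Tissue**: Otsu thresholding of tile luminance plus colour-rule
   pen-mark filters; a tile is retained only when its tissue area
   strictly exceeds 10% of the tile (26,214 px on a 512×512 tile).
2. **TLS segmentation**: a trainable pixelwise segmenter (multiscale
   stain/nucleus-density features + MLP decoder head, AdamW training
   with early stopping), or an oracle segmenter for validation; the
   probability map is binarized strictly above 0.5.
3. **Lymphocyte counting**: a pluggable nucleus detector; a tile's TLS
   area counts only when more than 80 lymphocytes fall inside it.

The package also includes ground-truth curation (the ≥50 CD3+/CD20+
cell rule, >40% tile curation, 7:1:2 splits), segmentation metrics
(Dice, IoU, pixel-level AUC with a 500-replicate tile bootstrap,
per-tile area correlation), a synthetic slide/cohort generator with
exact ground truth, and the downstream statistics: maximally selected
log-rank cutpoint, Kaplan–Meier/log-rank, Cox proportional hazards
(Efron ties, Wald CIs, Harrell's C), nested likelihood-ratio tests and
Wilcoxon responder comparisons.

See `vignettes/tls-ratio-pipeline.Rmd` for the model, every pinned
threshold, and what the synthetic generator does and does not emulate.

## Worked example

Generate a synthetic slide with known ground truth, quantify it with
the oracle branches, then fit the downstream survival model on a
simulated cohort whose hazard depends on the true ratio:

```r
library(tlsquant)

sl <- generate_slide(synth_slide_spec(seed = 7))
sl
#> <synth_slide> synth-7: 1024 x 1024 px @ 0.5 um/px, 3 TLS regions, 405 cells,
#>               true TLS ratio 0.1018

compute_slide_ratio(sl, oracle_segmenter(sl$tls_mask_true),
                    oracle_detector(sl$cells))
#> <ratio_result> synth-7: TLS ratio 0.0741 (46688 TLS px / 629932 tissue px;
#>                4/4 tiles retained)
```

The quantified ratio (0.0741) sits below the slide's raw true ratio
(0.1018) because one TLS region is split across tile borders and its
fragments fail the 80-lymphocyte filter — exactly the small-TLS
exclusion the filter is designed to perform.

```r
co  <- generate_cohort(synth_cohort_spec(n_subjects = 200,
                                         log_hazard_beta = -2, seed = 1))
cut <- optimal_cutpoint(co$clinical$true_ratio,
                        co$clinical$time_days, co$clinical$event)
cut$cutpoint                       #> 0.0986  (standardized log-rank 3.95)

co$clinical$group <- apply_cutpoint(co$clinical$true_ratio, cut$cutpoint)
cox_fit(co$clinical, c("group", "age", "sex", "tnm_stage"))
#> <cox_fit> n = 200 (117 events), C-index 0.606, loglik -490.18
#>                 coef     HR lower95 upper95
#> grouphigh    -0.8358 0.4335  0.2862  0.6568
#> age           0.0128 1.0128  0.9933  1.0328
#> sexM         -0.0609 0.9410  0.6367  1.3905
#> tnm_stageII   0.2117 1.2357  0.6942  2.1998
#> tnm_stageIII  0.5318 1.7020  0.9421  3.0746
#> tnm_stageIV   0.5314 1.7014  0.9188  3.1506
```

A high TLS ratio halves the hazard (HR 0.43, 95% CI 0.29–0.66) — the
protective effect the cohort generator simulated (β = −2 on the ratio).

A thin command-line wrapper for batch quantification of written slides
lives at `inst/cli/tlsquant.R`:

```sh
Rscript inst/cli/tlsquant.R quantify --slides slides/ --detector default \
    --out ratios.csv
```

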