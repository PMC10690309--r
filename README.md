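# octatten

Attenuation-coefficient analysis for distinguishing renal-cell-carcinoma
tissue from normal renal tissue in forward-viewing endoscopic OCT images.

## What problem this solves, and for whom

Percutaneous renal biopsy is guided by ultrasound/CT, which cannot identify
the tissue type directly ahead of the needle tip. A forward-viewing
endoscopic OCT probe can: tumor tissue is denser than normal renal tissue,
so its OCT signal decays faster with depth. This package is for researchers
working on OCT-based biopsy guidance who need a tested, reproducible
implementation of the attenuation-coefficient classification chain — and a
synthetic phantom generator so the whole chain can be exercised and
validated without instrument data.

## The model

Below the tissue surface the mean OCT intensity follows the Beer–Lambert
law

    I(z) = I0 · exp(−2µ (z − z_s)),       µ = −(1/2) · d log I / dz

with µ the attenuation coefficient (mm⁻¹). Per A-scan, µ is estimated by
ordinary least squares of log-intensity against physical depth over a
250-pixel window; per image, the computable A-scan estimates inside a
laterally centered 200 × 250 px region of interest are averaged. Under
fully developed speckle (exponential per-pixel intensity) the log signal is
shifted by a depth-independent constant, so the slope estimator stays
unbiased. Class-conditional normal distributions are then fitted to the
per-image µ values, the tumor-vs-normal decision threshold is placed at the
crossing point of the two fitted densities, and performance is evaluated by
ROC/AUC and one-vs-rest accuracy / precision / recall / F1 under
subject-rotating cross-testing (every kidney is the held-out test subject
exactly once). Signal-free pelvis images, where the logarithm is not
computable, abstain explicitly instead of producing a number.

## Worked example

Five simulated kidneys, 20 scans per tissue class, full pipeline:

```r
library(octatten)

ds     <- generate_phantom_dataset(n_subjects = 5, n_per_class = 20,
                                   seed = 424242, subject_jitter = 0.065,
                                   scan_jitter = 0.0375,
                                   width = 220, depth = 320)
mu_tab <- dataset_mu(ds)
fit    <- atten_classifier(mu ~ label, mu_tab[mu_tab$valid, ],
                           positive = "tumor")
fit
#> Gaussian attenuation classifier
#>   calyx    N(3.0778, 0.1679^2)  n = 100
#>   cortex   N(2.5014, 0.1302^2)  n = 100
#>   fat      N(1.9983, 0.0995^2)  n = 100
#>   medulla  N(1.4878, 0.0644^2)  n = 100
#>   tumor    N(8.1455, 0.4463^2)  n = 100
#>   threshold (tumor vs rest): 5.6309 mm^-1, tumor above
```

Each tissue class yields a narrow µ distribution; tumor (8.15 mm⁻¹) sits
far above the normal classes (1.5–3.1 mm⁻¹), and the fitted-density
crossing at 5.63 mm⁻¹ separates them. Pelvis is absent: all 100 pelvis
images abstained. Subject-level cross-testing fits the threshold on four
kidneys and classifies the fifth:

```r
plan <- make_split_plan(unique(mu_tab$subject_id))
cross_test_attenuation(mu_tab, plan, positive = "tumor")
#> Subject-level cross-testing (pooled held-out confusion matrix)
#>        predicted
#> truth   tumor rest
#>   tumor   100    0
#>   rest      0  400
#> abstentions: 100
```

The published confusion matrices ship as fixtures, and every printed
per-class metric recomputes from their integer counts:

```r
metrics_report(oct_table_fixture("table1a"))
#>    class   tp   fp    tn   fn accuracy_pct precision_pct recall_pct f1_pct
#>   cortex 9145 6241 33759  855        85.81         59.44      91.45  72.05
#>  medulla 9154 4706 35294  846        88.90         66.05      91.54  76.73
#>    calyx 1947 2562 37438 8053        78.77         43.18      19.47  26.84
#>      fat 4942  434 39566 5058        89.02         91.93      49.42  64.28
#>    tumor 9983  886 39114   17        98.19         91.85      99.83  95.67
```

Read: the attenuation feature recognizes tumor almost perfectly (98.19 %
accuracy, 99.83 % recall) but cannot tell the normal tissue types apart —
calyx recall is 19.47 %. `reproduce_printed_metrics()` checks all 21
published per-class values against these recomputations at printed
precision.

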