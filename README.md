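# nodedce

Enhancement-pattern analysis of dynamic contrast-enhanced MRI (DCE-MRI) of
lymph nodes.

Normal lymph nodes are not homogeneous perfusion compartments: the
medulla-adjacent center takes up a gadolinium contrast agent faster and more
strongly than the cortex-adjacent periphery, and clears it faster. `nodedce`
implements the full single-slice analysis that exposes this structure, for
imaging scientists working with dynamic T1-weighted series of small
(lymph-node-sized) structures:

1. **Motion correction** — translation-only rigid registration of every
   frame to a post-injection reference (default: the 2nd frame after the
   bolus), by normalized cross-correlation maximized on an integer grid and
   refined to subpixel precision; series whose residual displacement exceeds
   a threshold are flagged for exclusion.
2. **Normalized differential enhancement (NDE)** — per pixel,

   `NDE(t) = (SI(t) − SI_PRE) / (DE_MAX)_MUSCLE`

   where `SI_PRE` is the pixel's mean pre-contrast signal and
   `(DE_MAX)_MUSCLE` is the maximal post-injection differential enhancement
   of the mean signal in a muscle reference region. Normalizing by muscle
   makes the curves invariant to global intensity scaling and compensates
   (partially) for differences in effectively administered dose.
3. **PCA screen + k-means segmentation** — principal component analysis of
   the NDE curve set reports how much variance a few enhancement patterns
   explain (two components suffice for ≥ 90 % in normal nodes, which is the
   justification for `k = 2`); k-means on the raw NDE curves (no spatial
   term) splits the node pixels into an *inner* (higher-AUC) and an *outer*
   cluster.
4. **Semiquantitative parameters** per cluster-averaged curve — AUC
   (trapezoidal, post-injection window), wash-in rate (maximum consecutive
   slope between the last baseline frame and the enhancement peak), wash-out
   rate (least-squares slope of the last 40 frames), the latter two
   normalized by the node's maximal enhancement; plus the cluster's volume
   share of the node.
5. **Statistics** — mixed two-way ANOVA (cluster = within-node factor,
   contrast agent = between-node factor) with Bonferroni-adjusted
   within-agent inner-vs-outer contrasts, applied to a node × cluster
   parameter table. A transcription of the 15-node reference table
   (9 Gd-DTPA, 6 Gd-BOPTA nodes) ships with the package.

Because real data of this kind are rarely shareable, the package includes a
**digital phantom** (`phantom_spec()`, `generate_phantom()`): a
two-compartment elliptical node (inner: higher, faster uptake, steeper
washout), a muscle strip, static anatomical structure, Gaussian or Rician
noise, and an optional per-frame motion schedule — with exact ground truth
(masks, noiseless curves, applied shifts) so every stage is testable.

## Worked example

```r
library(nodedce)

spec <- phantom_spec(seed = 1)          # 64x64, 70 frames, 3 baselines
ph   <- generate_phantom(spec)

reg <- register_series(ph$series)
reg$report
#> <registration_report> 70 frames, reference 5
#>   estimated shift: max 0.09 px; residual: max 0.002 px; flagged: FALSE

nde <- compute_nde(reg$series, roi_mask(ph$truth$node_mask, "node"),
                   roi_mask(ph$truth$muscle_mask, "muscle"))
pca_screen(nde)
#> <pca_screen> explained variance (%): 91.24, 1.89, 0.20, 0.20, 0.19 ...
#>   first two components: 93.14% cumulative

seg <- kmeans_segment(nde, k = 2, seed = 1)
seg
#> <cluster_result> k=2, 373 pixels, inertia=706.8
#>   volume: inner 30.8%, outer 69.2%

extract_all(seg, node_id = 1, agent = "Gd-DTPA")
#>   node   agent cluster      auc   wash_in    wash_out volume_pct
#> 1    1 Gd-DTPA   inner 98.68727 1.7232317 -0.02125857    30.8311
#> 2    1 Gd-DTPA   outer 79.24759 0.4081196 -0.01028251    69.1689
```

The phantom was motionless, so all estimated shifts are ~0 and nothing is
flagged. Two principal components explain 93 % of the NDE variance,
supporting two clusters; the segmentation recovers the inner compartment
(30.8 % of node pixels vs the constructed 30 %), and the inner cluster shows
the higher AUC and wash-in and the steeper (more negative) wash-out — the
signature the analysis is designed to detect.

Statistics on the packaged reference table:

```r
two_way_anova(load_param_table(), "auc")
#> <nde_anova> parameter: auc
#>   effects:
#>           term          F            p
#>        cluster 52.2252569 6.681228e-06
#>          agent  0.8454305 3.745946e-01
#>  agent:cluster  0.1278073 7.264535e-01
#>   within-agent inner - outer contrasts (Bonferroni x2):
#>     agent estimate        t df            p        p_adj     direction
#>  Gd-BOPTA 51.16667 4.293650 13 8.734913e-04 0.0017469827 inner > outer
#>   Gd-DTPA 56.66667 5.823885 13 5.935896e-05 0.0001187179 inner > outer
```

The inner cluster's AUC exceeds the outer's in both agents (adjusted
p < 0.01), while the agent main effect is far from significance — the two
contrast agents produce the same enhancement pattern.

A thin command-line front end over these functions is installed at
`inst/cli/nodedce` (subcommands `simulate`, `register`, `enhance`,
`cluster`, `params`, `stats`, `run`).

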