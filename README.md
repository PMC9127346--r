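# adeeg

Staging Alzheimer's disease from multichannel EEG. Clinicians divide
patients' EEG into three states — **calm**, **transitional** and
**morbidity** — distinguished by increasingly large and irregular amplitude
fluctuation. `adeeg` implements a three-branch analysis of such recordings
and fuses the branches at the decision level:

1. **Phase-locking networks (PE branch).** For channels x(t), y(t) with
   instantaneous phases φₓ, φᵧ (zero-phase 8–30 Hz band-pass, analytic
   signal), the phase-locking value
   PLV = (1/N)|Σⱼ exp(i(φₓ(jΔt) − φᵧ(jΔt)))| is the edge weight c_ij of a
   functional connectivity graph, summarised by weighted clustering C_i,
   characteristic path length L, global and local efficiency G and Le_i,
   and betweenness b_i (shortest paths under edge length 1/c_ij). Combined
   with one-vs-rest common-spatial-pattern (CSP) features — filters W from
   simultaneous diagonalisation of whitened class covariances, with
   Λ₁ + Λ₂ = I — these feed a multinomial classifier.
2. **Recurrence images (RE branch).** Each series is delay-embedded and its
   distance matrix r_ij = ‖X(i) − X(j)‖ is kept *unthresholded* as
   ER_ij = |ε − r_ij| (ε = 0 by default, so ER = r), preserving structure
   that the classic binary plot R_ij = φ(ε − r_ij) discards. The image is
   classified by a small residual CNN (7×7/64 stride-2 stem, eight paired
   3×3 residual blocks of widths 64–512–128, global-average-pool softmax
   head) implemented in single-precision C++.
3. **Clinical covariates.** Age, sex, hypertension, hyperlipidemia,
   diabetes and an eye-movement score are screened across the three states
   at p < 0.05 (Kruskal–Wallis / chi-squared) and the survivors feed a
   multinomial model.

Per-branch class probabilities are fused by a stacked meta-classifier
(mean and fixed-weight fusion are available), and everything is evaluated
one-vs-rest: accuracy A = (TP + TN)/(TP + FP + TN + FN) and ROC/AUC.

A seeded synthetic-EEG generator with controllable pairwise phase coupling,
three amplitude/volatility regimes and injected clinical effects provides
ground truth for every stage; no clinical data are required or included.

Intended users: researchers prototyping EEG connectivity / recurrence
pipelines and anyone needing a fully reproducible, dependency-light
reference implementation of this analysis chain.

## Worked example

```r
library(adeeg)

# a 4-channel recording in which Fp2/F3/F4 share a phase driver
kappa <- diag(4); kappa[2:4, 2:4] <- 0.9; diag(kappa) <- 1
rec <- generate_coupled_recording(coupling_spec(kappa), n_samples = 1000,
                                  fs = 128, seed = 1, state = "calm",
                                  channel_labels = c("Fp1","Fp2","F3","F4"))
pm <- plv_matrix(rec, band = c(8, 30))
print(pm)
#> <plv_matrix> 4 channels, N = 1000 samples
#>       Fp1   Fp2    F3    F4
#> Fp1 1.000 0.109 0.146 0.154
#> Fp2 0.109 1.000 0.874 0.424
#> F3  0.146 0.874 1.000 0.750
#> F4  0.154 0.424 0.750 1.000

net <- from_plv(pm)
round(network_feature_vector(net), 3)
#>  C_Fp1  C_Fp2   C_F3   C_F4      L      G Le_Fp1 Le_Fp2  Le_F3  Le_F4
#>  0.687  0.584  0.346  0.606  4.369  0.412  0.683  0.350  0.230  0.382
#>  b_Fp1  b_Fp2   b_F3   b_F4
#>  0.000  0.000  1.000  0.000
```

The coupled clique (Fp2/F3/F4) shows strongly elevated phase locking
(PLV 0.42–0.87) while the uncoupled Fp1 stays near the independence floor
(≈ 0.11–0.15). The metrics summarise that structure: F3, the most tightly
locked hub, carries all the betweenness (it bridges Fp2 and F4 on the
shortest functional paths), and the characteristic path length reflects
how far Fp1 sits from the clique.

The worked betweenness example: a relay network where a source and sink are
joined by two parallel two-edge branches gives each relay node half of the
through-traffic:

```r
betweenness(two_branch_network(), "n2", normalization = "paper_fig2")
#> [1] 0.5
```

The full synthetic study — 150 recordings (50 subjects per state),
recurrence images at side 64, 30 training epochs, subject-level splits:

```r
rep <- run_pipeline(pipeline_config(seed = 1))
round(rep$accuracies, 3)
#>       pe       re clinical    fused
#>    1.000    0.889    0.611    1.000
round(rep$roc_auc, 3)
#>         calm transitional    morbidity
#>            1            1            1
rep$screening$selected
#> [1] "age"          "diabetes"     "eye_movement"
```

All three branches beat chance (1/3) individually on the 36 held-out
recordings — the synthetic states are separable by design — fusion follows
the strongest branch, and the screen recovers exactly the three covariates
with injected effects. The run takes about 3 minutes on one CPU core.

## Command line

A thin CLI over the same functions ships in `inst/cli/adeeg`:

```sh
Rscript inst/cli/adeeg simulate --n-per-state 10 --seed 1 --out-dir sim/
Rscript inst/cli/adeeg plv --in sim/rec001_calm.tsv --band 8,30 --out plv.tsv
Rscript inst/cli/adeeg network --plv plv.tsv --out metrics.tsv
Rscript inst/cli/adeeg run --n-per-state 50 --epochs 30 --seed 1 --out report.json
```

Recordings are plain TSV (three header lines: `#fs`, `#channels`, `#state`;
one row per channel); the clinical table is CSV.

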