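# photolag

Integrated transcript–protein analysis of light-pulse time courses in fungi.

A brief light pulse triggers a fast, transient wave of transcription in many
fungi, but only a small fraction of those mRNA changes ever becomes a protein
change, and the ones that do arrive with a delay of an hour or more. `photolag`
implements the full desk analysis of such a paired experiment — for
computational biologists integrating bulk mRNA-seq with isobaric-label (TMT)
proteomics time courses, and for methodologists who want a controlled,
ground-truthed test bed for post-transcriptional buffering analyses.

## What it computes

**Kinetic simulator.** Each gene follows first-order
transcription–translation kinetics driven by the pulse:

    dm/dt = α (1 + β L(t)) − δ_m m
    dp/dt = k_s b (m₀ + a (m − m₀)) − δ_p p

with `L(t) = 1` while the light is on, baseline `m₀ = α/δ_m`, translational
attenuation `a ∈ (0,1]` (buffering: the light-induced excess of template is
translated at reduced efficiency while basal output is preserved) and boost
`b ≥ 1` (protein-only regulation). Trajectories are piecewise-exact; observed
data add negative-binomial count noise, log-normal reporter noise, per-run
batch offsets and abundance-dependent whole-run dropout, mirroring a
three-replicate design with one TMT run per replicate.

**Transcript layer.** Median-of-ratios library normalization, per-condition
log2 fold-changes against the dark control (DD), Welch tests, and the
regulation rule *P < 0.01 and |log2FC| ≥ 1 in at least one time point*, with
early/late timing (peak ≤ 25 min vs later) and a PCA summary of the response.

**Protein layer.** A fixed processing chain: per-sample glog (arsinh)
variance stabilization → least-squares batch-offset removal → presence
filtering (quantified in ≥ 2 of 3 runs) → k-nearest-neighbour imputation →
moderated paired tests with Benjamini–Hochberg FDR, and the rule
*FDR < 0.05 and |log2FC| ≥ 1*.

**Integration.** Matching of features regulated in both layers into
mRNA/protein pairs; the four-way regulatory-category partition (pairs,
protein-only changes, buffered mRNAs with protein data, regulated mRNAs
without protein data); the Pearson lag-correlation grid between transcript
log2FC at time *i* and protein log2FC at time *j* over all pairs; and the
mRNA→protein delay estimate from the grid's r² maximum.

**Clustering & reporting.** Tight (data-extraction) clustering of z-scored
regulated profiles — only coherent groups are kept, the rest stay
unassigned — with up/down/oscillatory shape calls, plus summary statistics
(percent of genome regulated, up/down splits, final-time-point peak
fraction) computed with the field's mixed rounding conventions.

## Worked example

```r
library(photolag)
cfg <- default_config(seed = 1)
cfg$classes <- list(concordant = 200, transcript_only = 200,
                    protein_only = 100, null = 2000)
run <- run_pipeline(cfg)
print(run$summary)
```

```
[de-transcripts] 403 of 2500 transcripts regulated
[proteome] 2193 proteins analysed, 277 regulated
[integrate] 185 pairs; peak lag 10 min (5L0D -> 5L10D)
[cluster] 1 clusters, 248 of 403 genes (61.5%)
Light-response summary
  mRNAs: 403 regulated of 2500 evaluated (16.1% of evaluated, 16.1% of genome 2500)
    up 399 (99%), down 4 (1%)
  proteins: 277 regulated of 2193 evaluated (12.6%)
    up 277 (100%), down 0 (0%)
    peak at final time point: 92 (33.2%)
  pairs 185; protein-only 92; mRNA-only with protein data 199; no protein data 19
```

Reading the output: of 403 regulated transcripts, 199 have protein
quantitation but no protein change — the buffered class the simulator planted
(200 genes with attenuation 0.3) is recovered almost exactly. The 185
mRNA/protein pairs are dominated by the 200 planted concordant genes, and the
lag grid places the best mRNA→protein correlation one grid cell apart (the
grid's resolution limits the delay estimate; on noise-free data the same
estimator returns 90 min — see the methods vignette).

Ground truth is always available for checking any step:

```r
table(run$sim$truth$reg_class)
head(true_peak_lag(run$sim))   # per-gene noise-free mRNA->protein delay
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/photolag.R", package="photolag"))')" \
    run --config my_config.yaml --out results/
```

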