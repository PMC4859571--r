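# lobulescreen

Mining a volumetric in situ hybridization atlas for genes behind the
anterior-to-posterior gradient of cerebellar Purkinje cell vulnerability.

Across many diseases, toxins and mouse mutants, Purkinje cells of the
anterior cerebellar lobules (II–V) degenerate first while lobule X is
strikingly resistant. Since the pattern recurs regardless of the insult,
intrinsic transcriptional differences between the subpopulations are the
suspected cause. `lobulescreen` implements the corresponding in silico
screen for researchers who want to prioritize candidate neuroprotective
and susceptibility genes from spatial expression data:

1. **Matrix assembly** — per-gene expression-energy volumes plus an
   anatomical annotation volume become one gene × voxel matrix
   (`build_expression_matrix()`); voxels within two regions of interest —
   vulnerable lobules II/III vs resistant lobule X, within 1400 µm of the
   midline — are treated as replicate observations (`select_roi_pair()`).
2. **Differential screen** (`screen_genes()`) — for each gene *i*, the
   pooled-variance Student's t with Bonferroni correction
   (p·m capped at 1), and SAM's relative difference
   d(i) = (x̄_b − x̄_a)/(s(i) + s₀) with automatic fudge-factor selection,
   balanced label permutations, asymmetric Δ-cutoffs and a
   median-permutation FDR giving per-gene q-values. The top-1000 genes per
   method (configurable) form the union carried forward.
3. **Curation surrogates** (`curate_screen()`) — keep genes detectable in
   exactly one ROI (`detectability()`) whose lobule profile matches, or
   inverts, a reference Purkinje cell survival pattern
   (`pattern_concordance()`, Pearson |r| ≥ 0.7); classify survivors as
   candidate neuroprotective (posterior) or susceptibility (anterior)
   genes, cluster them (`cluster_candidates()`), and test annotation
   over-representation with a hypergeometric tail at α = 0.01
   (`enrichment_test()`).
4. **Synthetic atlas** (`simulate_atlas()`) — a seeded generator of
   zero-inflated log-normal expression-energy volumes with planted
   region-restricted genes and ground truth, so every stage runs and is
   testable without any external download. NRRD (ascii) and long-format
   TSV round trips are supported (`write_atlas()`, `read_atlas()`,
   `load_volumes()`).

Results are tibbles that chain with the pipe; `tidy()`, `glance()`,
`autoplot()` and `plot_*()` helpers cover the common summaries and
figures. See the vignette in `vignettes/` for the model, its assumptions
and the design decisions.

## Worked example

A small end-to-end run on a simulated atlas (500 genes, 5 posterior + 5
anterior planted, one seed):

```r
library(lobulescreen)

cfg <- screen_config(
  atlas = atlas_config(n_genes = 500, n_posterior = 5, n_anterior = 5),
  top_n = 50, n_perm = 200, seed = 1
)
run <- run_screen(cfg)
run$report
#> <screen_report>
#>   genes                500
#>   tested               500
#>   top_t                50
#>   top_sam              50
#>   union                50
#>   post_detectability   10
#>   post_concordance     10
#>   candidates           10
#>   candidates by region: anterior=5, posterior=5
#>   s0 = 0.05027; 200 permutations (sampled)
```

The funnel reads: all 500 genes were testable; each method nominated its
50 best; the union (50 genes here — the two rankings agreed) passed to the
curation filters, which kept exactly the 10 planted region-restricted
genes; none were mis-assigned. The candidate table:

```r
tidy(run)
#> # A tibble: 10 × 7
#>    gene_id region    candidate_class detect_fraction_a detect_fraction_b
#>  1 g00187  anterior  susceptibility              0.762             0
#>  2 g00270  anterior  susceptibility              0.745             0
#>  ...
#>  6 g00129  posterior neuroprotective             0                 0.756
#>  ...
```

`detect_fraction_*` is the share of ROI voxels with positive energy: each
candidate expresses in one region only, the formalized "absolute
expression difference". `concordance` (last column) is the signed
correlation with the survival pattern: ≈ +0.79 for posterior candidates
(expression follows survival — putative protectors, the Hspb1-like case),
≈ −0.73 for anterior ones (expression anti-tracks survival — putative
susceptibility factors, the Prkca-like case).

```r
autoplot(run$screen)              # SAM observed-vs-expected quantile plot
plot_candidate_heatmap(run$clustering)
plot_screen_funnel(run)
```

A thin CLI over the same functions lives at
`inst/scripts/lobulescreen-cli.R` (`simulate` and `run-all` subcommands).

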