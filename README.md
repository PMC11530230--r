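# wfcm — weighted families of contact maps for flexible protein ensembles

Conformational ensembles of intrinsically disordered proteins (IDPs/IDRs)
are hard to summarize: a single average contact map or a mean radius of
gyration dilutes transient helices, turns and long-range contacts that may
be populated by only 1–3% of the conformations, even though those are often
the functionally relevant features.

`wfcm` characterizes an ensemble as a **weighted family of contact maps**:

1. every residue pair of every conformation gets a continuous contact
   value ω ∈ [0, 1] that depends on the amino-acid identities, the sequence
   separation ("range"), the Cβ–Cβ distance, and — for ranges 2–4 — the
   deviation of the two residues' relative rotation from the pair class's
   preferred orientation. The ensemble becomes an n × L(L−1)/2 matrix
   W = (ω_ij;k);
2. the rows are embedded with UMAP (10-D) and partitioned with HDBSCAN,
   whose single resolution knob is the minimum cluster occupancy
   (default 1% of n); unassignable conformations stay *noise*;
3. each cluster C_k is summarized by its mean contact map
   W̄^k = (1/|C_k|) Σ_{l∈C_k} ω_ij;l with occupancy weight p_k = |C_k|/n,
   plus per-residue secondary-structure propensities (native Kabsch–Sander
   assignment), radius of gyration and end-to-end statistics. The K-tuple
   ((W̄^1, p_1), …, (W̄^K, p_K)) plus the noise fraction is the
   characterization.

The contact-function parameters (per pair/range "Euclidean contact
interval" [d_lo, d_hi], preferred rotation, orientation tolerance) are
estimated from a reference set of folded structures with
`estimate_parameters()`. A synthetic-reference demonstration table is
bundled so everything runs offline; it is not publication grade.

The package also provides the comparison featurizations (pairwise
distances, a 12-6 Lennard-Jones inter-residue energy baseline, the naive
8 Å binary contact-probability map), labelled synthetic-ensemble
generators for validation, and a native HDBSCAN implementation.

## Worked example

```r
library(wfcm)

# a labelled synthetic ensemble: 3 x 1000 conformations of a 27-mer
# (random coil; helix over residues 16-24; hairpin contact over 10-24)
syn <- make_three_family_ensemble(n_per = 1000, seed = 42)

fit <- wfcm(syn$ensemble, default_param_table(), seed = 0)
summary(fit)
#> wfcm fit: 3 clusters over n = 3000 conformations ( 0.0% noise ), L = 27
#>
#>  cluster size weight rg_mean rg_sd end_to_end   helix  strand
#>        1 1013  0.338    11.5  1.24       17.3 0.00665 0.22643
#>        2 1004  0.335    11.7  2.40       29.1 0.37373 0.00764
#>        3  983  0.328    13.0  2.85       32.1 0.02046 0.01285

adjusted_rand_index(labels(fit), syn$labels)
#> [1] 0.9831079
```

The three clusters recover the three planted families almost exactly
(adjusted Rand index 0.983): cluster 1 is the hairpin family (strand
propensity 0.23, compact, short end-to-end distance), cluster 2 the helix
family (helix propensity 0.37 averaged over all 27 residues, i.e. ~1 on
the 9-residue planted segment), cluster 3 the coil family (no structure,
most extended). Running the same ensemble through the pairwise-distance
baseline (`feature_kind = "distance"`) merges the helix family into the
coil — a local motif barely changes the global shape — which is the
method's reason for existing.

`plot(fit, "map", cluster = 1)` renders a cluster's contact map;
`wfcm(..., dim = 2)` plus `plot(fit, "embedding")` gives the 2-D
projection. `run_pipeline()` (or the `inst/cli/wfcm` script) runs
file-to-report with a reproducibility manifest: per-cluster maps,
representative conformations as multi-model PDB, labels CSV and a JSON
summary.

For real analyses, estimate contact parameters from a curated collection
of high-resolution structures:

```r
tab <- estimate_parameters(load_ensemble("domains.pdb", chain = "A"))
write_param_table(tab, "params.json")
```

## Layout

```
R/                      implementation (io, contact function, featurization,
                        UMAP/HDBSCAN clustering, characterization, fixtures)
inst/extdata/           bundled synthetic-reference parameter table (JSON)
inst/cli/wfcm           command-line front end (run / simulate / estimate-params)
tests/testthat/         unit, property and validation tests
scripts/acceptance.R    recompute validation quantities (see above)
vignettes/              methods vignette: model, assumptions, design choices
```
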