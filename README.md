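# rgspect

Detection and component annotation of resin glycoside acylsugars from
negative-mode LC-MS/MS data.

## The problem

Resin glycosides (RGs) are defense acylsugars of the morning-glory family
(Convolvulaceae): an oligosaccharide core of 2-7 sugars (pentoses,
deoxyhexoses, hexoses), one 14-18 carbon hydroxy- or dihydroxy fatty acid
that often closes a macrolactone ring, and short decorating acyl esters.
Untargeted LC-MS/MS of these plants yields thousands of features, nearly
all missing from spectral libraries. rgspect is for metabolomics
practitioners who need to find the RG-like features in such data and narrow
down what each one is made of, without reference standards.

The package exploits the characteristic negative-mode fragmentation of RGs.
The glycosidic bond to the hydroxyacyl chain survives fragmentation,
producing a **signature fragment pair**: the free hydroxy-acid anion
together with the same chain bound to one sugar, e.g. for jalapinolic acid
(11-hydroxyhexadecanoic acid, the dominant C16 chain) with a deoxyhexose:

    [C16-OH - H]^-            m/z 271.2279
    [C16-OH + dHex - H]^-     m/z 417.2858   (= 271.2279 + 146.0579)

With 10 hydroxyacyls and 3 sugar classes the detection criterion is a table
of 30 such pairs. Around it the package provides:

- **Detection** (`detect_rg`): blank-subtraction and area filters
  (area > 1000 and > 10x blank), linked-peak resolution, signature-pair
  matching with a 10% relative-intensity floor, organ (leaf/root/both)
  calls.
- **Annotation** (`annotate_spectra`): the top-20 fragments matched against
  a curated moiety database, pairwise neutral-loss inference (sugar
  residues, acyl residues/acids, water, CO2, formic acid), annotation
  coverage, residual mass.
- **Prediction** (`enumerate_candidates`, `score_candidates`): exhaustive
  enumeration of compositions `M = water + sum(residues) - ring water`
  whose adduct m/z ([M-H]- or [M+HCOO]-) matches the precursor within
  tolerance, evidence-ranked by observed fragments and losses.
- **Co-occurrence** (`fragment_correlations`, `organ_correlation`):
  pairwise Pearson correlations of nominal-mass fragment intensities with
  water-loss (Δ18) flags, and leaf-vs-root area correlation.
- **Simulation** (`simulate_dataset`): seeded synthetic MGF + alignment
  fixtures with planted compositions and filter-violating decoys.

Inputs are MS-DIAL-style MGF exports (`read_mgf`) and tab-separated
peak-area alignment tables (`read_alignment`).

## Worked example

Simulate a small dataset (10 planted RGs plus filter-violating decoys),
detect, annotate and predict:

```r
library(rgspect)

sim <- simulate_dataset(simulation_config(seed = 7, n_rg = 10))
det <- detect_rg(sim$records, sim$table)
det
#> <rg_detection> 10/22 features kept
#> attrition: blank_area=4  linked=1  signature_pair=7
head(det$detected[, c("feature_id", "precursor_mz", "matched_pairs", "organ_call")], 3)
#>   feature_id precursor_mz      matched_pairs organ_call
#> 1     RG_001     839.4644 C16-OH:deoxyhexose       both
#> 2     RG_002    1015.4976 C17-OH:deoxyhexose  root_only
#> 3     RG_003    1461.6751 C16-OH:deoxyhexose       both
```

All 10 planted RGs survive the filters; the 12 decoys fall at the filter
they were built to violate (4 at blank/area, 1 at linked-peak resolution, 7
at the signature pair). Annotation and prediction:

```r
ids <- vapply(sim$records, `[[`, character(1), "feature_id")
ann <- annotate_spectra(sim$records[ids %in% det$detected$feature_id])
annotation_coverage(ann)
#> [1] 1
cand <- predict_components(det, ann)
head(cand[["RG_001"]][, c("deoxyhexose", "hydroxyacyl", "acyls", "macrolactone",
                          "adduct", "delta", "score")], 2)
#>   deoxyhexose hydroxyacyl acyls macrolactone  adduct         delta score
#> 1           3      C16-OH    C5         open formate  0.0001591494     3
#> 2           2      C17-OH    C5         open formate  0.0001591494     2
```

Coverage 1 means every considered fragment of every detected spectrum was
explained by a database mass or a known neutral loss. The top-ranked
candidate for `RG_001` - three deoxyhexoses, open-chain C16-OH, one C5
acyl, formate adduct, 0.16 mDa from the precursor - is exactly the planted
composition (`sim$truth`).

A thin CLI over the same functions ships in `inst/cli/rgspect.R` with
subcommands `simulate`, `detect`, `annotate`, `predict`, `correlate` and
`run-all`; `run_pipeline()` is the programmatic equivalent.

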