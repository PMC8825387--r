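---
title: "Detecting and annotating resin glycosides from negative-mode LC-MS/MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and annotating resin glycosides from negative-mode LC-MS/MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgspect)
```

## The problem

Resin glycosides (RGs) are acylsugars of the morning-glory family
(Convolvulaceae).  Each molecule combines three kinds of building blocks: an
oligosaccharide core of 2-7 sugars drawn from three mass classes (pentose,
residue 132.0423 Da; deoxyhexose, 146.0579 Da; hexose, 162.0528 Da), exactly
one 14-18 carbon hydroxy- or dihydroxy fatty acid that may close an
intramolecular macrolactone ring, and up to a handful of short decorating
acyl esters (C2-C10 aliphatic, hydroxylated, or aromatic acids).  Hundreds of
species-specific variants exist, almost all of them absent from spectral
libraries, so untargeted LC-MS/MS experiments on these plants produce
thousands of unannotatable features.

rgspect implements a knowledge-based alternative to library search.  It
exploits the fact that RGs fragment predictably in negative mode: the
glycosidic bond to the hydroxyacyl chain survives collision-induced
dissociation, producing a *signature fragment pair* - the free hydroxy-acid
anion (m/z 271.2279 for jalapinolic acid, the dominant C16 chain) together
with the same chain bound to one sugar residue (m/z 417.2858 with a
deoxyhexose).  Everything in the package builds on this observation.

## Mass arithmetic and conventions

All masses are monoisotopic, from atomic masses C 12 (exact), H 1.00782503,
O 15.9949146, N 14.0030740.  Deprotonation subtracts a proton (1.007276 Da)
and keeps the electron; this convention reproduces the jalapinolic anion at
271.2279 to four decimals.  Sugars and acyls enter compositions as
*residues* (free molecule minus one water, the water lost on glycosidic or
ester bond formation); the neutral mass of a composition is

```
M = water + sum(sugar residues) + (hydroxy acid - water)
    + sum(acyl acid - water)  - (water if the macrolactone is closed)
```

with the leading water restoring the free reducing end.  Two pseudo-molecular
species are handled: `[M-H]-` (M - 1.007276) and the formate adduct
`[M+HCOO]-` (M + 44.998200), the latter ubiquitous with formic-acid mobile
phases.

```{r}
tricolorin_a <- rg_composition(c(deoxyhexose = 3, hexose = 1), "C16-OH",
                               c("C5", "C5"), "closed", "formate")
composition_mass(tricolorin_a)
precursor_mz(tricolorin_a)
```

## The moiety database

The shipped database holds the three sugar classes, ten hydroxyacyl chains
and twenty-two acyl fragment masses.  The ten hydroxyacyls are the mono- and
dihydroxy C14-C18 acids: C15-OH, C16-OH, C16-OHOH, C17-OH and C18-OH are
well documented in RG structures, and the set is completed symmetrically
across both hydroxylation states so that each chain length is represented.
The twenty-two acyls cover the short aliphatic series (acetic through
decanoic and the longer saturated/unsaturated chains), hydroxylated and keto
variants (HMBA, acetoacetic), and the aromatic series (benzoic, cinnamic,
coumaric, caffeic, ferulic) - the acyl-CoA space between 50 and 200 Da that
plausibly decorates acylsugars.  Because exact membership is a curation
choice, the database is serialisable to YAML (`write_moiety_db()`) and every
function accepts a replacement; masses are always recomputed from the
formulas on load so a file cannot drift out of sync.

A `frequent` flag marks the acyls commonly seen in RG data (acetic, butyric,
C5, tiglic, HMBA, cinnamic); `derive_frequent_acyls()` re-derives this set
empirically from any detected dataset as the acyls occurring in strictly
more than 5% of RG peaks.  The strict inequality is a deliberate reading of
"more than 5%": an acyl seen in exactly 5% of peaks stays out.

## Detection filters

`detect_rg()` applies four filters, in this order:

1. **Blank/area** - the feature's area in leaf or root must exceed 1000
   *and* exceed 10 times its blank area.  A blank area of 0 passes the
   ratio clause.  The low absolute floor is intentional: RG peaks of real
   interest can be faint on an Orbitrap.
2. **Linked peaks** - when the upstream alignment links a feature to a
   co-eluting feature of higher mass, only one of the two is processed
   (default: the higher).  Adduct-labelled features are always retained.
   This mirrors upstream behaviour faithfully, including its known cost: a
   genuine RG linked to a higher mass is lost.
3. **Signature pair** - at least one of the 30 hydroxyacyl / hydroxyacyl +
   sugar pairs must be present, and
4. **Relative intensity** - both members of a matching pair must exceed 10%
   of the base-peak intensity.  The 10% rule is applied to pair members
   only, not to every fragment: the documented false-negative case (a C15
   hydroxyacyl fragment at 4% of the base peak) concerns a pair member, and
   applying the rule spectrum-wide would discard information the annotation
   stage can still use.

Organ calls then follow the area scenarios: >1000 in one organ and 0 in the
other gives a single-organ call, >1000 in both gives `both`, anything else
is `ambiguous`.

The fragment-match tolerance defaults to an absolute 0.01 Da (ppm mode is
available).  No tolerance is dictated by the underlying method description;
0.01 Da is appropriate for Orbitrap MS/MS and absorbs the small differences
between theoretical and instrument-observed values (417.2854 observed vs
417.2858 theoretical; 299.2586 observed vs 299.2592 computed for C18-OH).
The theoretical values are canonical throughout; printed observed values
are treated as instrument readings of them.

## Fragment annotation

`annotate_spectrum()` considers the top 20 fragments by intensity (ties at
the cutoff resolve toward the lower m/z, making the selection
deterministic), matches them against a fragment database derived from the
moieties (hydroxyacyl anions, hydroxyacyl + 1 and + 2 sugars, acyl anions,
short sugar-chain ions), then compares all pairwise differences - with the
precursor included as a node - against a neutral-loss database: sugar
residues, acyl residues *and* acyl free acids, water (18.0106), CO2
(43.9898) and formic acid (46.0055).  Acyl losses appear in both residue and
free-acid form because ester cleavage can release either; acetic acid in
particular is recognised through its 60.0211 free-acid loss, never through
an acetate fragment ion.  A fragment counts as annotated when it carries at
least one assignment or participates in at least one loss edge;
`annotation_coverage()` pools this fraction across spectra.

The residual between the precursor and the highest annotated fragment is
recorded per spectrum; prediction verifies every candidate against the full
precursor mass rather than chaining arithmetic off the residual, which
avoids accumulating matching error across steps.

## Component prediction

`enumerate_candidates()` walks the full composition space - sugar multisets
of total size 2-7 over the three classes (116 cores), every hydroxyacyl,
acyl multisets up to the configured budget, open and closed ring, both
adducts - and keeps candidates within the precursor tolerance (default
0.01 Da).  Default mode uses the frequent acyl pool with at most three
acyls; extended mode allows five and adds decanoic acid.  Enumeration is
exhaustive and is verified in the test suite against a brute-force
generate-and-test oracle on reduced pools; an explicit candidate cap
(10 000) turns a runaway tolerance into an error instead of silent
truncation.

Ranking is two-stage.  Candidates are first ordered by mass closeness; with
an annotation available, `score_candidates()` adds one point per component
backed by an observed fragment or loss (hydroxyacyl anion, hydroxyacyl +
sugar pair per used class, each distinct acyl) and subtracts one point from
formate candidates when no formic-acid loss off the precursor was seen.
Ties resolve by |Δmass|, then fewer components, then the lexicographic
composition string - fully deterministic.

Two structural degeneracies deserve note.  First, deoxyhexose + HMBA is
exactly isobaric with hexose + C5 (146.0579 + 100.0524 = 162.0528 +
84.0575); the residue arithmetic fixes which swap is degenerate, and both
members are always reported.  Second, a closed-ring candidate is isobaric
with the open-ring candidate one water lighter; both are kept, since either
may be the true structure.

`evaluate_recall()` scores a known RG as correctly predicted when its
component identity - sugar counts, hydroxyacyl, acyl multiset - appears
anywhere in its peak's candidate set; ring state and adduct are mass
bookkeeping rather than components, so they are reported but not matched.

## Co-occurrence statistics

`build_fragment_matrix()` bins fragment intensities at nominal (integer Da)
mass, summing collisions so each row conserves its spectrum's total
intensity.  `fragment_correlations()` computes Pearson correlations for
column pairs with at least 3 jointly nonzero observations (pairs below that
are not reported; zero-variance columns yield NA, not 0) and flags pairs 18
Da apart as candidate water-loss partners.  Intensities enter raw by
default with a log10 option, since no transform is canonical for this
statistic.  `organ_correlation()` correlates leaf against root areas over
the detected RGs after normalising each organ to its total ("relative"
areas); raw mode is available, and fewer than three usable features returns
an explicit insufficient-data result.

## The synthetic generator, and what it does not show

`simulate_dataset()` builds a complete MGF + alignment-table fixture:
planted RGs with known compositions and organ assignments, plus decoy
features that each violate one specific filter (no signature pair,
blank-dominated, sub-1000 area, a pair member at 4% relative intensity, a
true RG linked to a higher mass).  Fragments follow
`fragment_composition()`: the hydroxyacyl anion as base peak (1e6), ladder
and satellite ions log-uniform between 10% and 100% of base - placed just
above the 10% rule so clean presets are detectable by construction -
Gaussian m/z jitter of SD 0.001 Da (a third of the match tolerance), and
precursor m/z confined to the 500-2000 instrument scan window.  Decoy m/z
values are rejection-sampled to sit at least 0.02 Da from every database
fragment mass and to form no database loss with any other peak, so
unexplainable means unexplainable by construction, not by luck.  Everything
is deterministic under the configured seed.

The generator emulates fragmentation topology, not physics: intensities are
not collision-energy models, there are no isotope envelopes, no chimeric
spectra, no retention-time structure, and sugar identity within a class
(rhamnose vs fucose vs quinovose) does not exist at this resolution.
Passing round-trip tests on clean synthetic data therefore demonstrates the
*logic* of the pipeline - filter semantics, annotation completeness on
explainable fragments, enumeration coverage - and says nothing about recall
on noisy instrument data, where fragment dropout and co-isolation dominate.

## Problem sizes and numerical choices

The shipped tests run detection fixtures of 20-60 features, a 13-spectrum
known-RG benchmark (including one five-acyl open-chain structure assembling
exactly to C62H104O27 and one decanoic-containing structure, the two cases
that require extended mode), enumeration-oracle comparisons on reduced
pools (2 hydroxyacyls, 3 acyls, cores of 2-4 sugars), and a 50-RG clean
round trip; these sizes exercise every code path while keeping the suite
fast.  Database mass consistency is enforced to 1e-6 Da; candidate and
fragment matching use the configured tolerances everywhere, and no value is
ever rounded before comparison.

## Known limitations

Stereochemistry, positional isomers, sugar identity within a mass class and
intermolecular RG condensates are out of scope.  Precision is intentionally
sacrificed for recall: candidate sets are complete within the configured
pools and tolerance, and are meant to be filtered by the evidence score and
by manual inspection of formate and acyl-specific losses.  Dataset-level
survey counts from instrument studies depend on upstream peak picking and
alignment and are not reproduced by this package; its guarantees are the
desk-scale ones its tests compute.
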