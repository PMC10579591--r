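# gutfast

Genome-centric analysis of gut-microbiome reassembly during prolonged
fasting.

## The problem

During a multi-day water-only fast the human gut loses most of its
bacterial biomass, yet the community does not simply thin out: it
reorganizes.  Some species bloom in relative terms while most collapse,
and the community recovers quickly after refeeding.  Describing this
requires working at several layers at once — metagenome-assembled
genome (MAG) catalogs, length-normalized abundance profiles,
genome-level metabolic potential, ecological statistics, absolute
(qPCR-anchored) cell counts, and associations with the host metabolome
and clinical variables.  `gutfast` packages that analysis as tested,
reusable R functions for anyone working with longitudinal shotgun
metagenomes of perturbation studies (fasting, antibiotics, dietary
interventions).

## What it computes

* **Catalog refinement** — the high-quality MAG gate (completeness
  ≥ 90%, contamination ≤ 5%) and the same-sample bin-merge rule
  (sequencing depth within ±10% of the pair mean, GC within ±2 points,
  identical species assignment), with merge groups as connected
  components; genome length/GC from FASTA.
* **Profiling** — relative abundances
  *a*ᵢₛ = (*r*ᵢₛ/*L*ᵢ) / Σⱼ(*r*ⱼₛ/*L*ⱼ) for species and genes, taxon
  roll-ups, and KO / CAZy-family profiles renormalized over annotated
  genes.
* **Module engine** — a parser for KEGG-style Boolean module
  definitions (steps; `+` complexes, `,` alternatives, `-` optional
  parts, `--` wildcards), the module completion ratio
  MCR = satisfied steps / counted steps, per-genome module abundance
  (KO gene copies × MCR), and per-sample gut metabolic module (GMM)
  profiles (median over detected KOs, zeroed below half coverage) with
  category summaries.
* **Ecological statistics** — Shannon diversity (nats), richness,
  Bray–Curtis dissimilarity, PCoA, PERMANOVA
  (R² = tr(*HGH*)/tr(*G*), permutation p-values, exhaustive
  enumeration for small n, adjusted R²), exact and approximate
  Wilcoxon rank-sum, Kruskal–Wallis, Student's t,
  Benjamini–Hochberg q-values, Spearman correlation.
* **Fasting response** — classification of fasting-resistant (FRB) and
  fasting-sensitive (FSB) species from pooled fasting vs non-fasting
  Wilcoxon tests with FDR control; gross group abundances; total
  bacterial load from qPCR by 2^−ΔΔCt with reference-strain
  calibration; absolute group abundances in cells per gram of feces.
* **Host association** — "one-to-all" PERMANOVA effect sizes of single
  species on the metabolome, combined effects of species sets, and a
  screened species–clinical Spearman correlation table
  (|ρ| > 0.35, q < 0.05 by default).
* **Synthetic study generator** — a seeded 46-subject × 5-timepoint
  multi-omic study (abundances, read counts, qPCR plates, metabolome)
  with planted responders and ground-truth labels, used by the test
  suite to demonstrate end-to-end recovery.

See `vignettes/fasting-microbiome-reassembly.Rmd` for the full model
description and the reasoning behind every under-specified choice.

## Worked example

```r
library(gutfast)

cfg <- sim_config(n_subjects = 10, n_species = 80, n_frb = 20, n_fsb = 20,
                  reads_per_sample = 2e5, seed = 42)
study <- simulate_study(cfg)

lengths   <- setNames(study$catalog$species$genome_length,
                      study$catalog$species$species_id)
abundance <- species_relative_abundance(study$counts, lengths)
res       <- classify_fasting_response(abundance, study$truth$design)
summary(res)
#> Fasting response: 80 species tested; 21 FRB, 20 FSB, 39 neutral
#> Strongest responders by |log2 fold|:
#>  species_id label log2_fold      q_value
#>      sp0065   FRB  2.724568 1.121527e-06
#>      sp0064   FRB  2.437991 7.612201e-07
#>      sp0063   FSB -2.377537 1.404792e-07
#>      sp0069   FSB -2.326069 2.214707e-07
#>      sp0003   FSB -2.309752 1.404792e-07
```

The classifier recovers all 40 planted responders with the planted
direction, plus one borderline neutral species called FRB (21 FRB and
20 FSB reported).  Anchoring relative abundances to qPCR loads turns
the picture absolute — in relative terms FRB jump from 19% to 61% of
the community, yet their absolute population still shrinks, because
total load collapses ~50-fold during fasting:

```r
loads    <- qpcr_total_load(study$qpcr$measurements, study$qpcr$references)
groups   <- group_relative_abundance(abundance, res)
absolute <- group_absolute_abundance(groups, loads)
signif(absolute[, c("subj01_T0", "subj01_T1")], 3)
#>         subj01_T0 subj01_T1
#> FRB      4.66e+08  54600000
#> FSB      1.76e+09   9950000
#> neutral  8.46e+08  38700000

permanova(bray_curtis(abundance), study$truth$design$timepoint,
          n_permutations = 999, seed = 1)
#> PERMANOVA: R2 = 0.4802 (adjusted 0.4340), F(4,45) = 10.391, p = 0.001 [999 permutations]
```

Timepoint explains 48% of the Bray–Curtis distance-space variance in
this small synthetic cohort (p = 0.001, the smallest value 999
permutations can resolve).

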