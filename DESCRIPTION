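Package: gutfast
Title: Genome-Centric Analysis of Gut Microbiome Reassembly During
    Prolonged Fasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-centric longitudinal analysis of the human
    gut microbiome under prolonged (water-only) fasting.  Refines
    metagenome-assembled genome (MAG) catalogs with a quality gate and a
    same-sample depth/GC/taxonomy bin-merge rule; computes
    length-normalized relative abundances for species, genes, KEGG
    orthologs (KO) and CAZy families; parses KEGG-style Boolean module
    definitions to obtain module completion ratios, per-genome module
    abundances and per-sample gut metabolic module (GMM) profiles;
    provides ecological and inferential statistics (Shannon diversity,
    Bray-Curtis dissimilarity, principal coordinates analysis, PERMANOVA
    with permutation p-values and adjusted R-squared, exact Wilcoxon
    rank-sum, Kruskal-Wallis, Student's t, Benjamini-Hochberg control,
    Spearman correlation); classifies fasting-resistant and
    fasting-sensitive bacteria, converts qPCR cycle thresholds into
    absolute bacterial loads by the 2^-ddCt method, and quantifies
    microbiome-metabolome and microbiome-clinical associations.  A
    seeded synthetic longitudinal multi-omic study generator with ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
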