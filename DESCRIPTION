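Package: oxyradapt
Title: Convergent OxyR Adaptation Analysis: i-Modulons, Structure Proximity, Allele Screening, Proteome Cost and Lag Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying convergent adaptive mutations in the
    bacterial peroxide sensor OxyR. Provides seeded synthetic-data generators with
    ground truth (expression matrices with planted independently modulated gene
    groups, coding-sequence collections with planted substitutions, two-conformer
    toy protein structures, lagged-logistic growth curves); robust independent
    component analysis of transcriptomes with i-modulon membership, regulon
    enrichment and differential activity tests; minimum heavy-atom distance
    mapping of mutations to structural stability features on oxidized and reduced
    conformers with rule-based impact classification; coding-sequence
    deduplication, substitution calling and screening of allele collections
    against a constitutive-activation reference set; a reduced linear
    proteome-allocation model of the growth cost of over-expressing
    stress-tolerance genes; and tangent-method lag-phase estimation with
    dose-response summaries. A pipeline driver orchestrates all stages from a
    single YAML configuration with one governing seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
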