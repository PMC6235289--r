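Package: micdiv
Title: Statistical Analysis of Microbial Population Microdiversity from Deep
    Amplicon Allele Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying within-population genetic microdiversity
    from deeply sequenced amplicon loci. Provides per-locus allele tables
    with codon-aware reference alignment; frequency-weighted pairwise
    distance spectra with geometric (asexual neutral drift) nulls; allele
    rank-frequency spectra with asexual and recombinant coalescent null
    bands; depth-conditioned site-frequency spectra of transition dimorphs
    with a beta-binomial sampling expectation; synonymous and
    non-synonymous divergence statistics (an error-normalized internal
    method and a codon-counting method), single-coalescence-time divergence
    fits, and GC-bias bookkeeping for genome pairs; two-site haplotype
    linkage statistics with joint-frequency-matched downsampling; and a
    sequencing-error model with a false-negative mixture solver. A built-in
    coalescent simulator (Kingman genealogies and the Hudson ancestral
    recombination graph, Kimura two-parameter mutation with optional GC
    bias) and a synthetic-data generator with controllable dn/ds and a
    454-style error overlay allow every stage to be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
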