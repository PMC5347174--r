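Package: bicodon
Title: Bicodon Usage Bias and Pause-Propensity Scoring of Synonymous Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes codon-pair (bicodon) usage statistics from two coding-sequence
    corpora contrasted by protein abundance, including relative synonymous bicodon
    usage (RSBU), a pause-propensity index (the low-abundance minus high-abundance
    RSBU difference), per-bicodon Fisher exact tests and codon-bias-corrected
    residual scores. Enumerates all synonymous bicodon variants reachable by point
    mutation, ranks the pause-propensity change of a synonymous SNP against that
    empirical null distribution, and compares groups of variants (for example
    disease-associated versus benign) with rank tests. Includes a synthetic
    coding-sequence generator with controlled codon usage and planted bicodon
    enrichment for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
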