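Package: papfam
Title: Purple Acid Phosphatase Gene-Family Discovery and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering and annotating
    purple acid phosphatase (PAP) gene families in plant proteomes.
    Builds a profile hidden Markov model from a seed alignment and scans
    proteomes for candidate family members; verifies candidates against
    the five conserved metallophosphoesterase motif blocks and seven
    metal-ligating residues, with tolerated substitutions and domain
    architecture calls; annotates candidates with molecular weight,
    isoelectric point (Bjellqvist pKa set), N-glycosylation sequons,
    exon/intron structure inferred from CDS-genomic comparison, and
    degenerate promoter cis-elements (P1BS, W-box, TC element); classifies
    candidates into subgroups on neighbor-joining trees with bootstrap
    support; and provides qPCR relative-expression statistics (delta-delta-Ct)
    and candidate-gene SNP-trait association with structure covariates,
    PVE and FDR control. A synthetic-data module generates every input
    with ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
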