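Package: sexbiasevo
Title: Evolution of Sex-Biased Gene Expression Across a Species Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of sex-biased gene expression across a
    species phylogeny from strain-replicated RNA-seq counts. Provides TPM
    quantification and expression filtering, a negative-binomial Wald stage
    for calling male-/female-biased genes at a controlled false discovery
    rate, cross-species sharing spectra and pairwise switch tables,
    Brownian-motion maximum-likelihood ancestral expression reconstruction
    with branch-polarized gain/loss/switch calling, concordance
    classification of male versus female expression changes, the
    divergence-to-polymorphism expression selection statistic (delta-x),
    the tissue-specificity index tau, X-versus-autosome enrichment tests,
    and a negative-binomial study simulator with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
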