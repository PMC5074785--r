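Package: epiland
Title: Buffering, Potentiation and Line-Crossing Epistasis in
    Strain-by-Condition Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a molecular buffer or potentiator
    (such as the chaperone Hsp90) hides or reveals genetic variation in
    quantitative single-cell phenotypes.  Provides a generator for
    synthetic per-cell morphological trait tables with known
    strain-by-condition structure; preprocessing (Box-Cox normalization,
    replicate correction, stage-specific principal components); a Gibbs
    sampler for a bivariate hierarchical variance-components model with
    condition-specific residual variances and highest-posterior-density
    tests on between-strain variance differences; a Robertson-type
    decomposition of genotype-by-condition interaction variance into
    line-spreading and line-crossing parts; divergence-from-ancestor
    response statistics; and a stabilizing-selection truncation model
    showing how selection turns crossing-type epistasis into apparent
    buffering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
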