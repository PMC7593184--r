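Package: mitosel
Title: Detecting Natural Selection on Mitochondrial Haplotypes in
    Replicated Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring natural selection on maternally inherited
    mitochondrial haplotypes from pool-sequenced experimental evolution
    lines. Provides a Wright-Fisher forward simulator of haplotype-frequency
    trajectories under selection and drift with two-stage pool-seq read
    sampling; control-sample-based filtering of protein-coding genes for
    mapping bias (goodness-of-fit chi-square with false-discovery-rate
    control); haplotype-frequency estimation as the mean of per-gene read
    proportions; per-line relative-fitness estimation from the haploid
    selection recursion; compositional analysis of fitness via principal
    components with repeated-measures ANOVA and permutation inference;
    partial least squares linking haplotype-frequency change to sex-specific
    reproductive-fitness change with a bias-corrected, sign-aligned
    bootstrap; and synonymous/nonsynonymous divergence summaries of the
    competing mitogenomes under the invertebrate mitochondrial code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
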