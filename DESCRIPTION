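Package: fnirsopt
Title: Metaheuristic Channel Selection for Multichannel fNIRS Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper channel selection for discriminating two participant
    groups from multichannel functional near-infrared spectroscopy (fNIRS)
    recordings. Provides three feature extractors (task-window temporal
    mean, pairwise Pearson functional connectivity, and Daubechies-5
    wavelet approximation energy), seven binary-mask metaheuristic
    optimizers (genetic algorithm, particle swarm optimization, three
    parallel GA-PSO hybrids, and two serial hybrids) driven by a
    cross-validated support-vector-machine fitness, evaluation metrics,
    balanced two-way ANOVA reporting with Bonferroni pairwise comparisons,
    and a seeded generator of fNIRS-like verbal-fluency-task datasets with
    known informative channels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
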