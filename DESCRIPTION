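Package: opcharge
Title: Optimal Point Charge Approximations of Molecular Charge Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Replaces an arbitrary distribution of point charges with a small
    number of optimally placed point charges that reproduce its multipole
    expansion to the highest possible order. Implements Cartesian and
    spherical multipole moments in the traceless (Buckingham) convention,
    exact Coulomb and truncated multipole potentials, spherical-shell error
    metrics, a general numeric solver based on sequential (lexicographic)
    minimization of the moment-discrepancy expansion, closed-form 1- and
    2-charge solutions (including the practical point charge approximation,
    PPCA, for neutral and charged groups), and a symmetric three-charge
    solver for C2v targets such as the water molecule. Charge sets are plain
    tibbles; fitted approximations come with broom-style tidy() and glance()
    methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
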