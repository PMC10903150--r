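Package: tprm
Title: Topological Parametric Response Mapping of Paired Lung CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise parametric response mapping (PRM) of co-registered
    inspiration/expiration lung CT and its topological extension: local
    Minkowski-functional maps (volume density and Euler-Poincare
    characteristic) per PRM class, spirometric staging and cohort statistics,
    and a patch-based sparse dictionary-learning classifier of fast versus
    slow FEV1 decline. Ships synthetic paired-CT phantom and cohort
    generators with known ground truth so the whole pipeline is testable
    without protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
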