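Package: ldltraj
Title: LDL Cholesterol Target Attainment and State-Sequence Trajectories
    from Routine Care Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for low-density lipoprotein cholesterol (LDL-c)
    management analyses in secondary-prevention cohorts assembled from
    routine-care electronic health records. Derives LDL-c by the Friedewald
    formula where no direct measurement exists, applies laboratory
    reliability filters, defines a cardiovascular-disease cohort, categorizes
    measurements against the guideline target, links repeated measurements
    into follow-up state sequences, estimates empirical Markov transition
    matrices, clusters sequences by optimal-matching dissimilarity, classifies
    favorable and unfavorable change including statin dose-equivalent changes,
    and fits the associated logistic models. Ships a synthetic EHR generator
    with known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
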