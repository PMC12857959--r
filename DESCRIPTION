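Package: krillspr
Title: Length-Based Spawning Potential Ratio Assessment for Antarctic Krill
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An equilibrium length-structured per-recruit model with
    growth-type groups for estimating the spawning potential ratio (SPR) of
    Antarctic krill (Euphausia superba) from fishery length compositions.
    Includes maximum-likelihood fitting of logistic selectivity and relative
    fishing mortality to 2-mm binned length data by management stratum and
    year, a growth-parameter sensitivity engine, SPR-based reference points
    with a hockey-stick harvest control rule, an environment-length
    random-intercept mixed-model stage, and a synthetic-data generator that
    emulates observer-program length records and environmental panels with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
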