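Package: drivesim
Title: Simulation and Estimation for CRISPR Homing Gene Drive Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic forward simulation of CRISPR homing gene drive
    inheritance in single-generation Drosophila crosses, covering standard,
    split (unlinked Cas9) and synthetic-target-site drive architectures:
    germline drive conversion, germline and early-embryo resistance allele
    (r1/r2) formation, maternal Cas9/gRNA deposition and one-generation
    Cas9 carryover into the offspring germline. Companion estimators
    recover drive performance parameters (drive conversion efficiency,
    embryo r2 resistance rate, germline r2 rate) from phenotype count
    tables, with Wilson score intervals, an exact two-sided Fisher test by
    hypergeometric enumeration, a Mendelian-inheritance check, and a
    Monte-Carlo parameter-recovery harness over a catalog of laboratory
    cross designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
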