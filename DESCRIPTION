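Package: pkprescreen
Title: Neural-Network Prescreening of Oral Absorption Models for
    Pharmacokinetic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Assigns an individualized oral-absorption model (first-order,
    Erlang transit-chain, or mixed "split-peak") to a 12-point
    concentration-time profile.  Provides closed-form solutions for the
    three one-compartment absorption models together with a
    numerical-integration oracle, a population simulator with log-normal
    between-subject variability and proportional residual error, per-subject
    min-max feature scaling, a seeded feed-forward softmax classifier
    trained by mini-batch gradient descent, confusion-matrix evaluation
    against the no-information rate, and a prescreening interface for
    NONMEM-style observed datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
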