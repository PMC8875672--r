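Package: TDMBayes
Title: Bayesian Therapeutic Drug Monitoring by Hamiltonian Monte Carlo
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual pharmacokinetic parameter estimation for therapeutic
    drug monitoring of amikacin, vancomycin, theophylline, and phenytoin from
    sparse concentration measurements. Implements lognormal population priors
    with covariate models (lean body weight, Cockcroft-Gault creatinine
    clearance), closed-form one- and two-compartment infusion and first-order
    absorption models, a Michaelis-Menten elimination model with zero-order
    input, a No-U-Turn Hamiltonian Monte Carlo sampler and a maximum a
    posteriori estimator for the individual parameters, steady-state dose
    target prediction with proportional dose recommendation, a virtual-patient
    simulator, and a simulation-based validation harness reporting mean
    percentage error and root mean squared error of predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
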