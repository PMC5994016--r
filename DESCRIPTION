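Package: capsidgp
Title: Bayesian Optimization of Capsid Self-Assembly Kinetics from Small-Angle Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers kinetic rate parameters of viral capsid self-assembly from
    time-resolved small-angle scattering (SAXS/SANS) data. Provides exact
    enumeration of the structurally unique intermediates of a dodecahedral
    (12-pentamer) model capsid under rotational isomorphism, deterministic
    (ODE) and stochastic (Gillespie) simulators of the monomer-addition
    reaction network, synthesis of time-resolved scattering experiments via
    the Debye structure factor under a dilute assumption, and a
    multi-Gaussian-process Bayesian optimizer that recovers rate constants by
    minimizing a scattering RMSD objective with a lower-confidence-bound
    acquisition function over a portfolio of seven covariance kernels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
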