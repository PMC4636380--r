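Package: tfbsdyn
Title: Biophysical Population Genetics of Transcription Factor Binding Site
    Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the gain and loss of transcription factor binding sites
    (TFBS) in regulatory DNA by coupling a thermodynamic model of TF occupancy
    to an origin-fixation (fixed-state) Markov chain over mismatch classes.
    Provides point and indel mutation kernels, substitution rate matrices,
    stationary distributions, spectral convergence diagnostics, mean
    first-passage (gain and loss) times with tridiagonal and shortest-path
    reductions, a forward Wright-Fisher simulator for regulatory sequences
    (including cooperative TF binding and alternative promoter fitness maps),
    closed-form promoter-scale theory for the accumulation of strong binding
    sites, and generators for synthetic sequences and randomized energy
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    deSolve
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
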