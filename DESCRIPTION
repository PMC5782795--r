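Package: dynaclamp
Title: In Silico Dynamic Clamp of Virtual Cardiomyocytes with Simulated
    Inward-Rectifier Current
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a dynamic-clamp rig for human induced
    pluripotent stem cell derived cardiomyocytes (iPSC-CMs). A fixed-tick
    (20 kHz) closed loop couples a time-dependent inward-rectifier potassium
    current (I_K1) model -- including instantaneous Mg2+ block and two modes
    of spermine block, one carried by a slow gate -- to a calibrated
    Hodgkin-Huxley surrogate of a suspended iPSC-CM (leak, fast Na+ and
    L-type Ca2+ currents). The package ships the standard voltage-clamp step
    protocols (Na+, Ca2+ and I_K1 current-voltage families, Ba2+
    subtraction), current-clamp pacing with per-cell stimulus optimization,
    I_K1 conductance titration, L-type Ca2+ channel pharmacology
    (nifedipine block, BayK-8644 agonism), and the analysis layer: action
    potential feature extraction (resting potential, amplitude, APD90,
    upstroke velocity), peak-current I-V curves, Boltzmann activation fits
    and Hill concentration-response fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
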