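Package: crevo
Title: Eco-Evolutionary Dynamics of Metabolic Allocation Strategies
    under Non-Linear Tradeoffs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consumer-resource models of microbial communities competing
    for p substitutable resources under a non-linear metabolic tradeoff
    on the allocation strategy (sum of alpha_j^gamma constrained to a
    fixed budget).  Provides chemostat and serial-dilution ecological
    dynamics integrated with 'deSolve', closed-form and numerical
    adaptive-dynamics analytics (singular strategy, invasion fitness,
    selection gradient, convergence and evolutionary stability), a
    mutation-selection evolution engine on the tradeoff surface, and
    observables for phenotype clustering, specialist classification and
    ecological community assembly.  The tradeoff curvature gamma controls
    the evolutionary outcome: diversification into at most p specialists
    for gamma < 1, a single generalist for gamma > 1, and neutral
    diffusive diversification only in the structurally unstable linear
    case gamma = 1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
NeedsCompilation: yes
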