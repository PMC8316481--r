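Package: maxentnet
Title: Maximum-Entropy Configuration Models for Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits exponential random graph models with local constraints
    (degree and strength sequences) by maximum likelihood: the undirected,
    directed and bipartite binary configuration models, the enhanced
    configuration models constraining degrees and strengths jointly, the
    conditional reconstruction method with exponential weights, and the
    degree-corrected gravity model. Three interchangeable solvers are
    provided (Newton with Armijo backtracking, a diagonal quasi-Newton
    method, and a fixed-point iteration on the stationarity conditions),
    together with problem reduction over identical-constraint node classes,
    canonical ensemble sampling, and accuracy diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
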