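Package: selexpo
Title: Selective Exposure and Naive Learning in Collective Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of collective decision-making on directed
    information networks with fixed in-degree. Agents either naively adopt the
    median opinion of their information sources or selectively rewire away from
    their most incongruent source, mixing the two behaviours with a propensity
    parameter. The package provides four generative models of initial opinions
    (binary jury, normal, bimodal mixture, exponential), closed-form
    no-influence null models (jury probability, central-limit and sample-median
    asymptotics), steady-state and trajectory measures (individual and
    collective performance, opinion diversity, giant strongly connected
    component, directed modularity), and a reproducible parameter-sweep
    harness.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
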