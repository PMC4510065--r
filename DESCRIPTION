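Package: coalgrow
Title: Neutral Coalescent Simulation and the Site Frequency Spectrum by
    Recursive Tip Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genealogies under the standard neutral (Kingman)
    coalescent with infinite-sites mutation, and grows an n-sample mutated
    genealogy into an (n+1)-sample genealogy by splitting a uniformly chosen
    tip and extending all tips by an exponential increment, with exact
    bookkeeping of the mutations on the split tip's root path. Provides the
    closed-form expectations of the site frequency spectrum, segregating
    sites, coalescent intervals and the time to the most recent common
    ancestor, and a Monte-Carlo harness that verifies every closed form
    against simulation with standard errors and z-scores. Includes Newick
    and ms-style text output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
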