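Package: supercut
Title: Cut-Based Compatibility and Agreement of Unrooted Phylogenetic Trees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decides whether a profile of unrooted phylogenetic trees with
    overlapping label sets admits a compatible supertree or an agreement
    supertree, using characterizations in terms of minimal edge cuts of the
    display graph and minimal vertex separators of its line graph (the edge
    label intersection graph).  Certificates are complete sets of pairwise
    parallel legal minimal cuts; supertrees are assembled from the splits the
    cuts induce, and a legal triangulation of the display graph can be built
    directly from any certificate.  Includes exact exhaustive deciders for
    desk-scale profiles, brute-force oracles, seeded random profile
    generators, certificate verification, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
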