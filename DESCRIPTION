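Package: phylogem
Title: Morphological Parsimony, Ancestral States and Event-Based
    Biogeography on Pixel Grids
Version: 0.1.0
Authors@R:
    person("phylogem", "maintainers", email = "maintainers@phylogem.invalid",
           role = c("aut", "cre"))
Author: phylogem maintainers [aut, cre]
Maintainer: phylogem maintainers <maintainers@phylogem.invalid>
Description: Tools for equal-weights morphological parsimony (Fitch tree
    length, consistency and retention indices, ACCTRAN/DELTRAN character
    optimization, synapomorphy classification), heuristic most-parsimonious
    tree search with strict consensus and Bremer (decay) support, parsimony
    ancestral-state reconstruction of categorical traits, and a
    geographically-explicit event model of range evolution that assigns
    vicariance, sympatry, point-sympatry or founder events to the nodes of a
    phylogeny over 1-degree pixel grids and minimizes reconstruction cost by
    a flipping search with permutation tests. Includes simulators for
    character matrices, trees, range histories and traits with known ground
    truth, readers and writers for TSV/TNT/NEXUS matrices, Newick trees and
    occurrence/trait tables, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
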