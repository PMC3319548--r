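Package: hiermod
Title: Hierarchical Modularity Scoring and Fuzzy Reconstruction of Gene Module Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the functional coherence of hierarchical gene modules
    against a hierarchical taxonomy of functional terms (such as the Gene
    Ontology) with the hierarchical modularity score (HMS): each internal
    node of a module tree is annotated with the most specific common
    functional terms of its children, weighted by term specificity and by a
    penalization factor that discounts annotation drift between parents and
    children. Provides Monte-Carlo empirical p-values for module scores,
    calibration of the penalization parameter against a validation set, and
    TAFI, a taxonomy-driven agglomerative fuzzy clustering algorithm that
    reconstructs an (possibly overlapping) functional hierarchy from a flat
    bag of genes. Includes Heidke, Peirce and Gerrity skill scores for
    comparing predicted subtrees with reference modules, seeded synthetic
    generators for taxonomies and planted modular gene sets, and readers and
    writers for OBO, GAF 2.x, GMT, Newick and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, graphics, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
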