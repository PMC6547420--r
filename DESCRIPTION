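Package: iesbound
Title: Boundary Analysis of Programmed DNA Deletions and Their Flanking
    Inverted Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of internal eliminated
    sequence (IES) boundaries in ciliates such as Tetrahymena
    thermophila. Refines deletion breakpoints from split-read (clipped
    read) evidence, normalizes junction microhomology, catalogues
    deletion forms into loci across strains, quantifies boundary
    variation, discovers flanking inverted-repeat regulatory sequences
    by positional concentricity of k-mer pairs, scans flanks with
    position weight matrices for G-rich and C-rich inverted repeats,
    and contrasts wild-type against boundary-control mutants. Includes
    a fully deterministic synthetic micronuclear-genome simulator with
    planted deletions, motifs and truth tables so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
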