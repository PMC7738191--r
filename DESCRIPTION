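Package: streamgenome
Title: Genome Architecture, Intron Evolution and Gene-Family Dynamics for
    Streamlined Arthropod Genomes
Version: 0.1.0
Authors@R:
    person("streamgenome", "developers", email = "dev@streamgenome.org",
           role = c("aut", "cre"))
Description: Tools for quantifying genome streamlining from standard
    annotation files. Partitions an assembly into coding, intronic and
    intergenic fractions from GFF3 coding-sequence coordinates, computes
    intron statistics (intronless-gene percentage, intron lengths, phases
    and 5'-bias of intron positions), projects intron sites onto protein
    multiple alignments and infers intron gains and losses on a species
    tree under Dollo parsimony, classifies intron-loss events as precise
    or imprecise, applies orthogroup count-matrix filters (birth-death
    input preparation, lineage mini-expansions, conserved-orthogroup
    absences, single-copy selection, essential-gene overlap), screens for
    horizontal gene transfer with the h-index bitscore statistic, and
    summarizes transposable-element coverage from RepeatMasker output.
    A fully seeded synthetic-data generator with machine-readable truth
    ledgers makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
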