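# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures.

# annotation from a compact gene spec list:
# list(list(id, scaffold, strand, starts, ends), ...)
make_annotation <- function(genes, scaffolds = NULL) {
  reps <- lapply(genes, function(g)
    streamgenome:::new_transcript(paste0(g$id, ".t1"), g$id, g$scaffold,
                                  g$strand, g$starts, g$ends))
  names(reps) <- vapply(genes, `[[`, character(1), "id")
  streamgenome:::build_annotation(reps, scaffolds)
}

make_transcript <- function(id = "t1", gene = "g1", scaffold = "s1",
                            strand = "+", starts, ends) {
  streamgenome:::new_transcript(id, gene, scaffold, strand, starts, ends)
}

# write a GFF3 file from raw lines (prepends the version pragma)
write_gff_lines <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# an aligned orthogroup from aligned strings and per-species intron specs
# given as list(species = data.frame(c_upstream, phase))
make_cluster <- function(alignment, introns = list(), id = "cl1") {
  anns <- lapply(names(alignment), function(sp) {
    a <- introns[[sp]]
    if (is.null(a))
      return(data.frame(c_upstream = integer(), phase = integer(),
                        residue_index = integer()))
    data.frame(c_upstream = a$c_upstream, phase = a$phase,
               residue_index = a$c_upstream %/% 3L)
  })
  names(anns) <- names(alignment)
  streamgenome:::new_aligned_orthogroup(id, alignment, anns)
}

# random orthogroup count matrix for filter property tests
random_og_matrix <- function(seed, n_og = 12L, n_sp = 6L) {
  set.seed(seed)
  m <- matrix(rpois(n_og * n_sp, 1.5), n_og, n_sp,
              dimnames = list(sprintf("OG%03d", seq_len(n_og)),
                              paste0("sp", seq_len(n_sp))))
  # sprinkle occasional large families
  m[sample(length(m), 2L)] <- sample(90:120, 2L)
  m
}
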