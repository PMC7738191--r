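sc1k <- data.frame(id = "s1", length = 1000L)

test_that("merge_cds_union merges overlapping and book-ended segments", {
  ann <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 10L, ends = 20L),
    list(id = "g2", scaffold = "s1", strand = "-", starts = 15L, ends = 30L)))
  expect_equal(merge_cds_union(ann)[, c("start", "end")],
               data.frame(start = 10L, end = 30L))
  annb <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 10L, ends = 20L),
    list(id = "g2", scaffold = "s1", strand = "+", starts = 21L, ends = 30L)))
  expect_equal(merge_cds_union(annb)[, c("start", "end")],
               data.frame(start = 10L, end = 30L))
  annc <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 10L, ends = 20L),
    list(id = "g2", scaffold = "s1", strand = "+", starts = 25L, ends = 30L)))
  u <- merge_cds_union(annc)
  expect_equal(u$end - u$start + 1L, c(11L, 6L))
})

test_that("partition_genome classifies single-gene and nested-gene layouts", {
  ann <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 11L, ends = 40L)),
    sc1k)
  ann$scaffolds$length <- 100L
  p <- partition_genome(ann)
  expect_equal(c(p$coding_bp, p$intronic_bp, p$intergenic_bp),
               c(30, 0, 70))
  # gene C nested inside gene A's intron: its CDS is coding, the rest of
  # the intron intronic; expected counts from the per-base oracle
  ann2 <- make_annotation(list(
    list(id = "gA", scaffold = "s1", strand = "+",
         starts = c(101L, 201L), ends = c(160L, 260L)),
    list(id = "gB", scaffold = "s1", strand = "+", starts = 301L, ends = 400L),
    list(id = "gC", scaffold = "s1", strand = "+", starts = 171L, ends = 185L)),
    sc1k)
  p2 <- partition_genome(ann2)
  o <- oracle_partition(ann2, sc1k)
  expect_equal(p2$coding_bp, o$coding_bp)
  expect_equal(p2$intronic_bp, o$intronic_bp)
  expect_equal(p2$intergenic_bp, o$intergenic_bp)
  expect_equal(p2$coding_bp, 60 + 60 + 100 + 15)
  expect_equal(p2$intronic_bp, 40 - 15)
  expect_equal(p2$total_bp,
               p2$coding_bp + p2$intronic_bp + p2$intergenic_bp)
  expect_error(partition_genome(ann2, scaffolds = NULL), "scaffold lengths")
})

test_that("extract_cds_introns computes ordinal, c_upstream and phase per strand", {
  plus <- make_transcript(strand = "+", starts = c(101L, 201L),
                          ends = c(160L, 260L))
  ip <- extract_cds_introns(plus)
  expect_equal(ip[, c("start", "end", "length", "ordinal", "c_upstream", "phase")],
               data.frame(start = 161L, end = 200L, length = 40L,
                          ordinal = 1L, c_upstream = 60L, phase = 0L))
  minus <- make_transcript(strand = "-", starts = c(101L, 201L),
                           ends = c(160L, 260L))
  im <- extract_cds_introns(minus)
  expect_equal(im$start, 161L)  # same genomic intron
  expect_equal(im$c_upstream, 60L)  # counted from the 201-260 segment
  expect_equal(extract_cds_introns(make_transcript(starts = 1L, ends = 300L)),
               extract_cds_introns(make_transcript(starts = 5L, ends = 304L)))
  expect_equal(nrow(extract_cds_introns(make_transcript(starts = 1L, ends = 300L))), 0L)
})

test_that("minus-strand c_upstream equals an explicit splice-and-count", {
  # three segments, traverse 3'->5' genomically: upstream coding bp before
  # each gap equals the summed lengths of segments to its right
  tx <- make_transcript(strand = "-", starts = c(1L, 101L, 301L),
                        ends = c(50L, 200L, 360L))
  introns <- extract_cds_introns(tx)
  expect_equal(introns$c_upstream[introns$ordinal == 1L], 60L)
  expect_equal(introns$c_upstream[introns$ordinal == 2L], 160L)
  expect_equal(introns$phase, introns$c_upstream %% 3L)
})

test_that("intergenic gaps clamp overlaps and skip terminal stretches", {
  ann <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 1L, ends = 100L),
    list(id = "g2", scaffold = "s1", strand = "+", starts = 201L, ends = 300L)))
  expect_equal(intergenic_gaps(ann), 100L)
  ov <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 1L, ends = 100L),
    list(id = "g2", scaffold = "s1", strand = "+", starts = 50L, ends = 150L)))
  expect_equal(intergenic_gaps(ov), 0L)
  expect_equal(intergenic_gaps(ov, clamp = FALSE), integer(0))
  single <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 5L, ends = 50L)))
  expect_equal(length(intergenic_gaps(single)), 0L)
})

test_that("architecture_summary counts intronless genes and medians", {
  ann <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 11L, ends = 40L),
    list(id = "g2", scaffold = "s1", strand = "+", starts = 101L, ends = 190L),
    list(id = "g3", scaffold = "s1", strand = "-", starts = 301L, ends = 390L),
    list(id = "g4", scaffold = "s1", strand = "+",
         starts = c(501L, 601L), ends = c(560L, 660L))), sc1k)
  s <- architecture_summary(ann)
  expect_equal(s$pct_intronless, 75)
  expect_equal(s$n_cds_introns, 1L)
  expect_equal(s$median_intron_length, 40)
  expect_error(architecture_summary(make_annotation(list(), sc1k)), "no genes")
})

test_that("medians equal sort-based brute force on generated genomes", {
  for (seed in c(2, 5, 9)) {
    g <- generate_genome(genome_sim_config(seed = seed, n_genes = 40))
    s <- architecture_summary(g$annotation)
    gaps <- intergenic_gaps(g$annotation)
    brute_median <- function(x) {
      x <- sort(x); n <- length(x)
      if (n %% 2L == 1L) x[(n + 1L) / 2L] else mean(x[n / 2L + c(0L, 1L)])
    }
    expect_equal(s$median_intergenic_gap, brute_median(gaps))
    introns <- cds_intron_table(g$annotation)
    expect_equal(s$median_intron_length, brute_median(introns$length))
  }
})

test_that("relative intron positions measure 5' bias", {
  ann <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+",
         starts = c(1L, 131L), ends = c(30L, 400L))), sc1k)
  prof <- relative_intron_positions(ann)
  expect_equal(prof$r, 0.1)  # 30 coding nt of 300 upstream
  expect_equal(sum(prof$histogram), 1L)
  expect_error(relative_intron_positions(make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 1L, ends = 30L)),
    sc1k)), "no CDS introns")
})

test_that("r is invariant under full coordinate reflection", {
  # reflect all coordinates through the scaffold and flip strands: the
  # spliced CDS is traversed identically, so each intron keeps its r
  L <- 1000L
  fwd <- make_transcript(strand = "+", starts = c(101L, 201L, 401L),
                         ends = c(160L, 260L, 520L))
  rev <- make_transcript(strand = "-",
                         starts = rev(L + 1L - c(160L, 260L, 520L)),
                         ends = rev(L + 1L - c(101L, 201L, 401L)))
  rf <- extract_cds_introns(fwd)
  rr <- extract_cds_introns(rev)
  expect_equal(sort(rf$c_upstream), sort(rr$c_upstream))
  expect_equal(rf$length[order(rf$ordinal)], rr$length[order(rr$ordinal)])
})

test_that("partition is strand-invariant and conserves total length", {
  g <- generate_genome(genome_sim_config(seed = 21, n_genes = 35))
  p <- partition_genome(g$annotation)
  expect_equal(p$coding_bp + p$intronic_bp + p$intergenic_bp,
               sum(g$scaffolds$length))
  flipped <- g$annotation
  flipped$genes$strand <- ifelse(flipped$genes$strand == "+", "-", "+")
  flipped$cds$strand <- ifelse(flipped$cds$strand == "+", "-", "+")
  pf <- partition_genome(flipped)
  expect_equal(pf$coding_bp, p$coding_bp)
  expect_equal(pf$intronic_bp, p$intronic_bp)
})

test_that("inserting a gene-free stretch grows only the intergenic count", {
  ann <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 11L, ends = 100L),
    list(id = "g2", scaffold = "s1", strand = "+",
         starts = c(301L, 401L), ends = c(360L, 460L))), sc1k)
  p0 <- partition_genome(ann)
  shift <- 250L  # insert 250 gene-free bp between the genes
  ann2 <- make_annotation(list(
    list(id = "g1", scaffold = "s1", strand = "+", starts = 11L, ends = 100L),
    list(id = "g2", scaffold = "s1", strand = "+",
         starts = c(301L, 401L) + shift, ends = c(360L, 460L) + shift)),
    data.frame(id = "s1", length = 1000L + shift))
  p1 <- partition_genome(ann2)
  expect_equal(p1$coding_bp, p0$coding_bp)
  expect_equal(p1$intronic_bp, p0$intronic_bp)
  expect_equal(p1$intergenic_bp, p0$intergenic_bp + shift)
})
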