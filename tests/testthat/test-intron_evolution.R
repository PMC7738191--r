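tree5 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
tree4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("annotate_protein_introns converts to protein coordinates", {
  # intron after 3 coding nt: phase 0, before residue 1
  t1 <- make_transcript(starts = c(1L, 104L), ends = c(3L, 400L))
  a1 <- annotate_protein_introns(t1)
  expect_equal(a1[1, ], data.frame(c_upstream = 3L, phase = 0L,
                                   residue_index = 1L),
               ignore_attr = TRUE)
  expect_equal(attr(a1, "protein_length"), 100L)
  # intron after 4 coding nt: phase 1, interrupts residue 1
  t2 <- make_transcript(starts = c(1L, 105L), ends = c(4L, 400L))
  a2 <- annotate_protein_introns(t2)
  expect_equal(a2$phase, 1L)
  expect_equal(a2$residue_index, 1L)
  # splice-and-count: introns after 60 and 150 nt of a 300-nt CDS
  t3 <- make_transcript(starts = c(1L, 101L, 301L),
                        ends = c(60L, 190L, 450L))
  a3 <- annotate_protein_introns(t3)
  expect_equal(a3$c_upstream, c(60L, 150L))
  expect_equal(a3$phase, c(0L, 0L))
  expect_equal(a3$residue_index, c(20L, 50L))
  # coding length not divisible by 3 rejected unless tolerated
  t4 <- make_transcript(starts = 1L, ends = 100L)
  expect_error(annotate_protein_introns(t4), "not divisible by 3")
  expect_silent(annotate_protein_introns(t4, allow_partial_codon = TRUE))
})

test_that("project_sites maps residues to columns and merges shared sites", {
  # two ungapped identical-length sequences, introns at residue 5 phase 0
  cl <- make_cluster(
    c(A = "MKLVITPQRS", B = "MKLVITPQRS"),
    list(A = list(c_upstream = 15L, phase = 0L),
         B = list(c_upstream = 15L, phase = 0L)))
  tab <- project_sites(cl)
  expect_equal(nrow(tab$sites), 1L)
  expect_equal(tab$sites$column, 6L)  # residue index 5 -> column 6
  expect_equal(unname(tab$states[, 1]), c("present", "present"))

  # a 2-residue insertion in B before its residue 5 puts B's site two
  # columns left of A's homologous-looking coordinate: two distinct sites
  cl2 <- make_cluster(
    c(A = "MKLVI--TPQRS", B = "MKLVIXYTPQRS"),
    list(A = list(c_upstream = 15L, phase = 0L),
         B = list(c_upstream = 15L, phase = 0L)))
  tab2 <- project_sites(cl2)
  expect_equal(nrow(tab2$sites), 2L)
  expect_equal(tab2$sites$column, c(6L, 8L))
  expect_equal(unname(tab2$states["A", ]), c("absent", "present"))
  expect_equal(unname(tab2$states["B", ]), c("present", "absent"))

  # same column, different phases: two distinct sites
  cl3 <- make_cluster(
    c(A = "MKLVITPQRS", B = "MKLVITPQRS"),
    list(A = list(c_upstream = 15L, phase = 0L),
         B = list(c_upstream = 16L, phase = 1L)))
  expect_equal(nrow(project_sites(cl3)$sites), 2L)

  # species in the roster without a sequence are ambiguous everywhere
  tab4 <- project_sites(cl, roster = c("A", "B", "Z"))
  expect_equal(unname(tab4$states["Z", ]), "ambiguous")
})

test_that("projection is invertible for every annotated site", {
  h <- generate_intron_history(tree5, n_sites = 40, seed = 13,
                               per_branch_loss_prob = 0.3,
                               indel_sites = c(5L, 20L),
                               indel_species = c("A", "D"))
  cl <- h$cluster
  tab <- project_sites(cl)
  for (sp in names(cl$alignment)) {
    cols <- streamgenome:::residue_columns(cl$alignment[[sp]])
    a <- cl$annotations[[sp]]
    for (i in seq_len(nrow(a))) {
      col <- cols[a$residue_index[i] + 1L]
      # map the column back to a residue index: count non-gaps before it
      back <- sum(cols <= col) - 1L
      expect_identical(back, a$residue_index[i])
    }
  }
})

test_that("filter_unambiguous applies the flank rule per species", {
  # site at column 6; A has only 4 residues left of it (one gap)
  cl <- make_cluster(
    c(A = "M-LVITPQRSXX", B = "MKLVITPQRSXX", C = "MKLVITPQRSXX"),
    list(B = list(c_upstream = 15L, phase = 0L),
         C = list(c_upstream = 15L, phase = 0L)))
  tab <- project_sites(cl)
  kept <- filter_unambiguous(tab, cl, focal = "A", min_flank = 5L,
                             min_other_species = 2L)
  expect_equal(nrow(kept$sites), 0L)
  # with a clean focal row the site survives and A is called absent
  cl2 <- make_cluster(
    c(A = "MKLVITPQRSXX", B = "MKLVITPQRSXX", C = "MKLVITPQRSXX"),
    list(B = list(c_upstream = 15L, phase = 0L),
         C = list(c_upstream = 15L, phase = 0L)))
  tab2 <- project_sites(cl2)
  kept2 <- filter_unambiguous(tab2, cl2, focal = "A", min_flank = 5L,
                              min_other_species = 2L)
  expect_equal(nrow(kept2$sites), 1L)
  expect_equal(unname(kept2$states["A", 1]), "absent")
  # permissive settings retain everything
  all_kept <- filter_unambiguous(tab, cl, focal = "A", min_flank = 0L,
                                 min_other_species = 1L)
  expect_equal(nrow(all_kept$sites), 1L)
})

test_that("filter_unambiguous is monotone in both thresholds", {
  h <- generate_intron_history(tree5, n_sites = 30, seed = 5,
                               per_branch_loss_prob = 0.3,
                               indel_sites = c(3L, 11L, 25L),
                               indel_species = c("B", "C", "E"))
  tab <- project_sites(h$cluster)
  n_kept <- function(flank, others)
    nrow(filter_unambiguous(tab, h$cluster, "A", flank, others)$sites)
  for (f in 0:3)
    expect_gte(n_kept(f, 1L), n_kept(f + 1L, 1L))
  for (k in 1:3)
    expect_gte(n_kept(2L, k), n_kept(2L, k + 1L))
})

test_that("select_clusters applies the three membership criteria", {
  roster <- c("focal", paste0("sp", 1:15))
  m <- matrix(1L, nrow = 3, ncol = 16,
              dimnames = list(c("ok", "too_few", "too_many"), roster))
  m["too_few", 4:16] <- 0L              # only 2 other species
  m["too_many", "sp3"] <- 4L            # a species above max_copies
  expect_equal(select_clusters(m, "focal"), "ok")
  expect_equal(select_clusters(m, "focal", min_other_species = 2L), c("ok", "too_few"))
  expect_error(select_clusters(m, "nope"), "not in roster")
})

test_that("dollo_events places single gains and minimal losses", {
  states <- function(...) {
    v <- c(...)
    tab <- list(cluster_id = "t", sites = data.frame(column = 6L, phase = 0L),
                states = matrix(v, ncol = 1, dimnames = list(names(v), NULL)),
                roster = names(v))
    structure(tab, class = "intron_site_table")
  }
  # present everywhere: one gain at the root, no losses
  ev <- dollo_events(states(A = "present", B = "present", C = "present",
                            D = "present"), tree4)
  root <- ape::Ntip(tree4) + 1L
  expect_equal(ev$branches$gains[root], 1L)
  expect_equal(sum(ev$branches$losses), 0L)
  # A=1 B=0 C=1 D=0: gain at root, losses on the B and D branches
  ev2 <- dollo_events(states(A = "present", B = "absent", C = "present",
                             D = "absent"), tree4)
  expect_equal(ev2$branches$gains[root], 1L)
  b <- match(c("B", "D"), tree4$tip.label)
  expect_equal(ev2$branches$losses[b], c(1L, 1L))
  expect_equal(sum(ev2$branches$losses), 2L)
  # A=1 B=1 C=0 D=0: gain at MRCA(A,B), no losses
  ev3 <- dollo_events(states(A = "present", B = "present", C = "absent",
                             D = "absent"), tree4)
  mrca <- ape::getMRCA(tree4, c("A", "B"))
  expect_equal(ev3$branches$gains[mrca], 1L)
  expect_equal(sum(ev3$branches$losses), 0L)
  # ambiguous leaves never force a loss
  ev4 <- dollo_events(states(A = "present", B = "ambiguous", C = "present",
                             D = "ambiguous"), tree4)
  expect_equal(sum(ev4$branches$losses), 0L)
  expect_error(dollo_events(states(A = "present", B = "absent",
                                   C = "absent", D = "absent"),
                            ape::unroot(tree5)), "rooted")
})

test_that("presence_histogram counts sites by presence and is order-stable", {
  st <- matrix(c("present", "present", "absent",
                 "present", "present", "absent",
                 "present", "present", "present",
                 "absent", "present", "present",
                 "absent", "present", "present"),
               nrow = 5, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  tab <- structure(list(cluster_id = "t",
                        sites = data.frame(column = c(6L, 12L, 18L),
                                           phase = c(0L, 0L, 0L)),
                        states = st, roster = rownames(st)),
                   class = "intron_site_table")
  h <- presence_histogram(tab)
  expect_equal(sum(h), 3L)
  expect_equal(unname(h[c("3", "5")]), c(2L, 1L))
  perm <- sample(rownames(st))
  tab2 <- tab; tab2$states <- st[perm, ]; tab2$roster <- perm
  expect_equal(presence_histogram(tab2), h)
})

test_that("classify_loss_precision separates flush and indel-bearing losses", {
  h <- generate_intron_history(tree5, n_sites = 12, seed = 31,
                               per_branch_loss_prob = 0.35,
                               indel_sites = integer())
  tab <- project_sites(h$cluster)
  # find a site absent in A but present elsewhere: gap-free alignment,
  # so the loss must classify as precise
  absent_in_A <- which(tab$states["A", ] == "absent" &
                         colSums(tab$states == "present") >= 1L)
  if (length(absent_in_A)) {
    cls <- classify_loss_precision(h$cluster, tab, absent_in_A[1L], "A")
    expect_equal(cls$verdict, "precise")
    expect_equal(cls$indel_residues, 0L)
  }
  # plant a 2-residue insertion in A at a site it lost
  h2 <- generate_intron_history(tree5, n_sites = 12, seed = 31,
                                per_branch_loss_prob = 0.35)
  tab2 <- project_sites(h2$cluster)
  k <- which(tab2$states["A", ] == "absent" &
               colSums(tab2$states == "present") >= 1L)[1L]
  expect_false(is.na(k))
  h3 <- generate_intron_history(tree5, n_sites = 12, seed = 31,
                                per_branch_loss_prob = 0.35,
                                indel_sites = k, indel_species = "A",
                                indel_len = 2L)
  tab3 <- project_sites(h3$cluster)
  cls3 <- classify_loss_precision(h3$cluster, tab3, k, "A")
  expect_equal(cls3$verdict, "imprecise")
  expect_equal(cls3$indel_residues, 2L)
  expect_error(classify_loss_precision(h3$cluster, tab3,
                                       which(tab3$states["A", ] == "present")[1L],
                                       "A"),
               "carries the intron")
})

test_that("intron-annotated FASTA round-trips through the header dialect", {
  h <- generate_intron_history(tree5, n_sites = 15, seed = 2,
                               per_branch_loss_prob = 0.3)
  path <- tempfile(fileext = ".fa")
  write_intron_fasta(h$cluster, path)
  back <- read_intron_fasta(path, cluster_id = h$cluster$cluster_id)
  expect_equal(back$alignment, h$cluster$alignment)
  for (sp in names(h$cluster$annotations))
    expect_equal(back$annotations[[sp]], h$cluster$annotations[[sp]],
                 ignore_attr = TRUE)
})
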