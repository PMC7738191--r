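# Independent brute-force oracles. These deliberately use the dumbest
# possible algorithms (per-base labeling, exhaustive enumeration, set
# comprehensions) and never call the implementation paths they check.

# per-base genome partition: label every base, priority coding > intronic
# > intergenic
oracle_partition <- function(annotation, scaffolds) {
  coding <- intronic <- intergenic <- 0
  for (i in seq_len(nrow(scaffolds))) {
    sc <- scaffolds$id[i]
    lab <- rep("intergenic", scaffolds$length[i])
    g <- annotation$genes[annotation$genes$scaffold_id == sc, , drop = FALSE]
    for (j in seq_len(nrow(g)))
      lab[g$span_start[j]:g$span_end[j]] <- "intronic"
    cds <- annotation$cds[annotation$cds$scaffold_id == sc, , drop = FALSE]
    for (j in seq_len(nrow(cds)))
      lab[cds$start[j]:cds$end[j]] <- "coding"
    coding <- coding + sum(lab == "coding")
    intronic <- intronic + sum(lab == "intronic")
    intergenic <- intergenic + sum(lab == "intergenic")
  }
  list(coding_bp = coding, intronic_bp = intronic, intergenic_bp = intergenic)
}

# Exhaustive single-gain / minimum-loss search: enumerate all binary state
# assignments to internal nodes and ambiguous tips; keep those with exactly
# one gain (a 0->1 edge, or state 1 at the root) and return the minimum
# number of 1->0 edges.
oracle_dollo_min_losses <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  fixed <- rep(NA_integer_, nn)
  for (i in seq_len(ntip)) {
    s <- states[[tree$tip.label[i]]]
    if (s == "present") fixed[i] <- 1L
    if (s == "absent") fixed[i] <- 0L
  }
  free <- which(is.na(fixed))
  k <- length(free)
  n_assign <- 2L^k
  M <- matrix(rep(fixed, each = n_assign), nrow = n_assign)
  if (k > 0) {
    bits <- sapply(seq_len(k), function(j)
      bitwAnd(seq_len(n_assign) - 1L, bitwShiftL(1L, j - 1L)) > 0L)
    M[, free] <- bits + 0L
  }
  P <- tree$edge[, 1L]
  C <- tree$edge[, 2L]
  gains <- rowSums(M[, P, drop = FALSE] == 0L & M[, C, drop = FALSE] == 1L) +
    M[, root]
  losses <- rowSums(M[, P, drop = FALSE] == 1L & M[, C, drop = FALSE] == 0L)
  valid <- gains == 1L
  if (!any(valid)) stop("no single-gain assignment exists")
  min(losses[valid])
}

# random rooted tree with n tips labelled sp1..spn
random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  t <- ape::rtree(n, rooted = TRUE, tip.label = paste0("sp", seq_len(n)))
  t
}

# one-line set-comprehension oracles for the orthogroup filters
oracle_cafe <- function(m, min_species = 10L, large_cutoff = 100L) {
  retained <- rownames(m)[sapply(rownames(m), function(og)
    sum(m[og, ] >= 1) >= min_species)]
  if (length(retained) == 0L)
    return(list(retained = retained, small = retained, large = retained))
  list(retained = retained,
       small = retained[sapply(retained, function(og) all(m[og, ] < large_cutoff))],
       large = retained[sapply(retained, function(og) any(m[og, ] >= large_cutoff))])
}
oracle_mini <- function(m, focal, relatives, min_members = 5L, fold = 2)
  rownames(m)[sapply(rownames(m), function(og)
    m[og, focal] > min_members && m[og, focal] >= fold * mean(m[og, relatives]))]
oracle_absent <- function(m, focal, required)
  rownames(m)[sapply(rownames(m), function(og)
    m[og, focal] == 0 && all(m[og, required] >= 1))]
oracle_single <- function(m)
  rownames(m)[sapply(rownames(m), function(og) all(m[og, ] == 1))]
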