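# Orthogroup count-matrix filters: input preparation for birth-death gene
# family analysis, lineage mini-expansion detection, conserved-orthogroup
# absence counting, single-copy selection and essential-gene overlap.
# The matrix layout follows OrthoFinder's Orthogroups.GeneCount table:
# rows = orthogroups (rownames = ids), columns = species, integer counts.

#' Read an orthogroup count matrix from a tab-separated file
#'
#' First column = orthogroup id, remaining columns = per-species counts
#' (header row of species names); compatible with OrthoFinder's
#' Orthogroups.GeneCount layout (a trailing "Total" column is dropped).
#'
#' @param path Tab-separated file path.
#' @return Integer matrix with orthogroup rownames and species colnames.
#' @export
read_orthogroup_matrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                  check.names = FALSE)
  d <- d[, colnames(d) != "Total", drop = FALSE]
  m <- as.matrix(d)
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("negative counts in orthogroup matrix")
  m
}

#' Prepare orthogroup sets for birth-death (CAFE-style) analysis
#'
#' Retains orthogroups present (count >= 1) in at least `min_species`
#' species, then splits them into "small" orthogroups (< `large_cutoff`
#' copies in every species) and "large" ones (>= `large_cutoff` copies in
#' at least one species), which a birth-death analysis treats separately.
#'
#' @param matrix Orthogroup count matrix.
#' @param min_species Minimum number of species with >= 1 member
#'   (default 10).
#' @param large_cutoff Copy-number cutoff separating small from large
#'   orthogroups (default 100).
#' @return List with character vectors `retained`, `small`, `large`
#'   (small and large partition retained).
#' @export
cafe_prepare <- function(matrix, min_species = 10L, large_cutoff = 100L) {
  m <- as.matrix(matrix)
  if (min_species > ncol(m))
    stop("min_species exceeds the number of species in the matrix")
  retained <- rownames(m)[rowSums(m >= 1L) >= min_species]
  mx <- apply(m[retained, , drop = FALSE], 1L, max)
  list(retained = retained,
       small = retained[mx < large_cutoff],
       large = retained[mx >= large_cutoff])
}

#' Detect lineage-specific orthogroup mini-expansions
#'
#' Flags orthogroups where the focal species has more than `min_members`
#' members and at least `fold` times the average member count of two close
#' relatives.
#'
#' @param matrix Orthogroup count matrix.
#' @param focal Focal species column name.
#' @param relatives Character vector of two relative species.
#' @param min_members Focal count must exceed this (strict; default 5).
#' @param fold Required ratio over the relatives' mean (inclusive;
#'   default 2).
#' @return Character vector of orthogroup ids, in input order.
#' @export
mini_expansions <- function(matrix, focal, relatives, min_members = 5L,
                            fold = 2) {
  m <- as.matrix(matrix)
  if (focal %in% relatives) stop("relatives must not include the focal species")
  stopifnot(all(c(focal, relatives) %in% colnames(m)))
  rel_mean <- rowMeans(m[, relatives, drop = FALSE])
  keep <- m[, focal] > min_members & m[, focal] >= fold * rel_mean
  rownames(m)[keep]
}

#' Orthogroups absent from the focal species but conserved elsewhere
#'
#' @param matrix Orthogroup count matrix.
#' @param focal Focal species.
#' @param required Species that must each have >= 1 member (excluding the
#'   focal species).
#' @return Character vector of orthogroup ids.
#' @export
absent_conserved <- function(matrix, focal, required) {
  m <- as.matrix(matrix)
  if (length(required) == 0L) stop("required species set is empty")
  if (focal %in% required) stop("required set must not include the focal species")
  stopifnot(all(c(focal, required) %in% colnames(m)))
  keep <- m[, focal] == 0L &
    rowSums(m[, required, drop = FALSE] >= 1L) == length(required)
  rownames(m)[keep]
}

#' Orthogroups with exactly one member in every species
#'
#' @param matrix Orthogroup count matrix.
#' @return Character vector of orthogroup ids.
#' @export
single_copy <- function(matrix) {
  m <- as.matrix(matrix)
  rownames(m)[rowSums(m == 1L) == ncol(m)]
}

#' Overlap of essential genes with orthogroups and clade absences
#'
#' Maps a list of essential genes (e.g. from a model organism) onto
#' orthogroups and counts how many of the hit orthogroups are absent from
#' an entire clade, and how many are absent from the focal species only
#' (present in every other clade species). Unmapped genes are skipped with
#' a message.
#'
#' @param matrix Orthogroup count matrix.
#' @param gene_to_og data.frame with columns `gene` and `orthogroup`.
#' @param essential_genes Character vector of essential gene ids.
#' @param clade Species set forming the clade of interest (must include
#'   `focal`).
#' @param focal Focal species.
#' @return List with `n_essential_ogs`, `n_absent_in_clade`,
#'   `n_absent_in_focal_only`, and the corresponding orthogroup id vectors
#'   `essential_ogs`, `absent_in_clade`, `absent_in_focal_only`.
#' @export
essential_overlap <- function(matrix, gene_to_og, essential_genes, clade,
                              focal) {
  m <- as.matrix(matrix)
  stopifnot(all(clade %in% colnames(m)), focal %in% clade)
  hit <- gene_to_og[gene_to_og$gene %in% essential_genes, , drop = FALSE]
  unmapped <- setdiff(essential_genes, gene_to_og$gene)
  if (length(unmapped))
    message(length(unmapped), " essential gene(s) without an orthogroup ",
            "mapping were skipped")
  ogs <- intersect(unique(hit$orthogroup), rownames(m))
  sub <- m[ogs, clade, drop = FALSE]
  absent_clade <- ogs[rowSums(sub >= 1L) == 0L]
  others <- setdiff(clade, focal)
  absent_focal <- ogs[m[ogs, focal] == 0L &
                        rowSums(m[ogs, others, drop = FALSE] >= 1L) ==
                          length(others)]
  list(n_essential_ogs = length(ogs),
       n_absent_in_clade = length(absent_clade),
       n_absent_in_focal_only = length(absent_focal),
       essential_ogs = ogs,
       absent_in_clade = absent_clade,
       absent_in_focal_only = absent_focal)
}
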