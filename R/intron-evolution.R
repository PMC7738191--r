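# Intron evolution across orthologous protein alignments.
#
# Intron coordinates follow one convention throughout: c_upstream counts
# coding nucleotides 5' of the exon/exon junction in transcription
# direction, phase = c_upstream mod 3, and the 0-based residue index is
# s = floor(c_upstream / 3). A phase-0 intron sits before residue s; a
# phase-1/2 intron interrupts residue s's codon. A site in an alignment is
# identified by the pair (alignment column of residue s, phase); a phase-0
# and a phase-1 intron at one column are distinct sites.

#' Protein-coordinate intron annotation of a transcript
#'
#' Converts each CDS intron of a transcript into protein coordinates:
#' upstream coding nucleotides `c_upstream`, `phase`, and 0-based residue
#' index `residue_index = floor(c_upstream / 3)`.
#'
#' @param transcript A transcript model.
#' @param allow_partial_codon Tolerate a coding length not divisible by 3
#'   (trailing partial codon); otherwise an error.
#' @return data.frame with columns `c_upstream`, `phase`, `residue_index`,
#'   in transcription order, with attribute `protein_length`.
#' @export
annotate_protein_introns <- function(transcript, allow_partial_codon = FALSE) {
  introns <- extract_cds_introns(transcript)
  clen <- transcript_cds_length(transcript)
  if (clen %% 3L != 0L && !allow_partial_codon)
    stop("coding length ", clen, " of transcript '", transcript$id,
         "' is not divisible by 3")
  if (nrow(introns)) {
    if (any(introns$c_upstream <= 0L | introns$c_upstream >= clen))
      stop("invalid intron placement in transcript '", transcript$id,
           "': c_upstream must lie strictly inside the coding sequence")
  }
  introns <- introns[order(introns$ordinal), , drop = FALSE]
  out <- data.frame(c_upstream = introns$c_upstream,
                    phase = introns$phase,
                    residue_index = introns$c_upstream %/% 3L)
  attr(out, "protein_length") <- clen %/% 3L
  out
}

#' Read an intron-annotated aligned orthogroup from FASTA
#'
#' Headers use the dialect `>name|i:c,p;c,p;...` where `name` identifies the
#' species (one retained sequence per species), `c` is the upstream coding
#' nucleotide count and `p` the phase of each intron. A header without an
#' `|i:` block denotes a sequence with no annotated introns.
#'
#' @param path Aligned multi-FASTA file (gap character `-`).
#' @param cluster_id Cluster identifier; defaults to the file name.
#' @return An `aligned_orthogroup`: list with `cluster_id`, `alignment`
#'   (named character vector of aligned sequences), and `annotations`
#'   (named list of data.frames with `c_upstream`, `phase`,
#'   `residue_index`).
#' @export
read_intron_fasta <- function(path, cluster_id = basename(path)) {
  aln <- Biostrings::readAAStringSet(path)
  headers <- names(aln)
  seqs <- as.character(aln)
  species <- sub("\\|.*$", "", headers)
  if (anyDuplicated(species))
    stop("more than one sequence per species in cluster '", cluster_id, "'")
  anns <- lapply(headers, function(h) {
    m <- regmatches(h, regexpr("\\|i:[0-9,;]+", h))
    if (length(m) == 0L)
      return(data.frame(c_upstream = integer(), phase = integer(),
                        residue_index = integer()))
    pairs <- strsplit(strsplit(sub("^\\|i:", "", m), ";", fixed = TRUE)[[1]],
                      ",", fixed = TRUE)
    c_up <- as.integer(vapply(pairs, `[`, character(1), 1L))
    p <- as.integer(vapply(pairs, `[`, character(1), 2L))
    stopifnot(all(p == c_up %% 3L))
    data.frame(c_upstream = c_up, phase = p, residue_index = c_up %/% 3L)
  })
  names(seqs) <- species
  names(anns) <- species
  new_aligned_orthogroup(cluster_id, seqs, anns)
}

new_aligned_orthogroup <- function(cluster_id, alignment, annotations) {
  stopifnot(length(unique(nchar(alignment))) == 1L,
            all(names(annotations) %in% names(alignment)))
  res_len <- nchar(gsub("-", "", alignment, fixed = TRUE))
  for (sp in names(annotations)) {
    a <- annotations[[sp]]
    if (nrow(a) && any(a$residue_index >= res_len[[sp]]))
      stop("intron residue_index beyond degapped length for '", sp, "'")
  }
  structure(list(cluster_id = cluster_id, alignment = alignment,
                 annotations = annotations), class = "aligned_orthogroup")
}

# column index of each residue (0-based residue index -> 1-based column)
residue_columns <- function(aligned_seq) {
  which(strsplit(aligned_seq, "", fixed = TRUE)[[1]] != "-")
}

#' Project per-sequence intron annotations onto alignment columns
#'
#' Each annotated intron maps its residue index to the alignment column of
#' that residue (counting non-gap positions). Introns sharing (column,
#' phase) across sequences merge into one site. Species in `roster` without
#' a sequence in the cluster are ambiguous at every site; species with a
#' sequence but no intron at a site are absent there.
#'
#' @param cluster An `aligned_orthogroup`.
#' @param roster Character vector of species; defaults to the cluster's
#'   sequence names.
#' @return An `intron_site_table`: list with `cluster_id`, `sites`
#'   (data.frame of `column`, `phase`, sorted), `states` (species x site
#'   matrix of "present"/"absent"/"ambiguous") and `roster`.
#' @export
project_sites <- function(cluster, roster = names(cluster$alignment)) {
  cols <- lapply(cluster$alignment, residue_columns)
  persec <- lapply(names(cluster$annotations), function(sp) {
    a <- cluster$annotations[[sp]]
    if (nrow(a) == 0L) return(NULL)
    cc <- cols[[sp]]
    if (any(a$residue_index + 1L > length(cc)))
      stop("residue index beyond degapped length for '", sp, "'")
    data.frame(species = sp, column = cc[a$residue_index + 1L],
               phase = a$phase)
  })
  persec <- do.call(rbind, persec)
  if (is.null(persec)) {
    sites <- data.frame(column = integer(), phase = integer())
    states <- matrix(character(), nrow = length(roster), ncol = 0,
                     dimnames = list(roster, NULL))
  } else {
    sites <- unique(persec[, c("column", "phase")])
    sites <- sites[order(sites$column, sites$phase), , drop = FALSE]
    rownames(sites) <- NULL
    states <- matrix("ambiguous", nrow = length(roster), ncol = nrow(sites),
                     dimnames = list(roster, NULL))
    in_cluster <- intersect(roster, names(cluster$alignment))
    states[in_cluster, ] <- "absent"
    key <- paste(sites$column, sites$phase)
    idx <- match(paste(persec$column, persec$phase), key)
    states[cbind(match(persec$species, roster), idx)] <- "present"
  }
  structure(list(cluster_id = cluster$cluster_id, sites = sites,
                 states = states, roster = roster),
            class = "intron_site_table")
}

# Does species sp satisfy the flank rule at a site column: the min_flank
# alignment columns on each side (and the site column itself) are non-gap
# in its row. min_flank = 0 only requires the site column to exist.
flank_ok <- function(chars, column, min_flank) {
  L <- length(chars)
  lo <- column - min_flank
  hi <- column + min_flank
  if (lo < 1L || hi > L) return(FALSE)
  all(chars[lo:hi] != "-")
}

#' Filter an intron-site table to unambiguous sites
#'
#' A species is unambiguous at a site when its sequence has `min_flank`
#' aligned (non-gap) residues in the alignment columns immediately on both
#' sides of the site column, and the site column itself is non-gap.
#' Retained sites are those where the focal species and at least
#' `min_other_species` other species are unambiguous; species failing the
#' flank rule at a retained site are marked ambiguous there.
#'
#' @param table An `intron_site_table`.
#' @param cluster The `aligned_orthogroup` the table was projected from
#'   (needed for flank checking).
#' @param focal Focal species name.
#' @param min_flank Required non-gap residues on each side (default 5).
#' @param min_other_species Required unambiguous non-focal species
#'   (default 11).
#' @return A filtered `intron_site_table`.
#' @export
filter_unambiguous <- function(table, cluster, focal, min_flank = 5L,
                               min_other_species = 11L) {
  if (!focal %in% table$roster) stop("focal species not in roster: ", focal)
  chars <- lapply(cluster$alignment, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  n_sites <- nrow(table$sites)
  keep <- logical(n_sites)
  states <- table$states
  for (j in seq_len(n_sites)) {
    col <- table$sites$column[j]
    ok <- vapply(table$roster, function(sp) {
      if (!sp %in% names(chars)) return(FALSE)
      flank_ok(chars[[sp]], col, min_flank)
    }, logical(1))
    states[!ok, j] <- "ambiguous"
    keep[j] <- ok[[focal]] && sum(ok[setdiff(table$roster, focal)]) >= min_other_species
  }
  keep <- keep & colSums(states == "present") >= 1L
  structure(list(cluster_id = table$cluster_id,
                 sites = table$sites[keep, , drop = FALSE],
                 states = states[, keep, drop = FALSE],
                 roster = table$roster),
            class = "intron_site_table")
}

#' Select orthologous clusters for intron analysis
#'
#' Keeps orthogroups with at least one member in the focal species,
#' members in at least `min_other_species` other species, and no species
#' exceeding `max_copies` members.
#'
#' @param matrix Orthogroup count matrix (rows = orthogroups, columns =
#'   species; rownames are orthogroup ids).
#' @param focal Focal species (column name).
#' @param min_other_species Minimum non-focal species with >= 1 member
#'   (default 14).
#' @param max_copies Maximum members per species (default 3).
#' @return Character vector of orthogroup ids, in input order.
#' @export
select_clusters <- function(matrix, focal, min_other_species = 14L,
                            max_copies = 3L) {
  m <- as.matrix(matrix)
  if (!focal %in% colnames(m)) stop("focal species not in roster: ", focal)
  others <- m[, setdiff(colnames(m), focal), drop = FALSE]
  keep <- m[, focal] >= 1L &
    rowSums(others >= 1L) >= min_other_species &
    apply(m, 1L, max) <= max_copies
  rownames(m)[keep]
}

#' Histogram of intron sites by number of species carrying the intron
#'
#' @param table An `intron_site_table` (or a list of them, pooled).
#' @return Named integer vector: counts of sites indexed by the number of
#'   species with state "present" (1 .. roster size).
#' @export
presence_histogram <- function(table) {
  tables <- if (inherits(table, "intron_site_table")) list(table) else table
  n_sp <- length(tables[[1]]$roster)
  counts <- unlist(lapply(tables, function(t)
    colSums(t$states == "present")), use.names = FALSE)
  if (length(counts) == 0L) stop("no sites in table")
  setNames(tabulate(counts, nbins = n_sp), seq_len(n_sp))
}

# --- Dollo parsimony -------------------------------------------------------

# children list indexed by node for an ape phylo tree
phylo_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

# Minimal-loss Dollo reconstruction for one site.
# states: named vector over tip labels with values present/absent/ambiguous.
# Returns list(gain = node id, losses = child-node ids of loss branches).
# The gain is placed at the MRCA of all present tips (single origin); within
# that subtree, a postorder sweep labels each node P (some present tip
# below, forced), A (only absent/ambiguous below, with >= 1 absent) or F
# (only ambiguous below). A loss is charged to each A child of a P node:
# ambiguous tips take whichever state avoids a loss, and a clade that is
# entirely absent is lost once on its stem.
dollo_site <- function(tree, states, children = phylo_children(tree)) {
  tips <- tree$tip.label
  pres <- which(tips %in% names(states)[states == "present"])
  if (length(pres) == 0L) stop("site has no present species")
  gain <- if (length(pres) == 1L) pres else ape::getMRCA(tree, pres)
  st <- character(ape::Ntip(tree) + tree$Nnode)
  losses <- integer(0)
  label <- function(v) {
    if (v <= length(tips)) {
      # tips outside the roster are treated as ambiguous
      s <- if (tips[v] %in% names(states)) states[[tips[v]]] else "ambiguous"
      st[v] <<- switch(s, present = "P", absent = "A", ambiguous = "F")
      return(st[v])
    }
    cs <- vapply(children[[v]], label, character(1))
    st[v] <<- if (any(cs == "P")) "P" else if (any(cs == "A")) "A" else "F"
    if (st[v] == "P")
      losses <<- c(losses, children[[v]][cs == "A"])
    st[v]
  }
  label(gain)
  list(gain = gain, losses = losses)
}

#' Infer intron gains and losses on a species tree by Dollo parsimony
#'
#' Each intron site is assumed to have a single evolutionary origin, placed
#' at the most recent common ancestor of all species carrying the intron;
#' losses are then placed on the minimum number of branches consistent with
#' the observed states. Ambiguous species never force a loss.
#'
#' @param table An `intron_site_table`, or a list of them (tallies summed).
#' @param tree A rooted `phylo` tree whose tip labels cover the roster.
#' @return A `dollo_events` object: list with `tree` and `branches`, a
#'   data.frame with one row per branch (`node` = child node id, `label`
#'   = tip label or internal node number, `gains`, `losses`), plus a root
#'   row for gains at the root.
#' @export
dollo_events <- function(table, tree) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  tables <- if (inherits(table, "intron_site_table")) list(table) else table
  roster <- tables[[1]]$roster
  if (!all(roster %in% tree$tip.label))
    stop("tree tips do not cover the species roster")
  children <- phylo_children(tree)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  gains <- losses <- integer(n_nodes)
  for (t in tables) {
    for (j in seq_len(nrow(t$sites))) {
      ev <- dollo_site(tree, t$states[, j], children)
      gains[ev$gain] <- gains[ev$gain] + 1L
      losses[ev$losses] <- losses[ev$losses] + 1L
    }
  }
  labels <- c(tree$tip.label,
              paste0("node", seq_len(tree$Nnode) + ape::Ntip(tree)))
  structure(list(tree = tree,
                 branches = data.frame(node = seq_len(n_nodes),
                                       label = labels,
                                       gains = gains, losses = losses)),
            class = "dollo_events")
}

#' @export
print.dollo_events <- function(x, ...) {
  cat("Dollo parsimony events:", sum(x$branches$gains), "gain(s),",
      sum(x$branches$losses), "loss(es)\n")
  print(x$branches[x$branches$gains + x$branches$losses > 0, ])
  invisible(x)
}

#' Classify an intron loss in the focal species as precise or imprecise
#'
#' Inspects the alignment within `window` columns of the site. A column is
#' discordant when the focal sequence has a residue where at least half of
#' the intron-bearing sequences have gaps, or a gap where at least half
#' have residues. The loss is precise iff no column is discordant.
#'
#' @param cluster An `aligned_orthogroup`.
#' @param table The cluster's `intron_site_table`.
#' @param site_index Index of the site (column of `table$states`).
#' @param focal Focal species; must be absent at the site while at least
#'   one other species is present.
#' @param window Columns inspected on each side of the site (default 5).
#' @return A `loss_classification`: list with `cluster_id`, `column`,
#'   `phase`, `focal`, `verdict` ("precise"/"imprecise") and
#'   `indel_residues` (number of discordant columns).
#' @export
classify_loss_precision <- function(cluster, table, site_index, focal,
                                    window = 5L) {
  st <- table$states[, site_index]
  if (st[[focal]] == "present")
    stop("focal species carries the intron at this site; nothing to classify")
  bearers <- names(st)[st == "present"]
  if (length(bearers) == 0L) stop("no species carries the intron at this site")
  col <- table$sites$column[site_index]
  chars <- lapply(cluster$alignment, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  L <- length(chars[[focal]])
  cols <- max(1L, col - window):min(L, col + window)
  fgap <- chars[[focal]][cols] == "-"
  bgap <- vapply(bearers, function(sp) chars[[sp]][cols] == "-",
                 logical(length(cols)))
  bgap <- matrix(bgap, nrow = length(cols))
  frac_gap <- rowMeans(bgap)
  discordant <- (!fgap & frac_gap >= 0.5) | (fgap & (1 - frac_gap) >= 0.5)
  n <- sum(discordant)
  structure(list(cluster_id = cluster$cluster_id, column = col,
                 phase = table$sites$phase[site_index], focal = focal,
                 verdict = if (n == 0L) "precise" else "imprecise",
                 indel_residues = n),
            class = "loss_classification")
}
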