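# Synthetic-data generators. Every generator takes an explicit seed, is
# byte-deterministic given its config, and returns a machine-readable
# truth ledger whose quantities are derivable again from the emitted
# files by the corresponding pipeline stage. Sequence content is
# arbitrary (uniform nucleotides/residues): no pipeline stage inspects
# composition.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic genome generator
#'
#' Defaults mimic a streamlined mite-like genome: ~84% intronless genes,
#' log-normal intron lengths with median 170 bp, log-normal intergenic
#' gaps with median ~540 bp, occasional genes nested inside another
#' gene's intron, and an even strand mixture.
#'
#' @param seed Integer seed for all randomness.
#' @param n_scaffolds,scaffold_length Number and size (bp) of scaffolds.
#' @param n_genes Total genes to place.
#' @param intronless_fraction Fraction of genes with a single CDS segment;
#'   the planted count is `round(intronless_fraction * n_genes)`, exact.
#' @param introns_per_gene_prob Geometric parameter; intron-bearing genes
#'   get `1 + rgeom(prob)` introns.
#' @param intron_length_meanlog,intron_length_sdlog Log-normal intron
#'   length parameters (median `exp(meanlog)`).
#' @param exon_length_meanlog,exon_length_sdlog Log-normal CDS exon length
#'   parameters.
#' @param intergenic_gap_meanlog,intergenic_gap_sdlog Log-normal
#'   intergenic gap parameters.
#' @param nested_gene_probability Probability that an eligible intronless
#'   gene is placed inside the previous gene's largest intron.
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @return A `genome_sim_config` list.
#' @export
genome_sim_config <- function(seed = 1L, n_scaffolds = 2L,
                              scaffold_length = 50000L, n_genes = 50L,
                              intronless_fraction = 0.837,
                              introns_per_gene_prob = 0.5,
                              intron_length_meanlog = log(170),
                              intron_length_sdlog = 0.6,
                              exon_length_meanlog = log(350),
                              exon_length_sdlog = 0.4,
                              intergenic_gap_meanlog = log(538),
                              intergenic_gap_sdlog = 0.8,
                              nested_gene_probability = 0.05,
                              minus_strand_fraction = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$intronless_fraction >= 0, cfg$intronless_fraction <= 1,
            cfg$scaffold_length > 0, cfg$n_scaffolds >= 1)
  structure(cfg, class = "genome_sim_config")
}

# random positive length from a log-normal, rounded, floored
rlen <- function(n, meanlog, sdlog, min_len) {
  pmax(min_len, as.integer(round(rlnorm(n, meanlog, sdlog))))
}

# Build one transcript's exon/intron layout (lengths only). Total CDS
# length is padded to a multiple of 3.
sim_gene_structure <- function(cfg, intronless) {
  n_introns <- if (intronless) 0L else 1L + rgeom(1L, cfg$introns_per_gene_prob)
  exons <- rlen(n_introns + 1L, cfg$exon_length_meanlog, cfg$exon_length_sdlog, 30L)
  pad <- (3L - sum(exons) %% 3L) %% 3L
  exons[length(exons)] <- exons[length(exons)] + pad
  introns <- if (n_introns > 0L)
    rlen(n_introns, cfg$intron_length_meanlog, cfg$intron_length_sdlog, 20L)
  else integer(0)
  list(exons = exons, introns = introns)
}

# genomic CDS segments for a structure starting at `start`
structure_segments <- function(start, str) {
  starts <- ends <- integer(length(str$exons))
  pos <- start
  for (i in seq_along(str$exons)) {
    starts[i] <- pos
    ends[i] <- pos + str$exons[i] - 1L
    pos <- ends[i] + 1L + if (i <= length(str$introns)) str$introns[i] else 0L
  }
  list(starts = starts, ends = ends)
}

#' Generate a synthetic genome annotation with a truth ledger
#'
#' Places genes left to right on each scaffold with sampled intergenic
#' gaps; eligible intronless genes may be nested inside the previous
#' gene's largest intron. The ledger's expected genome partition is
#' computed with an independent per-base labeling of every scaffold, and
#' expected medians come directly from the planted structures.
#'
#' @param config A [genome_sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa` and
#'   `genome.gff3`.
#' @return List with `annotation` (a `genome_annotation`), `scaffolds`,
#'   `ledger` (planted per-gene table, exact expected partition counts,
#'   expected medians, intronless count) and, with `out_dir`, `paths`.
#' @export
generate_genome <- function(config = genome_sim_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  n_intronless <- as.integer(round(cfg$intronless_fraction * cfg$n_genes))
  intronless <- sample(rep(c(TRUE, FALSE),
                           c(n_intronless, cfg$n_genes - n_intronless)))
  scaffolds <- data.frame(id = sprintf("scf%02d", seq_len(cfg$n_scaffolds)),
                          length = rep(cfg$scaffold_length, cfg$n_scaffolds))
  reps <- list()
  gene_rows <- list()
  sc_idx <- 1L
  pos <- 1L
  prev <- NULL  # previous non-nested gene (for nesting): list(segments, scaffold)
  i <- 1L
  while (i <= cfg$n_genes) {
    gid <- sprintf("g%04d", i)
    strand <- if (runif(1L) < cfg$minus_strand_fraction) "-" else "+"
    nested <- FALSE
    if (intronless[i] && !is.null(prev) &&
        runif(1L) < cfg$nested_gene_probability) {
      # try to nest inside the previous gene's largest intron
      seg <- prev$segments
      if (length(seg$starts) > 1L) {
        istarts <- seg$ends[-length(seg$ends)] + 1L
        iends <- seg$starts[-1L] - 1L
        h <- which.max(iends - istarts)
        room <- iends[h] - istarts[h] + 1L - 2L  # 1 bp margin each side
        if (room >= 33L) {
          len <- min(room, rlen(1L, cfg$exon_length_meanlog,
                                cfg$exon_length_sdlog, 30L))
          len <- len - len %% 3L
          gstart <- istarts[h] + 1L
          tx <- new_transcript(paste0(gid, ".t1"), gid, prev$scaffold,
                               strand, gstart, gstart + len - 1L)
          reps[[gid]] <- tx
          gene_rows[[gid]] <- data.frame(
            gene_id = gid, scaffold_id = prev$scaffold, strand = strand,
            intronless = TRUE, nested = TRUE, n_introns = 0L,
            coding_length = len)
          nested <- TRUE
        }
      }
    }
    if (!nested) {
      str <- sim_gene_structure(cfg, intronless[i])
      gap <- rlen(1L, cfg$intergenic_gap_meanlog, cfg$intergenic_gap_sdlog, 1L)
      gstart <- pos + gap
      glen <- sum(str$exons) + sum(str$introns)
      if (gstart + glen - 1L > cfg$scaffold_length) {
        sc_idx <- sc_idx + 1L
        if (sc_idx > cfg$n_scaffolds)
          stop("infeasible placement: scaffold capacity exhausted after ",
               i - 1L, " genes (expected gene footprint exceeds assembly)")
        pos <- 1L
        prev <- NULL
        next
      }
      seg <- structure_segments(gstart, str)
      tx <- new_transcript(paste0(gid, ".t1"), gid, scaffolds$id[sc_idx],
                           strand, seg$starts, seg$ends)
      reps[[gid]] <- tx
      gene_rows[[gid]] <- data.frame(
        gene_id = gid, scaffold_id = scaffolds$id[sc_idx], strand = strand,
        intronless = intronless[i], nested = FALSE,
        n_introns = length(str$introns), coding_length = sum(str$exons))
      prev <- list(segments = seg, scaffold = scaffolds$id[sc_idx])
      pos <- gstart + glen
    }
    i <- i + 1L
  }
  annotation <- build_annotation(reps, scaffolds)
  ledger <- genome_truth_ledger(annotation, scaffolds, do.call(rbind, gene_rows))
  out <- list(annotation = annotation, scaffolds = scaffolds, ledger = ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    gff <- file.path(out_dir, "genome.gff3")
    seqs <- Biostrings::DNAStringSet(vapply(scaffolds$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)))
    names(seqs) <- scaffolds$id
    Biostrings::writeXStringSet(seqs, fa)
    write_gff3(annotation, gff)
    out$paths <- list(fasta = fa, gff3 = gff)
  }
  out
}

# Independent per-base truth: label every base of every scaffold by brute
# force (coding > intronic > intergenic) and collect planted statistics.
genome_truth_ledger <- function(annotation, scaffolds, gene_table) {
  if (is.null(gene_table))
    gene_table <- data.frame(gene_id = character(), scaffold_id = character(),
                             strand = character(), intronless = logical(),
                             nested = logical(), n_introns = integer(),
                             coding_length = integer())
  coding <- intronic <- 0
  for (i in seq_len(nrow(scaffolds))) {
    sc <- scaffolds$id[i]
    lab <- integer(scaffolds$length[i])  # 0 intergenic, 1 intronic, 2 coding
    g <- annotation$genes[annotation$genes$scaffold_id == sc, , drop = FALSE]
    for (j in seq_len(nrow(g)))
      lab[g$span_start[j]:g$span_end[j]] <- 1L
    cds <- annotation$cds[annotation$cds$scaffold_id == sc, , drop = FALSE]
    for (j in seq_len(nrow(cds)))
      lab[cds$start[j]:cds$end[j]] <- 2L
    coding <- coding + sum(lab == 2L)
    intronic <- intronic + sum(lab == 1L)
  }
  total <- sum(as.numeric(scaffolds$length))
  # planted intron lengths and intergenic gaps, straight from placements
  intron_lengths <- unlist(lapply(gene_table$gene_id, function(gid) {
    seg <- annotation$cds[annotation$cds$gene_id == gid, , drop = FALSE]
    if (nrow(seg) < 2L) return(integer(0))
    seg$start[-1L] - seg$end[-nrow(seg)] - 1L
  }), use.names = FALSE)
  gaps <- unlist(lapply(split(annotation$genes, annotation$genes$scaffold_id),
                        function(d) {
    if (nrow(d) < 2L) return(integer(0))
    d <- d[order(d$span_start, d$span_end), , drop = FALSE]
    pmax(d$span_start[-1L] - d$span_end[-nrow(d)] - 1L, 0L)
  }), use.names = FALSE)
  list(genes = gene_table,
       n_genes = nrow(gene_table),
       n_intronless = sum(gene_table$intronless),
       expected_pct_intronless = if (nrow(gene_table))
         100 * sum(gene_table$intronless) / nrow(gene_table) else NA_real_,
       expected_partition = list(coding_bp = coding, intronic_bp = intronic,
                                 intergenic_bp = total - coding - intronic,
                                 total_bp = total),
       expected_n_cds_introns = length(intron_lengths),
       expected_median_intron_length = if (length(intron_lengths))
         median(intron_lengths) else NA_real_,
       expected_median_intergenic_gap = if (length(gaps)) median(gaps)
       else NA_real_)
}

#' Write an aligned orthogroup with intron-annotated headers to FASTA
#'
#' Headers use the `>name|i:c,p;...` dialect read by
#' [read_intron_fasta()].
#'
#' @param cluster An `aligned_orthogroup`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_intron_fasta <- function(cluster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in names(cluster$alignment)) {
    a <- cluster$annotations[[sp]]
    hdr <- if (!is.null(a) && nrow(a))
      paste0(sp, "|i:", paste(a$c_upstream, a$phase, sep = ",",
                              collapse = ";"))
    else sp
    writeLines(c(paste0(">", hdr), cluster$alignment[[sp]]), con)
  }
  invisible(path)
}

#' Simulate intron presence/absence histories on a species tree
#'
#' Each site originates exactly once on a uniformly sampled branch and is
#' then lost independently along each descendant branch with probability
#' `per_branch_loss_prob` (a loss silences the whole subtree, so there is
#' at most one event per branch per site). With `canonical = TRUE`
#' (default) sites are resampled until the simulated history is the
#' unique minimum-loss single-origin explanation of the leaf pattern, so
#' Dollo parsimony recovers the ledger exactly. The emitted alignment is
#' gap-free unless indels are planted for loss-precision tests.
#'
#' @param tree Rooted `phylo` species tree.
#' @param n_sites Number of intron sites.
#' @param per_branch_loss_prob Per-branch loss probability (scalar).
#' @param seed Integer seed.
#' @param spacing Alignment columns between consecutive sites (>= 6 keeps
#'   5-residue flanks intact).
#' @param indel_sites,indel_species Optional parallel vectors planting an
#'   insertion of `indel_len` residues in `indel_species` immediately
#'   after the given site's column (all other species gapped there).
#' @param indel_len Inserted residues per planted indel (default 2).
#' @param canonical Resample non-parsimony-identifiable histories
#'   (default TRUE).
#' @param cluster_id Cluster identifier.
#' @param out_file Optional FASTA output path.
#' @return List with `cluster` (an `aligned_orthogroup` covering all
#'   tree tips), `tree`, and `ledger`: per-site origins, phases, loss
#'   branches and presence matrix, plus per-branch `gains`/`losses`
#'   tallies indexed by child node.
#' @export
generate_intron_history <- function(tree, n_sites, per_branch_loss_prob = 0.25,
                                    seed = 1L, spacing = 12L,
                                    indel_sites = integer(),
                                    indel_species = character(),
                                    indel_len = 2L, canonical = TRUE,
                                    cluster_id = "sim_cluster",
                                    out_file = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  stopifnot(spacing >= 6L, per_branch_loss_prob >= 0,
            per_branch_loss_prob <= 1,
            length(indel_sites) == length(indel_species))
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  children <- phylo_children(tree)
  tips <- tree$tip.label
  site_cols <- spacing * seq_len(n_sites)
  L <- spacing * (n_sites + 1L)
  gains <- losses <- integer(nn)
  pres <- matrix(FALSE, ntip, n_sites, dimnames = list(tips, NULL))
  origins <- phases <- integer(n_sites)
  loss_events <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    accepted <- FALSE
    for (try in seq_len(1000L)) {
      origin <- sample.int(nn, 1L)
      present <- logical(nn)
      present[origin] <- TRUE
      lost <- integer(0)
      walk <- function(v) {
        for (ch in children[[v]]) {
          if (present[v]) {
            if (runif(1L) < per_branch_loss_prob) {
              lost <<- c(lost, ch)
            } else {
              present[ch] <<- TRUE
            }
          }
          walk(ch)
        }
      }
      walk(origin)
      pattern <- present[seq_len(ntip)]
      if (!any(pattern)) next
      if (canonical) {
        states <- setNames(ifelse(pattern, "present", "absent"), tips)
        rec <- dollo_site(tree, states, children)
        if (rec$gain != origin || !setequal(rec$losses, lost)) next
      }
      accepted <- TRUE
      break
    }
    if (!accepted)
      stop("could not sample a canonical history for site ", k,
           " in 1000 tries; lower per_branch_loss_prob")
    origins[k] <- origin
    phases[k] <- sample(0:2, 1L)
    loss_events[[k]] <- lost
    pres[, k] <- present[seq_len(ntip)]
    gains[origin] <- gains[origin] + 1L
    losses[lost] <- losses[lost] + 1L
  }
  # gap-free alignment plus per-species intron annotations
  chars <- lapply(tips, function(sp) sample(AA_ALPHABET, L, replace = TRUE))
  names(chars) <- tips
  annotations <- lapply(tips, function(sp) {
    kk <- which(pres[sp, ])
    s <- site_cols[kk] - 1L
    data.frame(c_upstream = 3L * s + phases[kk], phase = phases[kk],
               residue_index = s)
  })
  names(annotations) <- tips
  if (length(indel_sites)) {
    for (idx in order(-site_cols[indel_sites])) {
      k <- indel_sites[idx]
      sp <- indel_species[idx]
      col <- site_cols[k]
      ins <- sample(AA_ALPHABET, indel_len, replace = TRUE)
      for (s2 in tips) {
        piece <- if (s2 == sp) ins else rep("-", indel_len)
        chars[[s2]] <- append(chars[[s2]], piece, after = col)
      }
      a <- annotations[[sp]]
      shift <- a$residue_index >= col
      a$residue_index[shift] <- a$residue_index[shift] + indel_len
      a$c_upstream[shift] <- a$c_upstream[shift] + 3L * indel_len
      annotations[[sp]] <- a
    }
  }
  alignment <- vapply(chars, paste, character(1), collapse = "")
  cluster <- new_aligned_orthogroup(cluster_id, alignment, annotations)
  ledger <- list(
    sites = data.frame(site = seq_len(n_sites), origin = origins,
                       phase = phases,
                       n_present = colSums(pres)),
    presence = pres,
    loss_events = loss_events,
    branch = data.frame(node = seq_len(nn),
                        label = c(tips, paste0("node", ntip + seq_len(tree$Nnode))),
                        gains = gains, losses = losses),
    site_columns = site_cols)
  if (!is.null(out_file)) write_intron_fasta(cluster, out_file)
  list(cluster = cluster, tree = tree, ledger = ledger)
}

#' Generate a BLAST best-hit table with planted HGT candidates
#'
#' Planted queries exceed both screen thresholds (best non-metazoan
#' bitscore >= 75 + margin and h-index >= 30 + margin); background
#' queries violate at least one threshold by at least `margin`. A
#' fraction of background queries have no non-metazoan hit at all.
#'
#' @param n_queries Total queries.
#' @param n_planted Number of planted candidates.
#' @param margin Safety margin in bits (default 5).
#' @param seed Integer seed.
#' @param out_dir Optional directory; writes `hits.tsv` (12-column BLAST
#'   tabular with subjects `met|...` / `nonmet|...`) and
#'   `db_classes.tsv`.
#' @return List with `hits` (data.frame of tabular rows), `db_class`
#'   (named vector), `ledger` (per-query truth: planted flag, best
#'   scores, h) and, with `out_dir`, `paths`.
#' @export
generate_hgt_table <- function(n_queries, n_planted, margin = 5, seed = 1L,
                               out_dir = NULL) {
  stopifnot(n_planted <= n_queries, margin > 0)
  set.seed(seed)
  ids <- sprintf("q%04d", seq_len(n_queries))
  planted <- ids %in% sample(ids, n_planted)
  best_nonmet <- best_met <- numeric(n_queries)
  for (i in seq_len(n_queries)) {
    if (planted[i]) {
      best_nonmet[i] <- 75 + margin + round(runif(1L, 0, 60))
      met <- best_nonmet[i] - (30 + margin + round(runif(1L, 0, 30)))
      best_met[i] <- if (met > 0) met else NA_real_
    } else {
      mode <- sample(c("weak_nonmet", "low_h", "no_nonmet"), 1L,
                     prob = c(0.45, 0.45, 0.1))
      if (mode == "weak_nonmet") {
        best_nonmet[i] <- max(5, 75 - margin - round(runif(1L, 0, 40)))
        best_met[i] <- best_nonmet[i] + round(runif(1L, 0, 40))
      } else if (mode == "low_h") {
        best_nonmet[i] <- 75 + round(runif(1L, 0, 60))
        best_met[i] <- best_nonmet[i] - (30 - margin) + round(runif(1L, 0, 40))
      } else {
        best_nonmet[i] <- NA_real_
        best_met[i] <- 50 + round(runif(1L, 0, 100))
      }
    }
  }
  rows <- list()
  blast_row <- function(q, s, bits)
    data.frame(q = q, s = s, pident = 80, len = 100, mm = 10, go = 1,
               qs = 1, qe = 100, ss = 1, se = 100, ev = 1e-20, bits = bits)
  for (i in seq_len(n_queries)) {
    if (!is.na(best_met[i])) {
      rows[[length(rows) + 1L]] <- blast_row(ids[i], "met|s1", best_met[i])
      # a suboptimal hit exercises the per-class maximum
      rows[[length(rows) + 1L]] <-
        blast_row(ids[i], "met|s2", max(1, best_met[i] - round(runif(1L, 1, 20))))
    }
    if (!is.na(best_nonmet[i])) {
      rows[[length(rows) + 1L]] <- blast_row(ids[i], "nonmet|s1", best_nonmet[i])
      rows[[length(rows) + 1L]] <-
        blast_row(ids[i], "nonmet|s2",
                  max(1, best_nonmet[i] - round(runif(1L, 1, 20))))
    }
  }
  hits <- do.call(rbind, rows)
  db_class <- c(met = "metazoan", nonmet = "nonmetazoan")
  h <- ifelse(is.na(best_nonmet), NA_real_,
              best_nonmet - ifelse(is.na(best_met), 0, best_met))
  ledger <- data.frame(query_id = ids, planted = planted,
                       best_metazoan = best_met,
                       best_nonmetazoan = best_nonmet, h = h)
  out <- list(hits = hits, db_class = db_class, ledger = ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hp <- file.path(out_dir, "hits.tsv")
    dp <- file.path(out_dir, "db_classes.tsv")
    write.table(hits, hp, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(data.frame(db = names(db_class), class = unname(db_class)),
                dp, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    out$paths <- list(hits = hp, db_classes = dp)
  }
  out
}

#' Generate a RepeatMasker-style repeat landscape with known coverage
#'
#' Places repeat intervals left to right with small gaps until exactly
#' the target number of bases is masked. Some intervals are emitted as
#' two overlapping hits with different scores and classes, exercising
#' score-based overlap resolution; the ledger accounts each base to the
#' class of the higher-scoring hit.
#'
#' @param scaffolds Scaffold table (`id`, `length`).
#' @param target_coverage_pct Target masked percentage of the assembly
#'   (0 <= target < 100).
#' @param seed Integer seed.
#' @param classes Repeat class labels to sample from.
#' @param out_dir Optional directory; writes `repeats.out` in
#'   RepeatMasker .out layout.
#' @return List with `hits` (parsed-layout data.frame), `ledger` (exact
#'   `masked_bp`, `expected_pct`, per-class bp) and, with `out_dir`,
#'   `paths`.
#' @export
generate_repeat_landscape <- function(scaffolds, target_coverage_pct,
                                      seed = 1L,
                                      classes = c("DNA/TcMar", "LINE/L1",
                                                  "LTR/Gypsy", "Unknown"),
                                      out_dir = NULL) {
  stopifnot(target_coverage_pct >= 0, target_coverage_pct < 100)
  set.seed(seed)
  total <- sum(as.numeric(scaffolds$length))
  masked_target <- as.integer(round(target_coverage_pct / 100 * total))
  hits <- list()
  per_class <- setNames(numeric(length(classes)), classes)
  remaining <- masked_target
  hid <- 0L
  for (i in seq_len(nrow(scaffolds))) {
    if (remaining <= 0L) break
    L <- scaffolds$length[i]
    pos <- 1L
    while (remaining > 0L) {
      gap <- sample(1:50, 1L)
      len <- min(remaining, rlen(1L, log(300), 0.7, 30L))
      a <- pos + gap
      b <- a + len - 1L
      if (b > L) {
        # truncate to scaffold end if anything fits, else next scaffold
        if (a <= L) {
          b <- L
          len <- b - a + 1L
        } else break
      }
      hid <- hid + 1L
      cls <- sample(classes, 1L)
      if (len >= 60L && hid %% 4L == 0L) {
        # emit as an overlapping pair: high-scoring left hit wins the overlap
        cls2 <- sample(setdiff(classes, cls), 1L)
        m <- a + as.integer(floor(len * 0.6)) - 1L
        ov <- 10L
        hits[[length(hits) + 1L]] <- data.frame(
          sw_score = 1200, scaffold_id = scaffolds$id[i], start = a, end = m,
          strand = "+", repeat_id = sprintf("rep%04d", hid),
          repeat_class = cls, overlapped = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          sw_score = 500, scaffold_id = scaffolds$id[i], start = m - ov + 1L,
          end = b, strand = "+", repeat_id = sprintf("rep%04db", hid),
          repeat_class = cls2, overlapped = TRUE)
        per_class[cls] <- per_class[cls] + (m - a + 1L)
        per_class[cls2] <- per_class[cls2] + (b - m)
      } else {
        hits[[length(hits) + 1L]] <- data.frame(
          sw_score = round(runif(1L, 200, 2000)),
          scaffold_id = scaffolds$id[i], start = a, end = b, strand = "+",
          repeat_id = sprintf("rep%04d", hid), repeat_class = cls,
          overlapped = FALSE)
        per_class[cls] <- per_class[cls] + len
      }
      remaining <- remaining - len
      pos <- b + 1L
    }
  }
  if (remaining > 0L)
    stop("infeasible target coverage: assembly too small to mask ",
         masked_target, " bp with the sampled layout")
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sw_score = numeric(), scaffold_id = character(),
               start = integer(), end = integer(), strand = character(),
               repeat_id = character(), repeat_class = character(),
               overlapped = logical())
  ledger <- list(masked_bp = masked_target,
                 expected_pct = 100 * masked_target / total,
                 per_class_bp = per_class[per_class > 0],
                 assembly_bp = total)
  out <- list(hits = hits, ledger = ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "repeats.out")
    write_repeatmasker_out(hits, p)
    out$paths <- list(rm_out = p)
  }
  out
}

#' Write repeat hits in RepeatMasker .out layout
#'
#' @param hits data.frame in the layout of [parse_repeatmasker_out()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in queryatgc    matching             repeat              position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)       repeat               class/family     begin  end    (left)   ID",
    ""), con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf(
      "%6.0f  1.0  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d%s",
      hits$sw_score[i], hits$scaffold_id[i], hits$start[i], hits$end[i],
      hits$strand[i], hits$repeat_id[i], hits$repeat_class[i],
      hits$end[i] - hits$start[i] + 1L, i,
      if (isTRUE(hits$overlapped[i])) " *" else ""), con)
  }
  invisible(path)
}
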