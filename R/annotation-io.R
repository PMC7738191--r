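#' @importFrom stats median rbinom rgeom rlnorm runif setNames
#' @importFrom utils head tail read.table write.table
NULL

# Internal constructor for a transcript model: a list with id, gene_id,
# scaffold_id, strand, and a segments data.frame (start, end) sorted by start.
new_transcript <- function(id, gene_id, scaffold_id, strand, starts, ends) {
  o <- order(starts)
  list(id = id, gene_id = gene_id, scaffold_id = scaffold_id,
       strand = strand,
       segments = data.frame(start = starts[o], end = ends[o]))
}

validate_transcript <- function(tx) {
  seg <- tx$segments
  if (nrow(seg) == 0L || sum(seg$end - seg$start + 1L) <= 0L)
    stop("transcript '", tx$id, "' has no coding sequence")
  if (any(seg$start > seg$end))
    stop("transcript '", tx$id, "' has a CDS segment with start > end")
  if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
    stop("transcript '", tx$id, "' has overlapping CDS segments")
  if (!tx$strand %in% c("+", "-"))
    stop("transcript '", tx$id, "' has invalid strand '", tx$strand,
         "' (strand is required)")
  invisible(tx)
}

transcript_cds_length <- function(tx) sum(tx$segments$end - tx$segments$start + 1L)

#' Select the representative (longest-CDS) isoform of a gene
#'
#' Given all transcript models of one gene, returns the transcript with the
#' largest summed CDS length. Ties are broken by the lexicographically
#' smallest transcript id, so the choice is independent of input order.
#'
#' @param transcripts A list of transcript models (as produced internally by
#'   [read_gff3()]), all belonging to the same gene.
#' @return A single transcript model.
#' @export
select_longest_isoform <- function(transcripts) {
  if (length(transcripts) == 0L)
    stop("select_longest_isoform() requires at least one transcript")
  lens <- vapply(transcripts, transcript_cds_length, integer(1))
  ids <- vapply(transcripts, function(t) t$id, character(1))
  best <- which(lens == max(lens))
  transcripts[[best[order(ids[best])][1L]]]
}

#' Read scaffold lengths from a FASTA assembly
#'
#' @param path Path to a FASTA file with unique record ids.
#' @return A data.frame with columns `id` and `length` (residue counts).
#' @export
read_scaffold_lengths <- function(path) {
  lens <- Biostrings::fasta.seqlengths(path)
  if (length(lens) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(lens))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, length = unname(as.integer(lens)))
}

parse_gff3_attributes <- function(attr, keys = c("ID", "Parent")) {
  out <- lapply(strsplit(attr, ";", fixed = TRUE), function(parts) {
    kv <- strsplit(parts, "=", fixed = TRUE)
    keysv <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else NA_character_, character(1))
    setNames(vals, trimws(keysv))
  })
  res <- vapply(keys, function(k)
    vapply(out, function(x) if (k %in% names(x)) unname(x[[k]]) else NA_character_,
           character(1)),
    character(length(attr)))
  # vapply drops to a vector for single-line input
  if (is.null(dim(res)))
    res <- matrix(res, nrow = 1L, dimnames = list(NULL, keys))
  res
}

#' Read a GFF3 gene annotation into validated gene models
#'
#' Parses gene, mRNA/transcript and CDS features from a GFF3 file and builds
#' one gene model per protein-coding gene, keeping only the representative
#' (longest-CDS) isoform. Genes without any CDS-bearing transcript are
#' dropped with a warning. `##sequence-region` pragmas populate scaffold
#' lengths when `scaffolds` is not supplied. A CDS feature directly under a
#' gene (no mRNA level) is accepted as a single implicit transcript.
#'
#' @param path Path to a GFF3 file.
#' @param scaffolds Optional data.frame of scaffold `id`/`length` (e.g. from
#'   [read_scaffold_lengths()]). When supplied, every gene's scaffold must be
#'   present and all CDS must lie within the scaffold.
#' @return A `genome_annotation` object: a list with
#'   \describe{
#'     \item{genes}{data.frame of gene-level fields (gene_id, scaffold_id,
#'       strand, transcript_id, span_start, span_end, n_segments,
#'       coding_length)}
#'     \item{cds}{data.frame of representative CDS segments (gene_id,
#'       transcript_id, scaffold_id, strand, start, end)}
#'     \item{scaffolds}{scaffold table or NULL}
#'   }
#' @export
read_gff3 <- function(path, scaffolds = NULL) {
  lines <- readLines(path, warn = FALSE)
  seqregion <- NULL
  pr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(pr)) {
    f <- strsplit(trimws(pr), "\\s+")
    seqregion <- data.frame(
      id = vapply(f, `[`, character(1), 2L),
      length = as.integer(vapply(f, `[`, character(1), 4L)))
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L)
    return(build_annotation(list(), scaffolds %||% seqregion))
  f <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(f)
  if (any(nfield < 9L))
    stop("malformed GFF3 line ", lineno[which(nfield < 9L)[1L]],
         ": fewer than 9 tab-separated fields")
  feat <- data.frame(
    seqid  = vapply(f, `[`, character(1), 1L),
    type   = vapply(f, `[`, character(1), 3L),
    start  = suppressWarnings(as.integer(vapply(f, `[`, character(1), 4L))),
    end    = suppressWarnings(as.integer(vapply(f, `[`, character(1), 5L))),
    strand = vapply(f, `[`, character(1), 7L),
    attr   = vapply(f, `[`, character(1), 9L),
    line   = lineno)
  bad <- which(is.na(feat$start) | is.na(feat$end))
  if (length(bad))
    stop("malformed coordinate (non-integer) at GFF3 line ", feat$line[bad[1L]])
  bad <- which(feat$start > feat$end)
  if (length(bad))
    stop("malformed coordinate (start > end) at GFF3 line ", feat$line[bad[1L]])

  at <- parse_gff3_attributes(feat$attr)
  feat$ID <- at[, "ID"]; feat$Parent <- at[, "Parent"]

  is_gene <- feat$type == "gene"
  is_tx <- feat$type %in% c("mRNA", "transcript")
  is_cds <- feat$type == "CDS"
  gene_ids <- feat$ID[is_gene]
  tx2gene <- setNames(feat$Parent[is_tx], feat$ID[is_tx])

  cds <- feat[is_cds, , drop = FALSE]
  if (nrow(cds)) {
    if (anyNA(cds$Parent))
      stop("CDS without Parent attribute at GFF3 line ",
           cds$line[which(is.na(cds$Parent))[1L]])
    known <- cds$Parent %in% c(names(tx2gene), gene_ids)
    if (!all(known))
      stop("CDS references unknown Parent '", cds$Parent[!known][1L],
           "' at GFF3 line ", cds$line[!known][1L])
    if (any(!cds$strand %in% c("+", "-")))
      stop("CDS with strand '", cds$strand[!cds$strand %in% c("+", "-")][1L],
           "' at GFF3 line ",
           cds$line[!cds$strand %in% c("+", "-")][1L],
           " (strand is required)")
  }

  # group CDS rows into transcripts; a Parent that is a gene id forms an
  # implicit single transcript named after the gene
  genes <- list()
  if (nrow(cds)) {
    for (parent in unique(cds$Parent)) {
      rows <- cds[cds$Parent == parent, , drop = FALSE]
      gid <- if (parent %in% names(tx2gene)) tx2gene[[parent]] else parent
      if (length(unique(rows$seqid)) > 1L)
        stop("CDS of transcript '", parent, "' span multiple scaffolds")
      if (length(unique(rows$strand)) > 1L)
        stop("CDS of transcript '", parent, "' mix strands")
      tx <- new_transcript(parent, gid, rows$seqid[1L], rows$strand[1L],
                           rows$start, rows$end)
      validate_transcript(tx)
      genes[[gid]] <- c(genes[[gid]], list(tx))
    }
  }
  dropped <- setdiff(gene_ids, names(genes))
  if (length(dropped))
    warning(length(dropped), " gene(s) without CDS dropped: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  reps <- lapply(genes, select_longest_isoform)
  build_annotation(reps, scaffolds %||% seqregion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble a genome_annotation from a list of representative transcripts.
build_annotation <- function(reps, scaffolds = NULL) {
  if (length(reps)) {
    genes <- data.frame(
      gene_id = vapply(reps, function(t) t$gene_id, character(1)),
      scaffold_id = vapply(reps, function(t) t$scaffold_id, character(1)),
      strand = vapply(reps, function(t) t$strand, character(1)),
      transcript_id = vapply(reps, function(t) t$id, character(1)),
      span_start = vapply(reps, function(t) min(t$segments$start), integer(1)),
      span_end = vapply(reps, function(t) max(t$segments$end), integer(1)),
      n_segments = vapply(reps, function(t) nrow(t$segments), integer(1)),
      coding_length = vapply(reps, transcript_cds_length, integer(1)),
      row.names = NULL)
    cds <- do.call(rbind, lapply(reps, function(t)
      data.frame(gene_id = t$gene_id, transcript_id = t$id,
                 scaffold_id = t$scaffold_id, strand = t$strand,
                 start = t$segments$start, end = t$segments$end)))
    rownames(cds) <- NULL
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene ids in annotation")
  } else {
    genes <- data.frame(gene_id = character(), scaffold_id = character(),
                        strand = character(), transcript_id = character(),
                        span_start = integer(), span_end = integer(),
                        n_segments = integer(), coding_length = integer())
    cds <- data.frame(gene_id = character(), transcript_id = character(),
                      scaffold_id = character(), strand = character(),
                      start = integer(), end = integer())
  }
  ann <- structure(list(genes = genes, cds = cds, scaffolds = scaffolds),
                   class = "genome_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  sc <- ann$scaffolds
  if (!is.null(sc) && nrow(ann$genes)) {
    missing <- setdiff(unique(ann$genes$scaffold_id), sc$id)
    if (length(missing))
      stop("gene(s) on scaffold(s) absent from scaffold list: ",
           paste(missing, collapse = ", "))
    L <- setNames(sc$length, sc$id)
    if (any(ann$cds$end > L[ann$cds$scaffold_id]))
      stop("CDS segment extends beyond its scaffold end")
  }
  invisible(ann)
}

#' Extract one gene's representative transcript from an annotation
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @return A transcript model (list with id, gene_id, scaffold_id, strand,
#'   segments).
#' @export
get_transcript <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("no such gene: ", gene_id)
  seg <- annotation$cds[annotation$cds$gene_id == gene_id, , drop = FALSE]
  new_transcript(g$transcript_id, gene_id, g$scaffold_id, g$strand,
                 seg$start, seg$end)
}

#' Write a genome annotation back to GFF3
#'
#' Emits `##sequence-region` pragmas (when scaffold lengths are known) and
#' gene / mRNA / CDS features for every representative transcript, so that
#' re-reading with [read_gff3()] reproduces the annotation.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(annotation$scaffolds))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       annotation$scaffolds$id, annotation$scaffolds$length), con)
  g <- annotation$genes
  for (i in seq_len(nrow(g))) {
    seg <- annotation$cds[annotation$cds$gene_id == g$gene_id[i], , drop = FALSE]
    writeLines(c(
      sprintf("%s\tstreamgenome\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$scaffold_id[i], g$span_start[i], g$span_end[i], g$strand[i],
              g$gene_id[i]),
      sprintf("%s\tstreamgenome\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$scaffold_id[i], g$span_start[i], g$span_end[i], g$strand[i],
              g$transcript_id[i], g$gene_id[i]),
      sprintf("%s\tstreamgenome\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              seg$scaffold_id, seg$start, seg$end, seg$strand,
              g$transcript_id[i], g$transcript_id[i])), con)
  }
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "gene(s) on",
      length(unique(x$genes$scaffold_id)), "scaffold(s)\n")
  if (!is.null(x$scaffolds))
    cat("  assembly:", nrow(x$scaffolds), "scaffold(s),",
        sum(x$scaffolds$length), "bp\n")
  invisible(x)
}
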