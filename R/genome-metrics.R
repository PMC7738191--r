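# Genome architecture metrics: partition of an assembly into coding /
# intronic / intergenic fractions, CDS intron extraction with phase and
# ordinal, intergenic-gap and intron-length medians, and the 5'-bias
# profile of intron positions. All coordinates are GFF3-style 1-based
# inclusive; lengths are end - start + 1.

#' Merge representative CDS segments into a disjoint coding union
#'
#' Overlapping and book-ended CDS segments are merged per scaffold,
#' irrespective of strand, so no genomic base is counted twice.
#'
#' @param annotation A `genome_annotation`.
#' @return data.frame with columns `scaffold_id`, `start`, `end`; intervals
#'   sorted, pairwise disjoint and non-adjacent.
#' @export
merge_cds_union <- function(annotation) {
  cds <- annotation$cds
  if (nrow(cds) == 0L)
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer()))
  out <- lapply(split(cds, cds$scaffold_id), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(scaffold_id = d$scaffold_id[1L],
               start = IRanges::start(r), end = IRanges::end(r))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-scaffold IRanges of the CDS union and of gene spans
scaffold_ranges <- function(annotation) {
  cds <- split(annotation$cds, annotation$cds$scaffold_id)
  spans <- split(annotation$genes, annotation$genes$scaffold_id)
  list(
    cds = lapply(cds, function(d)
      IRanges::reduce(IRanges::IRanges(d$start, d$end))),
    span = lapply(spans, function(d)
      IRanges::reduce(IRanges::IRanges(d$span_start, d$span_end))))
}

#' Partition an assembly into coding, intronic and intergenic base counts
#'
#' Every base is classified with priority coding > intronic > intergenic:
#' coding if covered by the merged CDS union of representative isoforms;
#' otherwise intronic if inside any gene span (min CDS start to max CDS end
#' of the gene's representative — so the CDS of a gene nested inside
#' another gene's intron counts as coding, with the remaining intron bases
#' intronic); otherwise intergenic, including scaffold-terminal stretches.
#'
#' @param annotation A `genome_annotation`.
#' @param scaffolds data.frame of scaffold `id`/`length`; defaults to the
#'   annotation's own scaffold table.
#' @return A `genome_partition`: list with exact base counts `coding_bp`,
#'   `intronic_bp`, `intergenic_bp`, `total_bp` and percentages
#'   `coding_pct`, `intronic_pct`, `intergenic_pct`.
#' @export
partition_genome <- function(annotation, scaffolds = annotation$scaffolds) {
  if (is.null(scaffolds))
    stop("scaffold lengths are required to partition the genome")
  need <- unique(annotation$genes$scaffold_id)
  if (!all(need %in% scaffolds$id))
    stop("missing scaffold length for: ",
         paste(setdiff(need, scaffolds$id), collapse = ", "))
  rng <- scaffold_ranges(annotation)
  coding <- intronic <- 0
  for (sc in names(rng$cds)) {
    # the CDS union is a subset of the gene-span union (each CDS lies within
    # its own gene's span), so intronic = span bases not covered by CDS
    w_cds <- sum(IRanges::width(rng$cds[[sc]]))
    w_span <- sum(IRanges::width(rng$span[[sc]]))
    coding <- coding + w_cds
    intronic <- intronic + (w_span - w_cds)
  }
  total <- sum(as.numeric(scaffolds$length))
  intergenic <- total - coding - intronic
  structure(list(
    coding_bp = coding, intronic_bp = intronic, intergenic_bp = intergenic,
    total_bp = total,
    coding_pct = 100 * coding / total,
    intronic_pct = 100 * intronic / total,
    intergenic_pct = 100 * intergenic / total), class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(sprintf("genome partition of %.0f bp: coding %.2f%% | intronic %.2f%% | intergenic %.2f%%\n",
              x$total_bp, x$coding_pct, x$intronic_pct, x$intergenic_pct))
  invisible(x)
}

#' Extract CDS introns of one transcript
#'
#' One record per gap between consecutive CDS segments in genomic order.
#' Ordinal, upstream coding length and phase are computed in transcription
#' direction: minus-strand transcripts are traversed from the genomically
#' rightmost segment.
#'
#' @param transcript A transcript model (see [get_transcript()]).
#' @return data.frame with columns `gene_id`, `scaffold_id`, `start`, `end`,
#'   `length`, `ordinal`, `c_upstream`, `phase`.
#' @export
extract_cds_introns <- function(transcript) {
  validate_transcript(transcript)
  seg <- transcript$segments
  n <- nrow(seg)
  empty <- data.frame(gene_id = character(), scaffold_id = character(),
                      start = integer(), end = integer(), length = integer(),
                      ordinal = integer(), c_upstream = integer(),
                      phase = integer())
  if (n < 2L) return(empty)
  # genomic gaps between consecutive segments
  gstart <- seg$end[-n] + 1L
  gend <- seg$start[-1L] - 1L
  if (any(gend < gstart))
    stop("transcript '", transcript$id, "' has book-ended CDS segments; ",
         "zero-length introns are not valid")
  seglen <- seg$end - seg$start + 1L
  if (transcript$strand == "+") {
    c_up <- cumsum(seglen)[-n]
    ordn <- seq_len(n - 1L)
  } else {
    # transcription runs right to left: upstream coding bp for the gap after
    # (genomic) segment i is the total length of segments i+1..n
    c_up <- rev(cumsum(rev(seglen)))[-1L]
    ordn <- rev(seq_len(n - 1L))
  }
  data.frame(gene_id = transcript$gene_id,
             scaffold_id = transcript$scaffold_id,
             start = gstart, end = gend, length = gend - gstart + 1L,
             ordinal = ordn, c_upstream = c_up, phase = c_up %% 3L)
}

#' All CDS introns of an annotation
#'
#' @param annotation A `genome_annotation`.
#' @return A data.frame in the layout of [extract_cds_introns()], one row
#'   per intron across all genes, plus a `coding_length` column.
#' @export
cds_intron_table <- function(annotation) {
  multi <- annotation$genes$gene_id[annotation$genes$n_segments > 1L]
  clen <- setNames(annotation$genes$coding_length, annotation$genes$gene_id)
  rows <- lapply(multi, function(g)
    extract_cds_introns(get_transcript(annotation, g)))
  out <- if (length(rows)) do.call(rbind, rows) else
    extract_cds_introns(new_transcript("t", "g", "s", "+", 1L, 3L))
  out$coding_length <- as.integer(clen[out$gene_id])
  rownames(out) <- NULL
  out
}

#' Intergenic gap lengths between adjacent genes
#'
#' For each pair of genes adjacent by span start on a scaffold, the gap is
#' `next span_start - previous span_end - 1`, clamped at zero for
#' overlapping or nested genes. Scaffold-terminal stretches contribute no
#' gap.
#'
#' @param annotation A `genome_annotation`.
#' @param clamp If `FALSE`, overlapping pairs are excluded instead of
#'   contributing a zero-length gap.
#' @return Integer vector of gap lengths.
#' @export
intergenic_gaps <- function(annotation, clamp = TRUE) {
  g <- annotation$genes
  gaps <- unlist(lapply(split(g, g$scaffold_id), function(d) {
    if (nrow(d) < 2L) return(integer())
    d <- d[order(d$span_start, d$span_end), , drop = FALSE]
    d$span_start[-1L] - d$span_end[-nrow(d)] - 1L
  }), use.names = FALSE)
  if (clamp) pmax(gaps, 0L) else gaps[gaps >= 0L]
}

#' Genome architecture summary (one assembly row)
#'
#' @param annotation A `genome_annotation`.
#' @param scaffolds Scaffold table; defaults to the annotation's own.
#' @return An `architecture_summary`: list with `n_genes`, `pct_intronless`
#'   (percent of genes whose representative has a single CDS segment),
#'   `partition` ([partition_genome()] output), `median_intergenic_gap`,
#'   `median_intron_length` and `n_cds_introns`.
#' @export
architecture_summary <- function(annotation, scaffolds = annotation$scaffolds) {
  n <- nrow(annotation$genes)
  if (n == 0L) stop("annotation contains no genes")
  introns <- cds_intron_table(annotation)
  structure(list(
    n_genes = n,
    pct_intronless = 100 * sum(annotation$genes$n_segments == 1L) / n,
    partition = partition_genome(annotation, scaffolds),
    median_intergenic_gap = if (length(intergenic_gaps(annotation)))
      median(intergenic_gaps(annotation)) else NA_real_,
    median_intron_length = if (nrow(introns)) median(introns$length) else NA_real_,
    n_cds_introns = nrow(introns)), class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat(sprintf(
    "architecture: %d genes | %.2f%% intronless | %d CDS introns\n",
    x$n_genes, x$pct_intronless, x$n_cds_introns))
  cat(sprintf("  medians: intergenic %s bp, intron %s bp\n",
              format(x$median_intergenic_gap), format(x$median_intron_length)))
  print(x$partition)
  invisible(x)
}

#' Relative intron positions along coding sequences
#'
#' For every CDS intron, `r = c_upstream / coding_length` is the fraction of
#' the coding sequence 5' of the intron in transcription direction; intron-
#' poor genomes retaining 5' introns show an excess of small `r`.
#'
#' @param annotation A `genome_annotation` with at least one CDS intron.
#' @param bins Number of equal-width histogram bins over \[0, 1\].
#' @return List with `r` (per-intron fractions), `histogram` (counts per
#'   bin), `breaks`, and `fraction_5prime_half` (share of introns with
#'   `r < 0.5`).
#' @export
relative_intron_positions <- function(annotation, bins = 20L) {
  introns <- cds_intron_table(annotation)
  if (nrow(introns) == 0L) stop("annotation has no CDS introns")
  r <- introns$c_upstream / introns$coding_length
  breaks <- seq(0, 1, length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(r, breaks, rightmost.closed = TRUE), bins),
                nbins = bins)
  list(r = r, histogram = h, breaks = breaks,
       fraction_5prime_half = mean(r < 0.5))
}
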