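# RepeatMasker output parsing and transposable-element coverage. Overlaps
# between annotated repeat copies are resolved per base in favour of the
# hit with the higher Smith-Waterman score (ties: first in file order), so
# no base is counted in more than one class.

#' Parse a RepeatMasker .out file
#'
#' Expects the standard layout: two header lines plus a blank line, then
#' whitespace-delimited hit rows (score, divergence, deletions,
#' insertions, query, begin, end, left, strand, repeat, class/family,
#' repeat begin/end/left, ID, optional `*` overlap marker).
#'
#' @param path RepeatMasker .out file.
#' @return data.frame with columns `sw_score`, `scaffold_id`, `start`,
#'   `end`, `strand`, `repeat_id`, `repeat_class`, `overlapped` (the `*`
#'   marker), in file order.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  empty <- data.frame(sw_score = numeric(), scaffold_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), repeat_id = character(),
                      repeat_class = character(), overlapped = logical())
  body <- which(grepl("^\\s*[0-9]", lines))
  if (length(body) == 0L) return(empty)
  rows <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14L)
      stop("malformed RepeatMasker row at line ", i, ": expected >= 14 fields")
    start <- suppressWarnings(as.integer(f[6L]))
    end <- suppressWarnings(as.integer(f[7L]))
    score <- suppressWarnings(as.numeric(f[1L]))
    if (is.na(start) || is.na(end) || is.na(score) || start > end)
      stop("malformed coordinates/score at line ", i)
    data.frame(sw_score = score, scaffold_id = f[5L], start = start,
               end = end, strand = f[9L], repeat_id = f[10L],
               repeat_class = f[11L],
               overlapped = f[length(f)] == "*")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transposable-element coverage of an assembly
#'
#' Assigns every masked base to the overlapping hit with the highest
#' Smith-Waterman score (ties broken by file order) and reports per-class
#' and total masked base pairs and percentages of the assembly.
#'
#' @param hits data.frame from [parse_repeatmasker_out()].
#' @param scaffolds Scaffold table (`id`, `length`); the summed length is
#'   the denominator.
#' @param class_filter Optional character vector of repeat classes to
#'   keep; a hit matches when its full class/family string or its part
#'   before `/` is in the filter. Use it to exclude non-TE classes such
#'   as `Simple_repeat` or `Low_complexity`.
#' @return A `coverage_report`: list with `per_class` (data.frame
#'   `repeat_class`, `bp`, `pct`), `total_bp`, `total_pct`,
#'   `assembly_bp`.
#' @export
te_coverage <- function(hits, scaffolds, class_filter = NULL) {
  assembly <- sum(as.numeric(scaffolds$length))
  if (!is.null(class_filter)) {
    top <- sub("/.*$", "", hits$repeat_class)
    hits <- hits[hits$repeat_class %in% class_filter | top %in% class_filter,
                 , drop = FALSE]
  }
  if (nrow(hits)) {
    if (!all(hits$scaffold_id %in% scaffolds$id))
      stop("hit on unknown scaffold: ",
           setdiff(hits$scaffold_id, scaffolds$id)[1L])
    L <- setNames(scaffolds$length, scaffolds$id)
    if (any(hits$end > L[hits$scaffold_id]))
      stop("repeat hit extends beyond its scaffold end")
  }
  per_class <- setNames(numeric(0), character(0))
  total <- 0
  for (sc in unique(hits$scaffold_id)) {
    h <- hits[hits$scaffold_id == sc, , drop = FALSE]
    o <- order(-h$sw_score, seq_len(nrow(h)))  # score desc, then file order
    assigned <- IRanges::IRanges()
    for (i in o) {
      r <- IRanges::IRanges(h$start[i], h$end[i])
      new <- IRanges::setdiff(r, assigned)
      w <- sum(IRanges::width(new))
      if (w > 0) {
        cls <- h$repeat_class[i]
        per_class[cls] <- (if (cls %in% names(per_class)) per_class[[cls]] else 0) + w
        total <- total + w
        assigned <- IRanges::reduce(c(assigned, new))
      }
    }
  }
  pc <- data.frame(repeat_class = names(per_class), bp = unname(per_class),
                   pct = 100 * unname(per_class) / assembly)
  pc <- pc[order(-pc$bp), , drop = FALSE]
  rownames(pc) <- NULL
  structure(list(per_class = pc, total_bp = total,
                 total_pct = 100 * total / assembly,
                 assembly_bp = assembly), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("repeat coverage: %.0f of %.0f bp (%.2f%%)\n",
              x$total_bp, x$assembly_bp, x$total_pct))
  print(x$per_class)
  invisible(x)
}

#' Windowed gene and repeat density along scaffolds
#'
#' Tiles each scaffold with non-overlapping windows (last window
#' truncated) and reports per-window coding base pairs (merged CDS union)
#' and repeat-masked base pairs (union of hits, no double counting).
#'
#' @param annotation A `genome_annotation`.
#' @param hits data.frame from [parse_repeatmasker_out()].
#' @param window Window size in bp.
#' @param scaffolds Scaffold table; defaults to the annotation's own.
#' @return data.frame `scaffold_id`, `window_start`, `window_end`,
#'   `coding_bp`, `te_bp`.
#' @export
window_density <- function(annotation, hits, window,
                           scaffolds = annotation$scaffolds) {
  stopifnot(window > 0)
  cds_by_sc <- scaffold_ranges(annotation)$cds
  out <- lapply(seq_len(nrow(scaffolds)), function(i) {
    sc <- scaffolds$id[i]; L <- scaffolds$length[i]
    starts <- seq(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    win <- IRanges::IRanges(starts, ends)
    cds <- if (sc %in% names(cds_by_sc)) cds_by_sc[[sc]] else IRanges::IRanges()
    h <- hits[hits$scaffold_id == sc, , drop = FALSE]
    te <- IRanges::reduce(IRanges::IRanges(h$start, h$end))
    cov_in <- function(u) {
      if (length(u) == 0L) return(integer(length(win)))
      hitsm <- IRanges::findOverlaps(win, u)
      w <- IRanges::width(IRanges::pintersect(
        win[S4Vectors::queryHits(hitsm)], u[S4Vectors::subjectHits(hitsm)]))
      out <- integer(length(win))
      agg <- tapply(w, S4Vectors::queryHits(hitsm), sum)
      out[as.integer(names(agg))] <- as.integer(agg)
      out
    }
    data.frame(scaffold_id = sc, window_start = starts, window_end = ends,
               coding_bp = cov_in(cds), te_bp = cov_in(te))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
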