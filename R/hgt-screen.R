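# Horizontal-gene-transfer screen based on the h-index: the difference
# between a query protein's best non-metazoan and best metazoan BLASTp
# bitscores. Large positive h suggests horizontal acquisition.

#' Parse per-query best bitscores from a tabular BLAST file
#'
#' Reads a 12-column BLAST tabular file (outfmt 6: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). The
#' subject's source database is the part of `sseqid` before the first
#' `|`; `db_class` maps each database label to "metazoan" or
#' "nonmetazoan". Self-hits must have been excluded upstream (the focal
#' proteome is not a valid subject database).
#'
#' @param path BLAST tabular file.
#' @param db_class Named character vector or two-column data.frame
#'   (`db`, `class`) mapping database labels to classes.
#' @return data.frame with one row per query: `query_id`,
#'   `best_metazoan`, `best_nonmetazoan` (NA when the query has no hit in
#'   that class).
#' @export
parse_best_hits <- function(path, db_class) {
  if (is.data.frame(db_class))
    db_class <- setNames(db_class[[2L]], db_class[[1L]])
  if (!all(db_class %in% c("metazoan", "nonmetazoan")))
    stop("db_class values must be 'metazoan' or 'nonmetazoan'")
  d <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed BLAST tabular file: ",
                             conditionMessage(e)))
  if (ncol(d) < 12L)
    stop("BLAST tabular file must have >= 12 columns (outfmt 6)")
  q <- d[[1L]]
  db <- sub("\\|.*$", "", d[[2L]])
  bits <- as.numeric(d[[12L]])
  if (anyNA(bits))
    stop("malformed bitscore at line ", which(is.na(bits))[1L])
  unknown <- setdiff(unique(db), names(db_class))
  if (length(unknown))
    stop("unclassified database label(s): ", paste(unknown, collapse = ", "))
  cls <- db_class[db]
  best <- function(class) {
    sel <- cls == class
    v <- tapply(bits[sel], q[sel], max)
    v[unique(q)]
  }
  out <- data.frame(query_id = unique(q),
                    best_metazoan = unname(best("metazoan")),
                    best_nonmetazoan = unname(best("nonmetazoan")))
  rownames(out) <- NULL
  out
}

#' h-index of a best-hit record
#'
#' `h = best_nonmetazoan - best_metazoan`, with a missing metazoan best
#' hit treated as bitscore 0 (maximally foreign). Records without a
#' non-metazoan hit yield NA (no call is made for them).
#'
#' @param records data.frame as returned by [parse_best_hits()] (or a
#'   single-row equivalent).
#' @return Numeric vector of h values aligned with `records` rows.
#' @export
h_index <- function(records) {
  met <- ifelse(is.na(records$best_metazoan), 0, records$best_metazoan)
  ifelse(is.na(records$best_nonmetazoan), NA_real_,
         records$best_nonmetazoan - met)
}

#' Flag horizontal-transfer candidates by bitscore thresholds
#'
#' A query is a candidate when its best non-metazoan bitscore is at least
#' `min_score` and its h-index at least `min_h` (both inclusive). Queries
#' without any non-metazoan hit are skipped with a logged note.
#'
#' @param records data.frame from [parse_best_hits()].
#' @param min_score Minimum best non-metazoan bitscore (default 75).
#' @param min_h Minimum h-index (default 30).
#' @return data.frame `query_id`, `h`, `candidate` (logical); queries
#'   lacking a non-metazoan hit are excluded.
#' @export
flag_candidates <- function(records, min_score = 75, min_h = 30) {
  h <- h_index(records)
  skip <- is.na(h)
  if (any(skip))
    message(sum(skip), " quer(ies) without a non-metazoan hit skipped")
  r <- records[!skip, , drop = FALSE]
  h <- h[!skip]
  data.frame(query_id = r$query_id, h = h,
             candidate = r$best_nonmetazoan >= min_score & h >= min_h)
}
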