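.discard_reasons <- c(
  "malformed", "unknown_index", "primer_fail",
  "barcode_unmatched", "ambiguous_barcode"
)

#' Per-sample barcode count table
#'
#' Container for per-sample, per-(gene, tag-class) read counts together with
#' the discard counters produced by demultiplexing. Conservation holds by
#' construction: assigned reads plus discarded reads equal reads processed.
#'
#' @param counts data frame with columns `sample`, `gene_id`, `tag_class`
#'   (`"up"` or `"dn"`) and nonnegative integer `count`.
#' @param discards data frame with columns `reason`, `count`; defaults to all
#'   zeros over the standard reasons (`malformed`, `unknown_index`,
#'   `primer_fail`, `barcode_unmatched`, `ambiguous_barcode`).
#' @param n_processed total reads processed (NA when counts were not derived
#'   from reads, e.g. simulated directly).
#' @return Object of class `barseq_counts`.
#' @export
count_table <- function(counts, discards = NULL, n_processed = NA_integer_) {
  req <- c("sample", "gene_id", "tag_class", "count")
  missing <- setdiff(req, names(counts))
  if (length(missing)) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "))
  }
  counts <- counts[, req, drop = FALSE]
  if (any(counts$count < 0)) stop("negative counts are not allowed")
  if (!all(counts$tag_class %in% c("up", "dn"))) {
    stop("tag_class must be 'up' or 'dn'")
  }
  if (is.null(discards)) {
    discards <- data.frame(
      reason = .discard_reasons, count = 0L, stringsAsFactors = FALSE
    )
  }
  rownames(counts) <- NULL
  structure(
    list(counts = counts, discards = discards, n_processed = n_processed),
    class = "barseq_counts"
  )
}

# Accept either a barseq_counts object or a bare count data frame.
as_count_df <- function(x) {
  if (inherits(x, "barseq_counts")) x$counts else x
}

#' @export
print.barseq_counts <- function(x, ...) {
  cat(sprintf(
    "barseq_counts: %d samples, %s assigned reads, %s discarded\n",
    length(unique(x$counts$sample)),
    format(sum(x$counts$count), big.mark = ","),
    format(sum(x$discards$count), big.mark = ",")
  ))
  invisible(x)
}

.tsv_comment <- function(what, params = NULL) {
  p <- if (length(params)) {
    paste(sprintf("%s=%s", names(params), unlist(params)), collapse = " ")
  } else {
    ""
  }
  sprintf("# barseqfit %s %s", what, p)
}

.write_tsv <- function(df, path, what = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(what)) writeLines(.tsv_comment(what, params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a count table as TSV
#'
#' Counts are written as columns (sample, gene_id, tag_class, count), with a
#' leading `#` provenance comment. [read_counts()] accepts such files (the
#' comment and header are skipped) and returns a [count_table()] with zeroed
#' discard counters.
#'
#' @param x a [count_table()] or bare count data frame.
#' @param path file path.
#' @param params optional named list recorded in the provenance comment.
#' @return `path` ([write_counts()]) or a `barseq_counts` ([read_counts()]).
#' @export
write_counts <- function(x, path, params = NULL) {
  .write_tsv(as_count_df(x), path, "counts", params)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  count_table(df)
}

#' Write the discard summary of a count table
#'
#' @param x a [count_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_discards <- function(x, path) {
  stopifnot(inherits(x, "barseq_counts"))
  .write_tsv(x$discards, path, "discards",
    list(n_processed = x$n_processed)
  )
}
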