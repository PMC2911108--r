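# Well-position annotation flags carried over from library decoding:
# OK = as expected, W = wrongly placed, M = present in more than one well,
# C = contaminated well. Metadata only; never consulted during counting
# or scoring.
.position_flags <- c("OK", "W", "M", "C")

.tag_len <- 20L

.is_valid_tag <- function(x) grepl("^[ACGT]{20}$", x)

#' Build a strain/barcode catalog
#'
#' A catalog maps each deletion strain to its uptag and/or dntag barcode
#' (20-nt sequences over A/C/G/T). Barcodes used by more than one
#' (strain, tag-class) association cannot be attributed to a unique strain at
#' counting time; they are moved to the `ambiguous` set and excluded from the
#' exact-match `lookup` used by the demultiplexer. A barcode serving as both
#' uptag and dntag — even within a single strain — is treated the same way.
#'
#' @param records data frame with columns `gene_id`, `well_position`,
#'   `position_flag` (one of `OK`, `W`, `M`, `C`; empty means `OK`),
#'   `uptag`, `dntag` (20-nt sequences; empty string means absent).
#' @return An object of class `barseq_catalog`: a list with elements
#'   `records` (the validated records, tags upper-cased), `lookup`
#'   (data frame `barcode`, `gene_id`, `tag_class` with one row per uniquely
#'   assignable barcode) and `ambiguous` (same columns, all associations of
#'   barcodes used more than once).
#' @seealso [read_catalog()], [find_ambiguous()], [catalog_summary()]
#' @export
#' @examples
#' recs <- data.frame(
#'   gene_id = c("g1", "g2"), well_position = c("P01A01", "P01A02"),
#'   position_flag = c("OK", "OK"),
#'   uptag = c(strrep("A", 20), strrep("C", 20)),
#'   dntag = c(strrep("G", 20), strrep("T", 20))
#' )
#' cat <- catalog(recs)
#' nrow(cat$lookup)
catalog <- function(records) {
  records <- .coerce_records(records)
  .validate_records(records)
  assoc <- .tag_associations(records)
  dup <- unique(assoc$barcode[duplicated(assoc$barcode)])
  amb <- assoc$barcode %in% dup
  structure(
    list(
      records = records,
      lookup = assoc[!amb, , drop = FALSE],
      ambiguous = assoc[amb, , drop = FALSE]
    ),
    class = "barseq_catalog"
  )
}

.coerce_records <- function(records) {
  req <- c("gene_id", "well_position", "position_flag", "uptag", "dntag")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("catalog records lack column(s): ", paste(missing, collapse = ", "))
  }
  records <- records[, req, drop = FALSE]
  for (col in req) {
    v <- as.character(records[[col]])
    v[is.na(v)] <- ""
    records[[col]] <- trimws(v)
  }
  records$uptag <- toupper(records$uptag)
  records$dntag <- toupper(records$dntag)
  records$position_flag[!nzchar(records$position_flag)] <- "OK"
  rownames(records) <- NULL
  records
}

.validate_records <- function(records, lines = NULL) {
  where <- if (is.null(lines)) {
    function(i) sprintf("record %d", i)
  } else {
    function(i) sprintf("line %d", lines[i])
  }
  msgs <- character(0)
  for (i in seq_len(nrow(records))) {
    up <- records$uptag[i]
    dn <- records$dntag[i]
    if (!nzchar(up) && !nzchar(dn)) {
      msgs <- c(msgs, sprintf("%s: neither uptag nor dntag present", where(i)))
    }
    if (nzchar(up) && !.is_valid_tag(up)) {
      msgs <- c(msgs, sprintf(
        "%s: malformed uptag '%s' (need %d nt over A/C/G/T)", where(i), up, .tag_len
      ))
    }
    if (nzchar(dn) && !.is_valid_tag(dn)) {
      msgs <- c(msgs, sprintf(
        "%s: malformed dntag '%s' (need %d nt over A/C/G/T)", where(i), dn, .tag_len
      ))
    }
    if (!records$position_flag[i] %in% .position_flags) {
      msgs <- c(msgs, sprintf(
        "%s: unknown position flag '%s'", where(i), records$position_flag[i]
      ))
    }
  }
  if (length(msgs)) stop(paste(msgs, collapse = "\n"))
  invisible(records)
}

.tag_associations <- function(records) {
  up <- records[nzchar(records$uptag), c("gene_id", "uptag")]
  dn <- records[nzchar(records$dntag), c("gene_id", "dntag")]
  assoc <- rbind(
    data.frame(
      barcode = up$uptag, gene_id = up$gene_id, tag_class = rep("up", nrow(up)),
      stringsAsFactors = FALSE
    ),
    data.frame(
      barcode = dn$dntag, gene_id = dn$gene_id, tag_class = rep("dn", nrow(dn)),
      stringsAsFactors = FALSE
    )
  )
  assoc <- assoc[order(assoc$barcode, assoc$gene_id, assoc$tag_class), , drop = FALSE]
  rownames(assoc) <- NULL
  assoc
}

#' Read a strain/barcode catalog from a 5-column TSV
#'
#' Columns are: gene id, well position, position flag, uptag, dntag
#' (tab-separated). Lines starting with `#` are ignored; a single header row
#' is detected (first data line whose gene column reads like a column title or
#' whose tag columns contain non-DNA characters) and skipped. Tags are parsed
#' case-insensitively and stored upper case; an empty tag cell means the tag
#' is absent.
#'
#' @param path path to the TSV file.
#' @return A [catalog()] object.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  empty <- data.frame(
    gene_id = character(0), well_position = character(0),
    position_flag = character(0), uptag = character(0), dntag = character(0),
    stringsAsFactors = FALSE
  )
  if (!length(keep)) return(catalog(empty))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad_width <- vapply(parts, length, 0L) > 5L
  if (any(bad_width)) {
    stop("line ", keep[which(bad_width)[1]], ": more than 5 tab-separated fields")
  }
  m <- t(vapply(parts, function(x) {
    length(x) <- 5L
    x[is.na(x)] <- ""
    trimws(x)
  }, character(5)))
  recs <- data.frame(
    gene_id = m[, 1], well_position = m[, 2], position_flag = m[, 3],
    uptag = m[, 4], dntag = m[, 5], stringsAsFactors = FALSE
  )
  lineno <- keep
  if (nrow(recs) && .looks_like_header(recs[1, ])) {
    recs <- recs[-1, , drop = FALSE]
    lineno <- lineno[-1]
  }
  if (!nrow(recs)) return(catalog(empty))
  recs <- .coerce_records(recs)
  .validate_records(recs, lineno)
  catalog(recs)
}

.looks_like_header <- function(row) {
  non_dna <- function(x) nzchar(x) && grepl("[^ACGT]", toupper(x))
  tolower(row$gene_id) %in% c("gene", "gene_id", "gene_name", "gene name") ||
    non_dna(row$uptag) || non_dna(row$dntag)
}

#' Write a catalog back to the 5-column TSV layout
#'
#' @param catalog a [catalog()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "barseq_catalog"))
  write.table(catalog$records, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Find barcodes used by more than one (strain, tag-class) association
#'
#' @param records catalog records (see [catalog()]).
#' @return Data frame `barcode`, `gene_id`, `tag_class` containing every
#'   association of each barcode that occurs two or more times, ordered by
#'   barcode then gene id. Empty when all tags are distinct.
#' @export
find_ambiguous <- function(records) {
  records <- .coerce_records(records)
  assoc <- .tag_associations(records)
  dup <- unique(assoc$barcode[duplicated(assoc$barcode)])
  out <- assoc[assoc$barcode %in% dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a catalog after ambiguity exclusion
#'
#' @param catalog a [catalog()] object.
#' @return List with `n_strains` (records in the catalog), `n_one_tag`
#'   (strains with at least one uniquely assignable tag) and `n_both_tags`
#'   (strains whose uptag and dntag are both uniquely assignable).
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "barseq_catalog"))
  r <- catalog$records
  amb <- catalog$ambiguous$barcode
  up_ok <- nzchar(r$uptag) & !(r$uptag %in% amb)
  dn_ok <- nzchar(r$dntag) & !(r$dntag %in% amb)
  list(
    n_strains = nrow(r),
    n_one_tag = sum(up_ok | dn_ok),
    n_both_tags = sum(up_ok & dn_ok)
  )
}

#' Tabulate the ambiguous barcodes of a catalog
#'
#' @param catalog a [catalog()] object.
#' @return Data frame `barcode`, `n_associations`, `genes` (comma-separated).
#' @export
ambiguity_report <- function(catalog) {
  stopifnot(inherits(catalog, "barseq_catalog"))
  amb <- catalog$ambiguous
  if (!nrow(amb)) {
    return(data.frame(
      barcode = character(0), n_associations = integer(0),
      genes = character(0), stringsAsFactors = FALSE
    ))
  }
  sp <- split(amb, amb$barcode)
  out <- data.frame(
    barcode = names(sp),
    n_associations = vapply(sp, nrow, 0L),
    genes = vapply(sp, function(d) paste(sort(unique(d$gene_id)), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$barcode), , drop = FALSE]
}

#' Per-tag barcode sequences of a catalog
#'
#' Long-format map from (gene, tag class) to barcode sequence, taken from the
#' records as stored (ambiguous barcodes included — the map describes what
#' each strain carries, not what is uniquely countable). Used by
#' [emit_fastq()] to turn counts back into read sequences.
#'
#' @param catalog a [catalog()] object.
#' @return Data frame `gene_id`, `tag_class`, `barcode`.
#' @export
tag_map <- function(catalog) {
  stopifnot(inherits(catalog, "barseq_catalog"))
  r <- catalog$records
  up <- r[nzchar(r$uptag), c("gene_id", "uptag")]
  dn <- r[nzchar(r$dntag), c("gene_id", "dntag")]
  out <- rbind(
    data.frame(
      gene_id = up$gene_id, tag_class = rep("up", nrow(up)),
      barcode = up$uptag, stringsAsFactors = FALSE
    ),
    data.frame(
      gene_id = dn$gene_id, tag_class = rep("dn", nrow(dn)),
      barcode = dn$dntag, stringsAsFactors = FALSE
    )
  )
  rownames(out) <- NULL
  out
}

#' @export
print.barseq_catalog <- function(x, ...) {
  s <- catalog_summary(x)
  cat(sprintf(
    "barseq_catalog: %d strains (%d with >=1 unique tag, %d with both), %d unique barcodes, %d ambiguous\n",
    s$n_strains, s$n_one_tag, s$n_both_tags, nrow(x$lookup),
    length(unique(x$ambiguous$barcode))
  ))
  invisible(x)
}
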