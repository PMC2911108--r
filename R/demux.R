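#' Read layout of a multiplexed barcode-sequencing run
#'
#' Reads are 42 nt: a 4-nt multiplex index (cycles 1-4), the 18-nt universal
#' primer region distinguishing uptag from dntag amplicons (cycles 5-22), and
#' the 20-nt strain barcode (cycles 23-42). Internally positions are handled
#' 0-based half-open; cycle k corresponds to string position k.
#'
#' @param max_primer_mismatch maximum substitutions tolerated when matching
#'   the primer region (default 2; set 0 for strict matching).
#' @return List of class `read_layout` with fields `index_len`, `primer_len`,
#'   `barcode_len`, `up_primer`, `dn_primer`, `max_primer_mismatch`.
#' @export
read_layout <- function(max_primer_mismatch = 2) {
  layout <- list(
    index_len = 4L, primer_len = 18L, barcode_len = 20L,
    up_primer = "GAGGCAAGCTAAGATATC",
    dn_primer = "CCAGTGTCGAAAAGTATC",
    max_primer_mismatch = as.integer(max_primer_mismatch)
  )
  stopifnot(
    nchar(layout$up_primer) == layout$primer_len,
    nchar(layout$dn_primer) == layout$primer_len,
    layout$index_len + layout$primer_len + layout$barcode_len == 42L
  )
  class(layout) <- "read_layout"
  layout
}

#' Design a set of multiplex indexes with pairwise Hamming distance >= 2
#'
#' Uses the parity code over {A,C,G,T}^4 whose symbol values sum to 0 mod 4:
#' any two codewords agreeing at three positions are forced to agree at the
#' fourth, so the minimum pairwise distance is 2 and a single sequencing
#' error can never convert one index into another. The code has exactly 64
#' members, which is also the maximum possible (among any 65 4-mers two must
#' share their first three positions and hence lie at distance <= 1). Output
#' is deterministic: the first `n` codewords in lexicographic order.
#'
#' @param n number of indexes (1..64).
#' @param samples optional sample labels (default `S01`, `S02`, ...).
#' @return Data frame `sample`, `index`.
#' @export
design_indexes <- function(n, samples = NULL) {
  if (n < 1) stop("need at least one index")
  if (n > 64) {
    stop("capacity exceeded: no set of more than 64 4-nt indexes can have ",
         "pairwise Hamming distance >= 2")
  }
  grid <- expand.grid(d4 = 0:3, d3 = 0:3, d2 = 0:3, d1 = 0:3)
  keep <- (grid$d1 + grid$d2 + grid$d3 + grid$d4) %% 4L == 0L
  grid <- grid[keep, c("d1", "d2", "d3", "d4")]
  bases <- c("A", "C", "G", "T")
  codes <- apply(grid, 1, function(r) paste0(bases[r + 1L], collapse = ""))
  labels <- samples %||% sprintf("S%02d", seq_len(n))
  stopifnot(length(labels) == n)
  data.frame(sample = labels, index = codes[seq_len(n)], stringsAsFactors = FALSE)
}

#' Minimum pairwise Hamming distance of an index set
#'
#' @param indexes character vector of equal-length indexes, or a data frame
#'   with an `index` column.
#' @return The exact minimum over all pairs (0 if any two indexes are equal).
#' @export
validate_indexes <- function(indexes) {
  if (is.data.frame(indexes)) indexes <- indexes$index
  stopifnot(length(indexes) >= 2, length(unique(nchar(indexes))) == 1)
  chars <- strsplit(indexes, "", fixed = TRUE)
  n <- length(chars)
  dmin <- nchar(indexes[1])
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- sum(chars[[i]] != chars[[j]])
      if (d < dmin) dmin <- d
    }
  }
  dmin
}

# Vectorized three-step read assignment. Returns parallel vectors; reads that
# fail a step carry the discard reason and NA identity.
.demux_reads <- function(seqs, indexes, layout, catalog) {
  n <- length(seqs)
  sample <- gene <- class <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  ok <- rep(TRUE, n)

  read_len <- layout$index_len + layout$primer_len + layout$barcode_len
  short <- nchar(seqs) < read_len
  reason[short] <- "malformed"
  ok[short] <- FALSE

  # Step 1: exact index match (no single-mismatch rescue; the distance-2
  # code makes exact matching the safe policy).
  idx <- substr(seqs, 1L, layout$index_len)
  m <- match(idx, indexes$index)
  bad <- ok & is.na(m)
  reason[bad] <- "unknown_index"
  ok[bad] <- FALSE
  sample[ok] <- indexes$sample[m[ok]]

  # Step 2: primer region vs both universal primers, <= max_primer_mismatch
  # substitutions; the closer primer wins, a tie is a failure (defensive --
  # the two primers differ at far more positions than the tolerance).
  region <- substr(seqs, layout$index_len + 1L, layout$index_len + layout$primer_len)
  mm_up <- .char_mismatches(region, layout$up_primer)
  mm_dn <- .char_mismatches(region, layout$dn_primer)
  tol <- layout$max_primer_mismatch
  pclass <- rep(NA_character_, n)
  pclass[mm_up <= tol & mm_up < mm_dn] <- "up"
  pclass[mm_dn <= tol & mm_dn < mm_up] <- "dn"
  bad <- ok & is.na(pclass)
  reason[bad] <- "primer_fail"
  ok[bad] <- FALSE

  # Step 3: exact barcode lookup. Barcodes shared by several strains are
  # discarded (counted, not assigned); the lookup supplies gene and tag
  # class, the primer having gated the amplicon.
  bc <- substr(
    seqs, layout$index_len + layout$primer_len + 1L,
    layout$index_len + layout$primer_len + layout$barcode_len
  )
  amb <- ok & bc %in% catalog$ambiguous$barcode
  reason[amb] <- "ambiguous_barcode"
  ok[amb] <- FALSE
  bm <- match(bc, catalog$lookup$barcode)
  bad <- ok & is.na(bm)
  reason[bad] <- "barcode_unmatched"
  ok[bad] <- FALSE
  gene[ok] <- catalog$lookup$gene_id[bm[ok]]
  class[ok] <- catalog$lookup$tag_class[bm[ok]]

  list(assigned = ok, sample = sample, gene_id = gene,
       tag_class = class, reason = reason)
}

.char_mismatches <- function(strings, reference) {
  mm <- integer(length(strings))
  ref <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (p in seq_along(ref)) {
    mm <- mm + (substr(strings, p, p) != ref[p])
  }
  mm
}

#' Assign a single read to (sample, gene, tag class)
#'
#' Applies the three-step matching rule: exact index match, universal-primer
#' match with at most `layout$max_primer_mismatch` substitutions, exact
#' barcode lookup. Extra cycles beyond 42 are ignored.
#'
#' @param seq read sequence (>= 42 nt for a well-formed read).
#' @param indexes index set as from [design_indexes()].
#' @param catalog a [catalog()] object.
#' @param layout a [read_layout()].
#' @return For an assigned read, `list(sample, gene_id, tag_class)`;
#'   otherwise `list(discard = reason)` with reason one of `malformed`,
#'   `unknown_index`, `primer_fail`, `barcode_unmatched`,
#'   `ambiguous_barcode`.
#' @export
assign_read <- function(seq, indexes, catalog, layout = read_layout()) {
  r <- .demux_reads(toupper(seq), indexes, layout, catalog)
  if (r$assigned[1]) {
    list(sample = r$sample[1], gene_id = r$gene_id[1], tag_class = r$tag_class[1])
  } else {
    list(discard = r$reason[1])
  }
}

#' Count reads from FASTQ files against a catalog
#'
#' Streams each FASTQ file (plain or gzip), applies [assign_read()]'s
#' three-step rule to every read, and aggregates assigned reads into a
#' [count_table()]. Conservation holds: assigned + discarded = processed.
#'
#' @param paths FASTQ file paths.
#' @param indexes index set as from [design_indexes()] (columns `sample`,
#'   `index`).
#' @param catalog a [catalog()] object.
#' @param layout a [read_layout()].
#' @return A [count_table()] with per-reason discard counters and
#'   `n_processed` set.
#' @export
count_reads <- function(paths, indexes, catalog, layout = read_layout()) {
  key_acc <- integer(0)
  reason_acc <- setNames(integer(length(.discard_reasons)), .discard_reasons)
  n_total <- 0L
  for (p in paths) {
    seqs <- tryCatch(
      as.character(Biostrings::readDNAStringSet(p, format = "fastq")),
      error = function(e) {
        stop("failed to read FASTQ '", p, "': ", conditionMessage(e))
      }
    )
    n_total <- n_total + length(seqs)
    r <- .demux_reads(seqs, indexes, layout, catalog)
    if (any(r$assigned)) {
      k <- paste(r$sample[r$assigned], r$gene_id[r$assigned],
                 r$tag_class[r$assigned], sep = "\t")
      tb <- table(k)
      hit <- match(names(tb), names(key_acc))
      new <- is.na(hit)
      key_acc[names(tb)[new]] <- 0L
      key_acc[names(tb)] <- key_acc[names(tb)] + as.integer(tb)
    }
    if (any(!r$assigned)) {
      tb <- table(r$reason[!r$assigned])
      reason_acc[names(tb)] <- reason_acc[names(tb)] + as.integer(tb)
    }
  }
  if (length(key_acc)) {
    parts <- do.call(rbind, strsplit(names(key_acc), "\t", fixed = TRUE))
    counts <- data.frame(
      sample = parts[, 1], gene_id = parts[, 2], tag_class = parts[, 3],
      count = as.integer(key_acc), stringsAsFactors = FALSE
    )
    counts <- counts[order(counts$sample, counts$tag_class, counts$gene_id), ]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(
      sample = character(0), gene_id = character(0),
      tag_class = character(0), count = integer(0), stringsAsFactors = FALSE
    )
  }
  discards <- data.frame(
    reason = .discard_reasons, count = as.integer(reason_acc[.discard_reasons]),
    stringsAsFactors = FALSE
  )
  count_table(counts, discards, n_processed = n_total)
}
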