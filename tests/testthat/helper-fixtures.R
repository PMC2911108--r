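# Shared fixtures, all built in code.

# Deterministic 20-mers that are easy to eyeball in failures.
tag20 <- function(letter) strrep(letter, 20)

toy_records <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    well_position = c("P01A01", "P01A02", "P01A03"),
    position_flag = c("OK", "W", "OK"),
    uptag = c(tag20("A"), tag20("C"), tag20("G")),
    dntag = c(
      paste0(strrep("A", 10), strrep("C", 10)),
      paste0(strrep("C", 10), strrep("G", 10)),
      paste0(strrep("G", 10), strrep("T", 10))
    ),
    stringsAsFactors = FALSE
  )
}

write_records_tsv <- function(records, path, header = TRUE) {
  lines <- apply(records, 1, paste, collapse = "\t")
  if (header) {
    lines <- c("gene_id\twell_position\tposition_flag\tuptag\tdntag", lines)
  }
  writeLines(lines, path)
  path
}

# Small catalog with random tags, for property-style loops.
random_records <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tags <- barseqfit:::.random_tags(2L * n)
  data.frame(
    gene_id = sprintf("r%03d", seq_len(n)),
    well_position = sprintf("P01A%02d", seq_len(n)),
    position_flag = "OK",
    uptag = tags[seq_len(n)],
    dntag = tags[n + seq_len(n)],
    stringsAsFactors = FALSE
  )
}

# Build a count data frame for explicit per-sample counts.
# counts_list: named list sample -> named list tag_class -> named vector
# gene -> count.
manual_counts <- function(counts_list) {
  rows <- list()
  for (s in names(counts_list)) {
    for (cls in names(counts_list[[s]])) {
      v <- counts_list[[s]][[cls]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene_id = names(v), tag_class = cls,
        count = as.numeric(v), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
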