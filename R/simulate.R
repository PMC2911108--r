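#' Simulation configuration for a pooled Bar-seq experiment
#'
#' Bundles the generator parameters: library size, initial abundance
#' dispersion, sampled pool doublings, sequencing depth per tag class,
#' tag-specific amplification bias, per-base substitution error rate, spike-in
#' list and the master seed. Defaults emulate the study conditions of a
#' ~2,500-strain fission yeast pool sequenced at one million reads per tag
#' class over five pool doublings.
#'
#' @param n_strains number of library strains.
#' @param generations pool doublings at which samples are taken.
#' @param depth reads sequenced per tag class per sample.
#' @param abundance_sigma log-normal sigma of the initial strain abundances
#'   (dimensionless; 1 emulates an unevenly pooled library).
#' @param tag_bias_sigma log-normal sigma of the per-barcode amplification
#'   bias weight (0 = no bias). The weight is drawn once per barcode and
#'   reused across all samples, as PCR/tag efficiency differences are.
#' @param error_rate per-base substitution probability in emitted reads.
#' @param seed integer master seed.
#' @param spike_ins optional data frame (`gene_id`, `uptag`, `dntag`,
#'   `ratio`) of spike-in strains; ratios are cell fractions relative to the
#'   library, in (0, 1), summing to < 1.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_strains = 2500, generations = 1:5, depth = 1e6,
                       abundance_sigma = 1, tag_bias_sigma = 0,
                       error_rate = 0, seed = 1L, spike_ins = NULL) {
  stopifnot(
    n_strains >= 1, all(generations >= 0), depth >= 0,
    abundance_sigma >= 0, tag_bias_sigma >= 0,
    error_rate >= 0, error_rate < 1
  )
  if (!is.null(spike_ins)) {
    stopifnot(
      all(c("gene_id", "uptag", "dntag", "ratio") %in% names(spike_ins)),
      all(spike_ins$ratio > 0), all(spike_ins$ratio < 1)
    )
    if (sum(spike_ins$ratio) >= 1) stop("spike-in ratios must sum to < 1")
  }
  structure(
    list(
      n_strains = as.integer(n_strains), generations = generations,
      depth = depth, abundance_sigma = abundance_sigma,
      tag_bias_sigma = tag_bias_sigma, error_rate = error_rate,
      seed = as.integer(seed), spike_ins = spike_ins
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic strain/barcode catalog
#'
#' Random, pairwise-distinct 20-nt uptag and dntag sequences for `n_strains`
#' strains laid out on 96-well plates. All position flags are `OK`.
#'
#' @param n_strains number of strains.
#' @param seed optional integer seed (NULL = use current RNG state).
#' @param prefix gene-id prefix.
#' @return A [catalog()] object.
#' @export
simulate_catalog <- function(n_strains, seed = NULL, prefix = "mut") {
  if (!is.null(seed)) set.seed(seed)
  tags <- .random_tags(2L * n_strains)
  well <- sprintf(
    "P%02d%s%02d",
    (seq_len(n_strains) - 1L) %/% 96L + 1L,
    LETTERS[((seq_len(n_strains) - 1L) %% 96L) %/% 12L + 1L],
    (seq_len(n_strains) - 1L) %% 12L + 1L
  )
  records <- data.frame(
    gene_id = sprintf("%s%04d", prefix, seq_len(n_strains)),
    well_position = well,
    position_flag = "OK",
    uptag = tags[seq_len(n_strains)],
    dntag = tags[n_strains + seq_len(n_strains)],
    stringsAsFactors = FALSE
  )
  catalog(records)
}

.random_tags <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(c("A", "C", "G", "T"), .tag_len * need, replace = TRUE),
      nrow = need
    )
    out <- unique(c(out, apply(m, 1, paste0, collapse = "")))
  }
  out[seq_len(n)]
}

#' Ground-truth relative fitness per strain and condition
#'
#' Relative fitness f is expressed in strain doublings per pool doubling:
#' f = 1 is wild-type growth, f = 0 a strain whose cell number does not
#' increase at all, f > 1 a growth advantage. All entries default to 1;
#' planted effects are assigned by indexing, e.g.
#' `fit["mut0007", "EMM"] <- 0`.
#'
#' @param gene_ids strain identifiers (row names).
#' @param conditions condition labels (column names).
#' @return Numeric matrix of ones, `length(gene_ids)` x `length(conditions)`.
#' @export
fitness_profile <- function(gene_ids, conditions) {
  matrix(1,
    nrow = length(gene_ids), ncol = length(conditions),
    dimnames = list(gene_ids, conditions)
  )
}

#' Deterministic abundance fractions after competitive exponential growth
#'
#' Each strain grows exponentially at its own rate while the culture is
#' repeatedly diluted to stay in log phase; after `g` doublings of the total
#' pool the fraction of strain i is
#' `p_i(g) = p_i(0) 2^(f_i g) / sum_j p_j(0) 2^(f_j g)`.
#'
#' @param p0 initial abundance fractions (nonnegative; normalized internally).
#' @param fitness per-strain relative fitness (same length as `p0`, all >= 0).
#' @param g pool doublings (>= 0).
#' @return Abundance fractions summing to 1.
#' @export
simulate_abundances <- function(p0, fitness, g) {
  stopifnot(length(p0) == length(fitness), all(fitness >= 0), g >= 0, all(p0 >= 0))
  w <- p0 * 2^(fitness * g)
  s <- sum(w)
  if (s <= 0) stop("pool is empty: all abundance-weighted growth is zero")
  w / s
}

#' Draw initial pool abundances
#'
#' Log-normal relative abundances normalized to fractions; `sigma = 0` gives
#' a perfectly even pool.
#'
#' @param n number of strains.
#' @param sigma log-normal sigma.
#' @param seed optional integer seed.
#' @return Abundance fractions of length `n` summing to 1.
#' @export
simulate_initial_abundances <- function(n, sigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rlnorm(n, meanlog = 0, sdlog = sigma)
  x / sum(x)
}

#' Draw per-barcode amplification bias weights
#'
#' @param n number of barcodes.
#' @param sigma log-normal sigma of the multiplicative weight.
#' @param seed optional integer seed.
#' @return Positive weights of length `n` (all 1 when `sigma = 0`).
#' @export
simulate_tag_bias <- function(n, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) rep(1, n) else rlnorm(n, meanlog = 0, sdlog = sigma)
}

#' Multinomial sequencing counts for one sample
#'
#' Per tag class, one multinomial draw of size `depth` with probabilities
#' proportional to abundance times the per-barcode bias weight.
#'
#' @param abundances named abundance fractions (names = gene ids).
#' @param depth reads per tag class (>= 0).
#' @param bias_up,bias_dn optional per-strain bias weights for the uptag and
#'   dntag barcodes (default: no bias).
#' @param seed optional integer seed.
#' @param tag_classes tag classes to draw (default both).
#' @return Data frame `gene_id`, `tag_class`, `count`; counts per class sum
#'   to `depth`.
#' @export
simulate_counts <- function(abundances, depth, bias_up = NULL, bias_dn = NULL,
                            seed = NULL, tag_classes = c("up", "dn")) {
  if (depth < 0) stop("depth must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  genes <- names(abundances) %||% sprintf("strain%04d", seq_along(abundances))
  bias <- list(up = bias_up %||% rep(1, length(abundances)),
               dn = bias_dn %||% rep(1, length(abundances)))
  out <- lapply(tag_classes, function(cls) {
    w <- abundances * bias[[cls]]
    cnt <- if (depth == 0) {
      integer(length(w))
    } else {
      as.integer(rmultinom(1, size = depth, prob = w))
    }
    data.frame(
      gene_id = genes, tag_class = cls, count = cnt, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Add spike-in reads to a single-sample count table
#'
#' Spike-in strains are added at known cell ratios relative to the library;
#' with library reads L per tag class and spike ratios r_i (relative to total
#' cells, library plus spikes), each spike-in receives a binomial draw with
#' expectation `L * r_i / (1 - sum(r))`. Library counts are left untouched.
#'
#' @param counts single-sample count data frame (`gene_id`, `tag_class`,
#'   `count`).
#' @param spike_ins data frame `gene_id`, `ratio` (optionally `uptag`,
#'   `dntag` for later read emission); ratios in (0, 1), summing to < 1.
#' @param seed optional integer seed.
#' @return The count data frame with spike-in rows appended.
#' @export
inject_spikeins <- function(counts, spike_ins, seed = NULL) {
  if (is.null(spike_ins) || !nrow(spike_ins)) return(counts)
  stopifnot(all(spike_ins$ratio > 0))
  rsum <- sum(spike_ins$ratio)
  if (rsum >= 1) stop("spike-in ratios must sum to < 1")
  if (!is.null(seed)) set.seed(seed)
  extra <- lapply(unique(counts$tag_class), function(cls) {
    L <- sum(counts$count[counts$tag_class == cls])
    n <- rbinom(nrow(spike_ins), size = L, prob = spike_ins$ratio / (1 - rsum))
    data.frame(
      gene_id = spike_ins$gene_id, tag_class = cls, count = n,
      stringsAsFactors = FALSE
    )
  })
  rbind(counts, do.call(rbind, extra))
}

#' Emit a single-sample FASTQ file from a count table
#'
#' One read per count, laid out as 4-nt multiplex index + 18-nt tag-class
#' universal primer + 20-nt barcode (42 nt total). Each base is independently
#' substituted with probability `error_rate`, uniformly over the three
#' alternative bases. Read order is shuffled deterministically given the RNG
#' state; quality is the constant string of `I` (qualities are never used
#' downstream).
#'
#' @param counts single-sample count data frame (`gene_id`, `tag_class`,
#'   `count`).
#' @param barcodes barcode map as from [tag_map()] (`gene_id`, `tag_class`,
#'   `barcode`), covering every counted barcode.
#' @param index the sample's 4-nt multiplex index.
#' @param path output FASTQ path (`.gz` suffix writes gzip).
#' @param layout a [read_layout()].
#' @param error_rate per-base substitution probability.
#' @param seed optional integer seed.
#' @param sample sample name used in read identifiers.
#' @return `path`, invisibly; attribute `n_reads` carries the read count.
#' @export
emit_fastq <- function(counts, barcodes, index, path, layout = read_layout(),
                       error_rate = 0, seed = NULL, sample = "sample") {
  stopifnot(nchar(index) == layout$index_len, grepl("^[ACGT]+$", index))
  if (!is.null(seed)) set.seed(seed)
  key <- paste(counts$gene_id, counts$tag_class)
  bkey <- paste(barcodes$gene_id, barcodes$tag_class)
  m <- match(key, bkey)
  used <- counts$count > 0
  if (any(used & is.na(m))) {
    stop(
      "no barcode sequence for: ",
      paste(head(key[used & is.na(m)], 5), collapse = ", ")
    )
  }
  primer <- c(up = layout$up_primer, dn = layout$dn_primer)
  tmpl <- paste0(index, primer[counts$tag_class], barcodes$barcode[m])
  seqs <- rep(tmpl, counts$count)
  n <- length(seqs)
  if (n > 0) {
    seqs <- seqs[sample.int(n)]
    if (error_rate > 0) seqs <- .substitute_errors(seqs, error_rate)
  }
  read_len <- layout$index_len + layout$primer_len + layout$barcode_len
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n > 0) {
    rec <- character(4L * n)
    rec[seq(1L, by = 4L, length.out = n)] <- sprintf("@%s_%d", sample, seq_len(n))
    rec[seq(2L, by = 4L, length.out = n)] <- seqs
    rec[seq(3L, by = 4L, length.out = n)] <- "+"
    rec[seq(4L, by = 4L, length.out = n)] <- strrep("I", read_len)
    writeLines(rec, con)
  }
  structure(invisible(path), n_reads = n)
}

.substitute_errors <- function(seqs, error_rate) {
  bases <- c("A", "C", "G", "T")
  len <- nchar(seqs[1])
  n <- length(seqs)
  for (p in seq_len(len)) {
    hit <- which(runif(n) < error_rate)
    if (!length(hit)) next
    orig <- substr(seqs[hit], p, p)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    new <- bases[((match(orig, bases) - 1L + shift) %% 4L) + 1L]
    substr(seqs[hit], p, p) <- new
  }
  seqs
}

#' Simulate a full pooled-growth experiment at the count level
#'
#' Draws initial abundances and tag-bias weights once, grows the pool under
#' each condition, and sequences each (condition, generation) sample by a
#' multinomial draw per tag class. Sample names follow the
#' `<condition>_g<generation>` convention used by [experiment_design()].
#'
#' @param catalog a [catalog()] object (defines the strain set).
#' @param fitness a [fitness_profile()] matrix (strains x conditions).
#' @param config a [sim_config()]; `generations`, `depth`,
#'   `abundance_sigma` and `tag_bias_sigma` are taken from it.
#' @param conditions conditions to grow (default: all fitness columns).
#' @param seed optional integer seed (default: `config$seed`).
#' @return A [count_table()] covering all samples. Attribute `truth` carries
#'   the ground truth (`p0`, `bias_up`, `bias_dn`, `fitness`).
#' @export
simulate_pool_experiment <- function(catalog, fitness, config,
                                     conditions = colnames(fitness),
                                     seed = config$seed) {
  stopifnot(inherits(catalog, "barseq_catalog"), inherits(config, "sim_config"))
  genes <- catalog$records$gene_id
  stopifnot(all(genes %in% rownames(fitness)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  p0 <- setNames(
    simulate_initial_abundances(n, config$abundance_sigma), genes
  )
  bias_up <- simulate_tag_bias(n, config$tag_bias_sigma)
  bias_dn <- simulate_tag_bias(n, config$tag_bias_sigma)
  out <- list()
  for (cond in conditions) {
    f <- fitness[genes, cond]
    for (g in config$generations) {
      ab <- simulate_abundances(p0, f, g)
      cnt <- simulate_counts(ab, config$depth, bias_up, bias_dn)
      if (!is.null(config$spike_ins)) {
        cnt <- inject_spikeins(cnt, config$spike_ins)
      }
      cnt$sample <- sprintf("%s_g%d", cond, as.integer(g))
      out[[length(out) + 1L]] <- cnt
    }
  }
  all <- do.call(rbind, out)
  ct <- count_table(all[, c("sample", "gene_id", "tag_class", "count")])
  attr(ct, "truth") <- list(
    p0 = p0, bias_up = bias_up, bias_dn = bias_dn, fitness = fitness
  )
  ct
}
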