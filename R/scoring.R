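#' Scoring parameters
#'
#' @param pseudocount reads added to every raw count before forming the fold
#'   change, to avoid division by zero (default 1).
#' @param min_control_reads a barcode's GI is left uncomputed when its raw
#'   control-sample reads fall below this at any weighted generation
#'   (default 12); guards against noise from low control coverage.
#' @param normalization_total per-sample, per-tag-class matched reads are
#'   scaled to this total (default one million).
#' @return List of class `scoring_params`.
#' @export
scoring_params <- function(pseudocount = 1, min_control_reads = 12,
                           normalization_total = 1e6) {
  stopifnot(pseudocount > 0, min_control_reads >= 0, normalization_total > 0)
  structure(
    list(
      pseudocount = pseudocount, min_control_reads = min_control_reads,
      normalization_total = normalization_total
    ),
    class = "scoring_params"
  )
}

#' Experiment design: control/treatment samples, generations, weights
#'
#' An experiment compares a control to a treatment condition over a set of
#' pool doublings g, each carrying a weight a_g in the GI score. Weights must
#' be nonnegative and sum to 1. The rich-vs-minimal growth design uses
#' generations 1..5 with weights (0, 0, 1/3, 1/3, 1/3); drug and irradiation
#' designs sample only g = 5 with weight 1, so GI = log2(FC_5)/5.
#'
#' @param control,treatment condition labels.
#' @param generations sampled pool doublings.
#' @param weights weight a_g per generation (default: equal weights).
#' @param replicate replicate identifier (e.g. "A", "B", "C").
#' @param samples optional data frame `condition`, `generation`, `sample`
#'   mapping each (condition, generation) to a sample name in the count
#'   table; defaults to `<condition>_g<generation>`.
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(control, treatment, generations,
                              weights = NULL, replicate = "A",
                              samples = NULL) {
  n <- length(generations)
  weights <- weights %||% rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= 0), all(generations > 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("generation weights must sum to 1")
  names(weights) <- as.character(generations)
  if (is.null(samples)) {
    samples <- data.frame(
      condition = rep(c(control, treatment), each = n),
      generation = rep(generations, 2),
      sample = sprintf("%s_g%d", rep(c(control, treatment), each = n),
                       as.integer(rep(generations, 2))),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      control = control, treatment = treatment, generations = generations,
      weights = weights, replicate = replicate, samples = samples
    ),
    class = "experiment_design"
  )
}

#' Normalize counts to a fixed per-tag-class total
#'
#' Each count is scaled by `total / (matched reads of its sample and tag
#' class)`, so every (sample, tag class) stratum sums to `total` (one million
#' by default) and samples of different depth become comparable.
#'
#' @param x a [count_table()] or count data frame.
#' @param total target total per sample and tag class.
#' @return The count data frame with an added numeric `norm` column.
#' @export
normalize_counts <- function(x, total = 1e6) {
  df <- as_count_df(x)
  key <- paste(df$sample, df$tag_class)
  tot <- tapply(df$count, key, sum)
  if (any(tot == 0)) {
    stop(
      "no matched reads for sample/tag class: ",
      paste(names(tot)[tot == 0], collapse = ", ")
    )
  }
  df$norm <- df$count * total / as.numeric(tot[key])
  df
}

#' Normalized control-versus-treatment fold change of one barcode
#'
#' `FC = ((raw_control + pseudocount) * S_c) / ((raw_treatment + pseudocount)
#' * S_t)` where `S_x = normalization_total / total_x`. Scale factors come
#' from the raw (un-pseudocounted) matched totals; the pseudocount only
#' protects the ratio against zero reads, so FC is always positive.
#' Vectorized over counts and totals.
#'
#' @param raw_control,raw_treatment raw barcode reads in the two samples.
#' @param control_total,treatment_total raw matched reads of the relevant tag
#'   class in each sample (> 0).
#' @param params a [scoring_params()].
#' @return Positive fold change(s), control over treatment.
#' @export
compute_fc <- function(raw_control, raw_treatment, control_total,
                       treatment_total, params = scoring_params()) {
  stopifnot(all(control_total > 0), all(treatment_total > 0))
  sc <- params$normalization_total / control_total
  st <- params$normalization_total / treatment_total
  ((raw_control + params$pseudocount) * sc) /
    ((raw_treatment + params$pseudocount) * st)
}

#' Growth-inhibition score from per-generation fold changes
#'
#' `GI = sum_g a_g * log2(FC_g) / g`, the weighted average of per-generation
#' log2 depletion rates. A strain unaffected by the treatment has FC_g = 1 at
#' every generation and GI = 0; a strain whose cell number does not increase
#' at all while the pool doubles has FC_g = 2^g and GI = 1; a growth
#' advantage under treatment gives a negative GI.
#'
#' @param fc named numeric vector of fold changes, names = generations.
#' @param weights named numeric vector of weights a_g (nonnegative, summing
#'   to 1), names = generations.
#' @return The GI score, or `NA` when a fold change is missing at a
#'   positively weighted generation.
#' @export
gi_score <- function(fc, weights) {
  stopifnot(all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  w <- weights[weights > 0]
  g <- as.numeric(names(w))
  if (any(is.na(g))) stop("weights must be named by generation")
  f <- fc[names(w)]
  if (any(is.na(f))) return(NA_real_)
  sum(w * log2(f) / g)
}

#' Combine uptag and dntag GI scores into one per-strain score
#'
#' Both defined: their mean. One defined: that value. Neither: `NA`.
#'
#' @param gi_up,gi_dn per-tag GI scores (`NA` = undefined).
#' @return Combined GI or `NA`. Vectorized.
#' @export
strain_gi <- function(gi_up, gi_dn) {
  out <- rowMeans(cbind(gi_up, gi_dn), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  unname(out)
}

#' Score one experiment: per-strain fold changes and GI
#'
#' For every catalogued strain and tag class: the tag is skipped when the
#' barcode is not uniquely assignable, or when its raw control reads fall
#' below `params$min_control_reads` at any positively weighted generation.
#' Otherwise FC_g is computed per weighted generation ([compute_fc()]), the
#' tag GI via [gi_score()], and the strain GI via [strain_gi()]. Counts
#' absent from the table are zero (the strain simply received no reads).
#'
#' @param counts a [count_table()] or count data frame covering all samples
#'   the design references at positively weighted generations.
#' @param catalog a [catalog()] object.
#' @param design an [experiment_design()].
#' @param params a [scoring_params()].
#' @return Data frame of class `gi_table`: one row per strain with columns
#'   `gene_id`, `gi_up`, `gi_dn`, `gi`, `status` (`ok`,
#'   `insufficient_control_reads`, or `no_barcode`) and per-generation fold
#'   changes `fc_<class>_g<g>`. Attributes: `design`, `params`, and `gtest`
#'   (per-tag control/treatment counts and totals at the last weighted
#'   generation, the input to the significance filter in
#'   [call_sensitive()]).
#' @export
score_experiment <- function(counts, catalog, design,
                             params = scoring_params()) {
  stopifnot(
    inherits(catalog, "barseq_catalog"),
    inherits(design, "experiment_design")
  )
  df <- as_count_df(counts)
  wsel <- design$weights > 0
  wg <- design$generations[wsel]
  w <- design$weights[wsel]
  sample_of <- function(cond, g) {
    s <- design$samples$sample[design$samples$condition == cond &
                                design$samples$generation == g]
    if (length(s) != 1) {
      stop("design has no unique sample for condition '", cond,
           "' at generation ", g)
    }
    s
  }
  csamp <- vapply(wg, function(g) sample_of(design$control, g), "")
  tsamp <- vapply(wg, function(g) sample_of(design$treatment, g), "")
  absent <- setdiff(c(csamp, tsamp), unique(df$sample))
  if (length(absent)) {
    stop("count table lacks sample(s): ", paste(absent, collapse = ", "))
  }

  genes <- catalog$records$gene_id
  ng <- length(genes)
  res <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  per_tag <- list()
  gtest <- list()
  final_j <- which.max(wg)

  for (cls in c("up", "dn")) {
    lk <- catalog$lookup[catalog$lookup$tag_class == cls, ]
    usable <- genes %in% lk$gene_id
    sub <- df[df$tag_class == cls, ]
    grab <- function(s) {
      ss <- sub[sub$sample == s, ]
      v <- ss$count[match(genes, ss$gene_id)]
      v[is.na(v)] <- 0
      v
    }
    totals <- function(s) sum(sub$count[sub$sample == s])
    C <- matrix(vapply(csamp, grab, numeric(ng)), nrow = ng)
    Tt <- matrix(vapply(tsamp, grab, numeric(ng)), nrow = ng)
    ctot <- vapply(csamp, totals, 0)
    ttot <- vapply(tsamp, totals, 0)
    if (any(ctot == 0) || any(ttot == 0)) {
      bad <- c(csamp[ctot == 0], tsamp[ttot == 0])
      stop("no matched ", cls, "-tag reads in sample(s): ",
           paste(bad, collapse = ", "))
    }
    FC <- matrix(NA_real_, ng, length(wg))
    for (j in seq_along(wg)) {
      FC[, j] <- compute_fc(C[, j], Tt[, j], ctot[j], ttot[j], params)
    }
    enough <- rowSums(C < params$min_control_reads) == 0
    keep <- usable & enough
    gi_tag <- rep(NA_real_, ng)
    gi_tag[keep] <- as.numeric(
      log2(FC[keep, , drop = FALSE]) %*% (w / wg)
    )
    for (j in seq_along(wg)) {
      col <- sprintf("fc_%s_g%d", cls, as.integer(wg[j]))
      res[[col]] <- ifelse(usable, FC[, j], NA_real_)
    }
    per_tag[[cls]] <- list(gi = gi_tag, usable = usable)
    gtest[[cls]] <- data.frame(
      gene_id = genes[usable], tag_class = cls,
      control = unname(C[usable, final_j]),
      treatment = unname(Tt[usable, final_j]),
      control_total = unname(ctot[final_j]),
      treatment_total = unname(ttot[final_j]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }

  res$gi_up <- per_tag$up$gi
  res$gi_dn <- per_tag$dn$gi
  res$gi <- strain_gi(res$gi_up, res$gi_dn)
  has_tag <- per_tag$up$usable | per_tag$dn$usable
  res$status <- ifelse(!has_tag, "no_barcode",
                       ifelse(is.na(res$gi), "insufficient_control_reads", "ok"))
  fc_cols <- grep("^fc_", names(res), value = TRUE)
  res <- res[, c("gene_id", "gi_up", "gi_dn", "gi", "status", fc_cols)]
  class(res) <- c("gi_table", "data.frame")
  attr(res, "design") <- design
  attr(res, "params") <- params
  attr(res, "gtest") <- rbind(gtest$up, gtest$dn)
  res
}

#' Write a GI table as TSV
#'
#' @param gi_table a `gi_table` from [score_experiment()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gi_table <- function(gi_table, path) {
  d <- attr(gi_table, "design")
  params <- if (is.null(d)) NULL else list(
    control = d$control, treatment = d$treatment, replicate = d$replicate
  )
  .write_tsv(as.data.frame(gi_table), path, "gi", params)
}

#' @rdname write_gi_table
#' @export
read_gi_table <- function(path) {
  res <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(res) <- c("gi_table", "data.frame")
  res
}
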