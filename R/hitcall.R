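#' Hit-calling parameters
#'
#' Sensitive hits must clear a GI cutoff derived from the per-experiment GI
#' distribution (median + k x NIQR, with k depending on how many tags carry
#' a score) and a G-test significance cutoff, in at least `min_experiments`
#' of the supplied experiments. Resistant candidates are ranked by ascending
#' GI and flagged below `resistant_flag_cutoff`.
#'
#' @param single_tag_mult k for strains scored by one tag only (default 3).
#' @param averaged_mult k for the averaged GI of dual-tag strains
#'   (default 2.5).
#' @param per_tag_mult k each individual tag of a dual-tag strain must clear
#'   (default 2).
#' @param p_cutoff G-test p-value cutoff (default 0.005).
#' @param min_experiments experiments a gene must pass in (default 2, i.e.
#'   two of three).
#' @param resistant_flag_cutoff GI at or below which a strain is flagged as
#'   a resistance candidate (default -0.5, inclusive).
#' @param williams apply the Williams correction to the G statistic
#'   (default FALSE, the plain statistic).
#' @return List of class `hitcall_params`.
#' @export
hitcall_params <- function(single_tag_mult = 3, averaged_mult = 2.5,
                           per_tag_mult = 2, p_cutoff = 0.005,
                           min_experiments = 2,
                           resistant_flag_cutoff = -0.5,
                           williams = FALSE) {
  stopifnot(
    single_tag_mult > 0, averaged_mult > 0, per_tag_mult > 0,
    p_cutoff > 0, p_cutoff < 1, min_experiments >= 1
  )
  structure(
    list(
      single_tag_mult = single_tag_mult, averaged_mult = averaged_mult,
      per_tag_mult = per_tag_mult, p_cutoff = p_cutoff,
      min_experiments = min_experiments,
      resistant_flag_cutoff = resistant_flag_cutoff,
      williams = williams
    ),
    class = "hitcall_params"
  )
}

#' Robust location and spread: median and normalized IQR
#'
#' Quartiles are taken by linear interpolation of the order statistics
#' (type-7 quantiles). `NIQR = IQR * 0.7413` rescales the interquartile
#' range so that it estimates the standard deviation of a normal
#' distribution (1/1.349 of the normal IQR), giving outlier-resistant
#' analogues of the mean and SD.
#'
#' @param values numeric vector, at least 2 finite values.
#' @return List with `median`, `iqr`, `niqr`.
#' @export
robust_stats <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2) stop("need at least 2 finite values")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  list(median = q[2], iqr = iqr, niqr = 0.7413 * iqr)
}

#' Likelihood-ratio G-test on a 2x2 count table
#'
#' Tests whether a barcode's read proportion differs between two samples.
#' The table is (a, total_a - a) vs (b, total_b - b); expected counts come
#' from the marginals and `G = 2 * sum O * ln(O / E)` with zero cells
#' contributing nothing. G is compared to a chi-square distribution with one
#' degree of freedom. No replicates are required, which suits per-barcode
#' count data. Vectorized over `a`, `b` and the totals.
#'
#' @param a,b barcode reads in the two samples.
#' @param total_a,total_b total matched reads of the two samples (> 0).
#' @param williams divide G by the Williams correction factor.
#' @return Data frame with columns `G`, `df` (always 1), `p`.
#' @export
g_test <- function(a, b, total_a, total_b, williams = FALSE) {
  stopifnot(
    all(total_a > 0), all(total_b > 0),
    all(a >= 0), all(b >= 0), all(a <= total_a), all(b <= total_b)
  )
  o11 <- a
  o12 <- total_a - a
  o21 <- b
  o22 <- total_b - b
  n <- total_a + total_b
  c1 <- o11 + o21
  c2 <- o12 + o22
  e11 <- total_a * c1 / n
  e12 <- total_a * c2 / n
  e21 <- total_b * c1 / n
  e22 <- total_b * c2 / n
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  G <- 2 * (term(o11, e11) + term(o12, e12) + term(o21, e21) + term(o22, e22))
  G <- pmax(G, 0)
  if (williams) {
    q <- 1 + ((n / total_a + n / total_b - 1) * (n / pmax(c1, 1) + n / pmax(c2, 1) - 1)) / (6 * n)
    ok <- c1 > 0 & c2 > 0
    G <- ifelse(ok, G / q, G)
  }
  data.frame(G = G, df = 1L, p = pchisq(G, df = 1, lower.tail = FALSE))
}

#' GI cutoffs from the per-experiment score distribution
#'
#' @param gi_values combined strain GI scores of one experiment (non-finite
#'   values are dropped).
#' @param params a [hitcall_params()].
#' @return List with `median`, `niqr` and the three thresholds
#'   `single_tag`, `averaged`, `per_tag` (median + k x NIQR).
#' @export
gi_cutoffs <- function(gi_values, params = hitcall_params()) {
  rs <- robust_stats(gi_values)
  list(
    median = rs$median, niqr = rs$niqr,
    single_tag = rs$median + params$single_tag_mult * rs$niqr,
    averaged = rs$median + params$averaged_mult * rs$niqr,
    per_tag = rs$median + params$per_tag_mult * rs$niqr
  )
}

#' Call sensitive hits across replicate experiments
#'
#' Per experiment, a gene passes when (i) its GI clears the distribution
#' cutoff — for a single scored tag, that tag's GI at or above
#' median + 3 x NIQR; for two scored tags, the averaged GI at or above
#' median + 2.5 x NIQR with each tag at or above median + 2 x NIQR — and
#' (ii) at least one of its tags has a [g_test()] p-value below
#' `params$p_cutoff`, computed from the raw control/treatment counts at the
#' last weighted generation. A gene is a sensitive hit when it passes in at
#' least `params$min_experiments` experiments. Boundary comparisons are
#' inclusive.
#'
#' @param experiments list of `gi_table`s from [score_experiment()] (the
#'   per-tag count data for the significance filter travel in their `gtest`
#'   attribute). Names label the experiments; unnamed lists get `exp1`,
#'   `exp2`, ...
#' @param params a [hitcall_params()].
#' @return Data frame of class `hit_table`: `gene_id`, per-experiment
#'   columns `gi_<name>` and `pass_<name>`, `n_pass`, and `hit_status`
#'   (`sensitive` or `none`).
#' @export
call_sensitive <- function(experiments, params = hitcall_params()) {
  stopifnot(length(experiments) >= 1)
  enames <- names(experiments) %||% sprintf("exp%d", seq_along(experiments))
  enames[!nzchar(enames)] <- sprintf("exp%d", which(!nzchar(enames)))
  genes <- experiments[[1]]$gene_id
  for (e in experiments[-1]) genes <- union(genes, e$gene_id)

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  n_pass <- integer(length(genes))
  for (k in seq_along(experiments)) {
    g <- experiments[[k]]
    cut <- gi_cutoffs(g$gi, params)
    i <- match(genes, g$gene_id)
    up <- g$gi_up[i]
    dn <- g$gi_dn[i]
    comb <- g$gi[i]
    ntags <- (!is.na(up)) + (!is.na(dn))
    single_val <- ifelse(is.na(up), dn, up)
    pass_gi <- rep(FALSE, length(genes))
    one <- which(ntags == 1)
    pass_gi[one] <- single_val[one] >= cut$single_tag
    two <- which(ntags == 2)
    pass_gi[two] <- comb[two] >= cut$averaged &
      up[two] >= cut$per_tag & dn[two] >= cut$per_tag

    gt <- attr(g, "gtest")
    if (is.null(gt)) {
      stop("experiment '", enames[k],
           "' carries no count data for the significance filter")
    }
    pv <- g_test(gt$control, gt$treatment, gt$control_total,
                 gt$treatment_total, williams = params$williams)$p
    minp <- tapply(pv, gt$gene_id, min)
    minp <- as.numeric(minp[match(genes, names(minp))])
    pass_p <- !is.na(minp) & minp < params$p_cutoff

    pass <- pass_gi & pass_p
    pass[is.na(pass)] <- FALSE
    out[[paste0("gi_", enames[k])]] <- comb
    out[[paste0("pass_", enames[k])]] <- pass
    n_pass <- n_pass + pass
  }
  out$n_pass <- n_pass
  out$hit_status <- ifelse(n_pass >= params$min_experiments, "sensitive", "none")
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Rank strains by ascending GI to surface resistance candidates
#'
#' The strongest resistance candidates have the most negative GI — they were
#' enriched rather than depleted under treatment. No formal multi-experiment
#' test is applied; this is a stable ranking (ties broken by gene id) with a
#' descriptive flag at `params$resistant_flag_cutoff` (inclusive).
#'
#' @param gi_table a `gi_table` from [score_experiment()].
#' @param params a [hitcall_params()].
#' @return Data frame `rank`, `gene_id`, `gi`, `flagged`, ascending in GI.
#' @export
rank_resistant <- function(gi_table, params = hitcall_params()) {
  d <- gi_table[is.finite(gi_table$gi), c("gene_id", "gi")]
  if (!nrow(d)) stop("no strain has a defined GI score")
  o <- order(d$gi, d$gene_id)
  out <- data.frame(
    rank = seq_len(nrow(d)),
    gene_id = d$gene_id[o],
    gi = d$gi[o],
    flagged = d$gi[o] <= params$resistant_flag_cutoff,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write hit / resistant tables as TSV
#'
#' @param x a `hit_table` from [call_sensitive()] or the ranking from
#'   [rank_resistant()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(x, path) {
  .write_tsv(as.data.frame(x), path, "hits")
}
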