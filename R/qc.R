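#' Extract one sample's normalized counts as a named vector
#'
#' Convenience accessor for the QC statistics: normalizes the count table
#' (per sample and tag class) and returns the chosen stratum keyed by gene.
#'
#' @param x a [count_table()] or count data frame.
#' @param sample sample name.
#' @param tag_class `"up"` or `"dn"`.
#' @param total normalization total (default one million).
#' @return Named numeric vector of normalized counts.
#' @export
sample_norm_vector <- function(x, sample, tag_class = "up", total = 1e6) {
  df <- as_count_df(x)
  df <- df[df$sample == sample, , drop = FALSE]
  if (!nrow(df)) stop("no counts for sample '", sample, "'")
  df <- normalize_counts(df, total)
  df <- df[df$tag_class == tag_class, , drop = FALSE]
  setNames(df$norm, df$gene_id)
}

#' Pearson correlation of two replicate samples
#'
#' Computed on log10 normalized counts over the barcodes positive in both
#' samples (barcodes absent from either are excluded, mirroring the "> 0 in
#' both samples" convention for replicate scatter plots).
#'
#' @param norm_a,norm_b named vectors of normalized counts (e.g. from
#'   [sample_norm_vector()]).
#' @param log correlate log10 values (default) or the raw normalized scale.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(norm_a, norm_b, log = TRUE) {
  shared <- intersect(names(norm_a), names(norm_b))
  a <- norm_a[shared]
  b <- norm_b[shared]
  keep <- a > 0 & b > 0
  if (sum(keep) < 3) stop("fewer than 3 barcodes positive in both samples")
  if (log) {
    cor(log10(a[keep]), log10(b[keep]))
  } else {
    cor(a[keep], b[keep])
  }
}

#' Agreement between uptag- and dntag-derived log ratios
#'
#' For strains with both tags uniquely assignable, computes per-tag log2
#' ratios of normalized counts (control over treatment) and their Pearson
#' correlation. Strains qualify when both tags have at least `min_control`
#' raw reads in the control sample and more than zero raw reads in the
#' treatment sample.
#'
#' @param counts a [count_table()] or count data frame containing both
#'   samples.
#' @param catalog a [catalog()] object.
#' @param control_sample,treatment_sample sample names.
#' @param min_control minimum raw control reads per tag (default 12).
#' @param total normalization total.
#' @return List with `n` (qualifying strains) and `r` (Pearson correlation
#'   of uptag vs dntag log2 ratios).
#' @export
tag_agreement <- function(counts, catalog, control_sample, treatment_sample,
                          min_control = 12, total = 1e6) {
  df <- as_count_df(counts)
  df <- df[df$sample %in% c(control_sample, treatment_sample), , drop = FALSE]
  norm <- normalize_counts(df, total)
  lk <- catalog$lookup
  both <- intersect(
    lk$gene_id[lk$tag_class == "up"], lk$gene_id[lk$tag_class == "dn"]
  )
  grab <- function(s, cls, col) {
    ss <- norm[norm$sample == s & norm$tag_class == cls, ]
    v <- ss[[col]][match(both, ss$gene_id)]
    v[is.na(v)] <- 0
    v
  }
  c_up_raw <- grab(control_sample, "up", "count")
  c_dn_raw <- grab(control_sample, "dn", "count")
  t_up_raw <- grab(treatment_sample, "up", "count")
  t_dn_raw <- grab(treatment_sample, "dn", "count")
  keep <- c_up_raw >= min_control & c_dn_raw >= min_control &
    t_up_raw > 0 & t_dn_raw > 0
  if (sum(keep) < 3) stop("fewer than 3 strains satisfy the tag-agreement filter")
  ratio_up <- log2(grab(control_sample, "up", "norm")[keep] /
                     grab(treatment_sample, "up", "norm")[keep])
  ratio_dn <- log2(grab(control_sample, "dn", "norm")[keep] /
                     grab(treatment_sample, "dn", "norm")[keep])
  list(n = sum(keep), r = cor(ratio_up, ratio_dn))
}

#' Linearity of spike-in quantification
#'
#' Least-squares fit of log10 normalized reads against log10 spike-in cell
#' ratio. On noise-free proportional data the slope is exactly 1. Levels
#' with nonpositive reads are dropped with a warning.
#'
#' @param norm_reads normalized read counts per spike-in level.
#' @param ratios spike-in cell ratios (e.g. 1/200 ... 1/20000).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
spikein_fit <- function(norm_reads, ratios) {
  stopifnot(length(norm_reads) == length(ratios), all(ratios > 0))
  keep <- norm_reads > 0
  if (any(!keep)) {
    warning(sum(!keep), " spike-in level(s) with nonpositive reads dropped")
  }
  if (length(unique(ratios[keep])) < 2) {
    stop("need at least 2 distinct spike-in ratios with positive reads")
  }
  x <- log10(ratios[keep])
  y <- log10(norm_reads[keep])
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n = sum(keep)
  )
}

#' Uncentered-correlation distance matrix
#'
#' Similarity about zero, `s(x, y) = sum(x y) / sqrt(sum(x^2) sum(y^2))`,
#' turned into the distance `1 - s` (range 0..2). A zero-norm profile has no
#' direction; its similarity to everything is defined as 0 (distance 1) and
#' reported via a message.
#'
#' @param mat numeric matrix; distances are between rows.
#' @return A `dist` object over the rows.
#' @export
uncentered_dist <- function(mat) {
  mat <- as.matrix(mat)
  cp <- tcrossprod(mat)
  nrm <- sqrt(diag(cp))
  zero <- nrm == 0
  if (any(zero)) {
    message(
      "zero-norm profile(s), similarities set to 0: ",
      paste(rownames(mat)[zero] %||% which(zero), collapse = ", ")
    )
    nrm[zero] <- 1
  }
  s <- cp / outer(nrm, nrm)
  s[zero, ] <- 0
  s[, zero] <- 0
  as.dist(1 - s)
}

#' Hierarchical clustering of GI profiles
#'
#' Agglomerative average-linkage clustering of the gene-by-condition GI
#' matrix under the uncentered-correlation distance, applied to rows (genes)
#' and columns (conditions). Missing values are imputed (default 0 = "no
#' fitness change") before clustering, with a message stating how many cells
#' were filled.
#'
#' @param mat numeric matrix (>= 2 rows, >= 2 columns), typically genes x
#'   conditions of GI scores.
#' @param impute value substituted for missing cells.
#' @return List with `rows` and `cols`, each an [stats::hclust] tree.
#' @export
cluster_profiles <- function(mat, impute = 0) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  nas <- is.na(mat)
  if (any(nas)) {
    message(sum(nas), " missing value(s) imputed as ", impute)
    mat[nas] <- impute
  }
  list(
    rows = hclust(uncentered_dist(mat), method = "average"),
    cols = hclust(uncentered_dist(t(mat)), method = "average")
  )
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via the standard hclust-to-phylo
#' conversion.
#'
#' @param hc an [stats::hclust] tree (e.g. from [cluster_profiles()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
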