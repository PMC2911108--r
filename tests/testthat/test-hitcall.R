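test_that("robust stats use interpolated quartiles and the 0.7413 scaling", {
  rs <- robust_stats(rep(2.5, 10))
  expect_equal(rs$median, 2.5)
  expect_equal(rs$niqr, 0)

  # a vector whose quartiles are the exact standard-normal quartiles
  q <- 0.6744898
  rs <- robust_stats(c(-1, -q, 0, q, 1))
  expect_equal(rs$niqr, 1, tolerance = 1e-3)

  rs <- robust_stats(1:5)
  expect_equal(rs$iqr, 2)
  expect_equal(rs$niqr, 1.4826)
  expect_error(robust_stats(3), "at least 2")
  expect_error(robust_stats(c(1, NA, Inf)), "at least 2")
})

test_that("the G statistic matches its definition and the chi-square tail", {
  # equal proportions: observed = expected
  r <- g_test(100, 50, 1000, 500)
  expect_equal(r$G, 0)
  expect_equal(r$p, 1)

  r <- g_test(50, 25, 1e6, 1e6)
  expect_equal(r$G, 8.50, tolerance = 0.01)
  expect_equal(r$p, 0.0036, tolerance = 0.01)

  r <- g_test(0, 0, 1000, 1000)
  expect_equal(r$G, 0)
  expect_equal(r$p, 1)

  expect_error(g_test(5, 5, 0, 10))
  expect_error(g_test(11, 5, 10, 10))
})

test_that("the G statistic equals the binomial likelihood-ratio statistic", {
  # independent oracle: 2*log(L1/L0) for two binomial proportions
  lrt <- function(a, b, ta, tb) {
    ll <- function(k, n, p) {
      dbinom(k, n, p, log = TRUE)
    }
    p1 <- a / ta
    p2 <- b / tb
    p0 <- (a + b) / (ta + tb)
    2 * (ll(a, ta, p1) + ll(b, tb, p2) - ll(a, ta, p0) - ll(b, tb, p0))
  }
  set.seed(61)
  for (i in 1:50) {
    ta <- sample(10:5000, 1)
    tb <- sample(10:5000, 1)
    a <- rbinom(1, ta, runif(1, 0.01, 0.9))
    b <- rbinom(1, tb, runif(1, 0.01, 0.9))
    expect_lt(abs(g_test(a, b, ta, tb)$G - lrt(a, b, ta, tb)), 1e-9)
  }
})

test_that("null count tables produce approximately uniform small p-values", {
  # identical multinomial proportions in control and treatment
  set.seed(62)
  n_bc <- 1e4
  p <- simulate_initial_abundances(n_bc, sigma = 1)
  a <- as.integer(rmultinom(1, 1e6, p))
  b <- as.integer(rmultinom(1, 1e6, p))
  pv <- g_test(a, b, 1e6, 1e6)$p
  frac <- mean(pv < 0.005)
  # binomial 99% band around 0.005 (chi-square approximation is rough for
  # the low-count barcodes, so the band is the assertion, not exactness)
  se <- sqrt(0.005 * 0.995 / n_bc)
  expect_lt(abs(frac - 0.005), 2.58 * se + 0.002)
})

test_that("GI cutoffs are median + k*NIQR and translate with the distribution", {
  x <- c(-0.1, 0, 0, 0.1, 0.2)
  rs <- robust_stats(x)
  cut <- gi_cutoffs(x)
  expect_equal(cut$single_tag, rs$median + 3 * rs$niqr)
  expect_equal(cut$averaged, rs$median + 2.5 * rs$niqr)
  expect_equal(cut$per_tag, rs$median + 2 * rs$niqr)

  cut_shift <- gi_cutoffs(x + 0.3)
  expect_equal(cut_shift$single_tag, cut$single_tag + 0.3)
  expect_equal(cut_shift$averaged, cut$averaged + 0.3)
  expect_equal(cut_shift$per_tag, cut$per_tag + 0.3)
})

# Hand-built gi_table with a controllable gtest attribute.
make_gi_table <- function(gene_id, gi_up, gi_dn, p_small) {
  gi <- strain_gi(gi_up, gi_dn)
  tab <- data.frame(
    gene_id = gene_id, gi_up = gi_up, gi_dn = gi_dn, gi = gi,
    status = ifelse(is.na(gi), "no_barcode", "ok"),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("gi_table", "data.frame")
  # p_small genes get a strongly significant count contrast, others a flat one
  gt <- data.frame(
    gene_id = gene_id, tag_class = "up",
    control = ifelse(gene_id %in% p_small, 500, 100),
    treatment = ifelse(gene_id %in% p_small, 100, 100),
    control_total = 1e6, treatment_total = 1e6,
    stringsAsFactors = FALSE
  )
  attr(tab, "gtest") <- gt
  tab
}

test_that("call_sensitive enforces the dual cutoffs and the 2-of-3 rule", {
  genes <- sprintf("g%02d", 1:20)
  # background GIs near 0; g01 high in 2 experiments, g02 high in only 1;
  # g03 high everywhere but never significant
  base_up <- seq(-0.05, 0.05, length.out = 20)
  base_dn <- rev(base_up)
  mk <- function(hot, p_small) {
    up <- base_up
    dn <- base_dn
    up[match(hot, genes)] <- 1
    dn[match(hot, genes)] <- 1
    make_gi_table(genes, up, dn, p_small)
  }
  exps <- list(
    A = mk(c("g01", "g03"), p_small = c("g01", "g02")),
    B = mk(c("g01", "g02", "g03"), p_small = c("g01", "g02")),
    C = mk(c("g03"), p_small = c("g01", "g02"))
  )
  hits <- call_sensitive(exps)
  expect_equal(hits$hit_status[hits$gene_id == "g01"], "sensitive")  # 2 of 3
  expect_equal(hits$hit_status[hits$gene_id == "g02"], "none")       # 1 of 3
  expect_equal(hits$hit_status[hits$gene_id == "g03"], "none")       # no p pass
  expect_equal(hits$n_pass[hits$gene_id == "g01"], 2L)
  expect_true(all(hits$hit_status[!hits$gene_id %in% c("g01")] == "none"))

  # all-zero GI: no hits (NIQR 0 but p filter alone cannot pass a flat GI...
  # every gene sits exactly at the cutoff = median = 0, passes GI, but only
  # p_small genes pass p; construct with no significant gene)
  flat <- make_gi_table(genes, rep(0, 20), rep(0, 20), p_small = character(0))
  hits0 <- call_sensitive(list(flat, flat, flat))
  expect_true(all(hits0$hit_status == "none"))
})

test_that("single-tag genes face the 3*NIQR cutoff, dual-tag genes the 2.5/2 pair", {
  genes <- sprintf("g%02d", 1:21)
  v <- 0.105  # sits between the averaged (2.5*NIQR) and single-tag (3*NIQR) cutoffs
  up <- c(seq(-0.05, 0.05, length.out = 20), v)
  tab_dual <- make_gi_table(genes, up, up, p_small = "g21")
  cut <- gi_cutoffs(tab_dual$gi)
  expect_lt(cut$averaged, v)
  expect_gt(cut$single_tag, v)
  expect_lt(cut$per_tag, v)

  hits_dual <- call_sensitive(list(tab_dual, tab_dual),
                              hitcall_params(min_experiments = 2))
  expect_equal(hits_dual$hit_status[hits_dual$gene_id == "g21"], "sensitive")

  # same scores but dntag missing: the single-tag branch is stiffer and fails
  tab_single <- make_gi_table(genes, up, rep(NA_real_, 21), p_small = "g21")
  expect_gt(gi_cutoffs(tab_single$gi)$single_tag, v)
  hits_single <- call_sensitive(list(tab_single, tab_single),
                                hitcall_params(min_experiments = 2))
  expect_equal(hits_single$hit_status[hits_single$gene_id == "g21"], "none")

  # experiments without count data cannot run the significance filter
  no_gt <- tab_dual
  attr(no_gt, "gtest") <- NULL
  expect_error(call_sensitive(list(no_gt)), "no count data")
})

test_that("hit calling is monotone in GI under frozen thresholds", {
  genes <- sprintf("g%02d", 1:20)
  up <- seq(-0.05, 0.05, length.out = 20)
  tab <- make_gi_table(genes, up, up, p_small = genes)
  cut <- gi_cutoffs(tab$gi)
  bumped <- tab
  i <- 7
  bumped$gi_up[i] <- bumped$gi_dn[i] <- bumped$gi[i] <- cut$single_tag + 1
  # with thresholds frozen at the original distribution, the bumped gene must
  # pass everything it passed before and more
  pass_before <- tab$gi[i] >= cut$averaged
  pass_after <- bumped$gi[i] >= cut$averaged
  expect_true(!pass_before || pass_after)
  expect_true(pass_after)
})

test_that("resistant ranking is ascending, stable, and flags at -0.5 inclusively", {
  tab <- data.frame(
    gene_id = c("gx", "gy", "gz", "gw"),
    gi_up = c(0.2, -0.9, 0, -0.5), gi_dn = c(0.2, -0.9, 0, -0.5),
    gi = c(0.2, -0.9, 0, -0.5), status = "ok", stringsAsFactors = FALSE
  )
  class(tab) <- c("gi_table", "data.frame")
  r <- rank_resistant(tab)
  expect_equal(r$gene_id, c("gy", "gw", "gz", "gx"))
  expect_equal(r$flagged, c(TRUE, TRUE, FALSE, FALSE))  # -0.5 inclusive

  # ties break by gene id
  tab$gi <- c(0, 0, 0, 0)
  r2 <- rank_resistant(tab)
  expect_equal(r2$gene_id, sort(tab$gene_id))

  tab$gi <- NA_real_
  expect_error(rank_resistant(tab), "no strain")
})

test_that("a planted fitness-advantage strain ranks first by GI", {
  cat <- simulate_catalog(200, seed = 71)
  fit <- fitness_profile(cat$records$gene_id, c("ctrl", "drug"))
  fit["mut0042", "drug"] <- 1.5
  cfg <- sim_config(n_strains = 200, generations = 5, depth = 1e6, seed = 72)
  cnt <- simulate_pool_experiment(cat, fit, cfg)
  des <- experiment_design("ctrl", "drug", 5, weights = 1)
  gi <- score_experiment(cnt, cat, des)
  r <- rank_resistant(gi)
  expect_equal(r$gene_id[1], "mut0042")
  expect_true(r$gi[1] < -0.4)
})
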