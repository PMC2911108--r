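test_that("normalization scales every sample/tag-class stratum to the target total", {
  df <- manual_counts(list(s1 = list(up = c(a = 2, b = 3, c = 5))))
  norm <- normalize_counts(df)
  expect_equal(norm$norm, c(200000, 300000, 500000))

  # already at one million: unchanged
  df2 <- manual_counts(list(s1 = list(up = c(a = 4e5, b = 6e5))))
  expect_equal(normalize_counts(df2)$norm, c(4e5, 6e5))

  # sums equal the target per stratum
  df3 <- manual_counts(list(
    s1 = list(up = c(a = 7, b = 13), dn = c(a = 1, b = 2)),
    s2 = list(up = c(a = 10, b = 1))
  ))
  norm3 <- normalize_counts(df3)
  sums <- tapply(norm3$norm, paste(norm3$sample, norm3$tag_class), sum)
  expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6))

  df4 <- manual_counts(list(s1 = list(up = c(a = 0, b = 0))))
  expect_error(normalize_counts(df4), "no matched reads.*s1 up")
})

test_that("fold change applies the pseudocount to counts and raw totals to scales", {
  expect_equal(compute_fc(10, 10, 1000, 1000), 1)
  expect_equal(compute_fc(31, 0, 1000, 1000), 32)
  expect_equal(compute_fc(0, 31, 1000, 1000), 1 / 32)
  # unequal depths rescale through the raw totals
  expect_equal(compute_fc(10, 20, 1000, 2000), 11 / (21 / 2))
  expect_true(compute_fc(0, 0, 5, 5) > 0)
  expect_error(compute_fc(1, 1, 0, 10))
})

test_that("the GI score is the weighted mean of per-generation log2 depletion rates", {
  w <- setNames(rep(1 / 3, 3), 3:5)
  expect_equal(gi_score(setNames(c(1, 1, 1), 3:5), w), 0)
  expect_equal(gi_score(setNames(2^(3:5), 3:5), w), 1)
  # single-generation drug design: GI = log2(FC_5)/5
  expect_equal(gi_score(c(`5` = 32), c(`5` = 1)), 1)
  # missing FC at a weighted generation -> undefined, not an error
  expect_true(is.na(gi_score(setNames(c(2, NA, 2), 3:5), w)))
  # zero-weight generations may be absent entirely
  w5 <- setNames(c(0, 0, 0, 0, 1), 1:5)
  expect_equal(gi_score(c(`5` = 4), w5), log2(4) / 5)
  expect_error(gi_score(c(`5` = 1), c(`5` = 0.9)), "sum to 1")
})

test_that("per-tag scores combine by averaging, with single-tag fallback", {
  expect_equal(strain_gi(0.4, 0.6), 0.5)
  expect_equal(strain_gi(0.4, NA), 0.4)
  expect_equal(strain_gi(NA, 0.7), 0.7)
  expect_true(is.na(strain_gi(NA, NA)))
  expect_equal(strain_gi(c(0.4, NA), c(0.6, 0.2)), c(0.5, 0.2))
})

test_that("score_experiment filters low-coverage control tags and flags statuses", {
  recs <- toy_records()
  cat <- catalog(recs)
  # gA uptag has 11 control reads at g5 -> uptag excluded, dntag carries
  cnts <- manual_counts(list(
    ctrl_g5 = list(up = c(gA = 11, gB = 500, gC = 489),
                   dn = c(gA = 300, gB = 400, gC = 300)),
    trt_g5 = list(up = c(gA = 100, gB = 450, gC = 450),
                  dn = c(gA = 300, gB = 400, gC = 300))
  ))
  des <- experiment_design("ctrl", "trt", 5, weights = 1)
  gi <- score_experiment(cnts, cat, des)
  expect_true(is.na(gi$gi_up[gi$gene_id == "gA"]))
  expect_false(is.na(gi$gi_dn[gi$gene_id == "gA"]))
  expect_equal(gi$status, rep("ok", 3))
  expect_equal(gi$gi[gi$gene_id == "gA"], gi$gi_dn[gi$gene_id == "gA"])

  # both tags below threshold -> insufficient_control_reads
  cnts2 <- manual_counts(list(
    ctrl_g5 = list(up = c(gA = 5, gB = 500, gC = 495),
                   dn = c(gA = 5, gB = 500, gC = 495)),
    trt_g5 = list(up = c(gA = 5, gB = 500, gC = 495),
                  dn = c(gA = 5, gB = 500, gC = 495))
  ))
  gi2 <- score_experiment(cnts2, cat, des)
  expect_equal(gi2$status[gi2$gene_id == "gA"], "insufficient_control_reads")

  # missing sample is fatal
  des2 <- experiment_design("ctrl", "missing", 5, weights = 1)
  expect_error(score_experiment(cnts, cat, des2), "lacks sample")
})

test_that("strains without a usable barcode are reported, not scored", {
  recs <- toy_records()
  recs$uptag[2] <- recs$uptag[1]   # gA/gB uptags collide
  recs$dntag[1] <- recs$dntag[2]   # gA/gB dntags collide -> both tagless
  cat <- catalog(recs)
  cnts <- manual_counts(list(
    ctrl_g5 = list(up = c(gC = 100), dn = c(gC = 100)),
    trt_g5 = list(up = c(gC = 100), dn = c(gC = 100))
  ))
  des <- experiment_design("ctrl", "trt", 5, weights = 1)
  gi <- score_experiment(cnts, cat, des)
  expect_equal(gi$status[gi$gene_id %in% c("gA", "gB")],
               rep("no_barcode", 2))
  expect_equal(gi$status[gi$gene_id == "gC"], "ok")
})

test_that("swapping control and treatment negates every defined GI", {
  cat <- simulate_catalog(40, seed = 51)
  fit <- fitness_profile(cat$records$gene_id, c("A", "B"))
  fit[1:5, "B"] <- 0.3
  cfg <- sim_config(n_strains = 40, generations = c(3, 4, 5), depth = 1e5,
                    seed = 52)
  cnt <- simulate_pool_experiment(cat, fit, cfg)
  fwd <- experiment_design("A", "B", c(3, 4, 5))
  rev <- experiment_design("B", "A", c(3, 4, 5))
  gi_f <- score_experiment(cnt, cat, fwd)
  gi_r <- score_experiment(cnt, cat, rev)
  # antisymmetry is exact where both directions survive the control filter
  both <- !is.na(gi_f$gi) & !is.na(gi_r$gi)
  expect_true(any(both))
  expect_equal(gi_f$gi[both], -gi_r$gi[both])
})

test_that("raising treatment counts never raises a strain's GI", {
  set.seed(53)
  for (rep_i in 1:20) {
    t0 <- sample(0:100, 1)
    fc1 <- compute_fc(50, t0, 1000, 1000)
    fc2 <- compute_fc(50, t0 + sample(1:50, 1), 1000, 1000)
    w <- c(`5` = 1)
    expect_lte(gi_score(c(`5` = fc2), w), gi_score(c(`5` = fc1), w))
  }
})

test_that("FC and GI are invariant to depth rescaling up to the pseudocount", {
  fc_a <- compute_fc(200, 100, 1e4, 1e4, scoring_params(pseudocount = 1))
  # scale counts by 10x with the pseudocount scaled accordingly: exact
  fc_b <- compute_fc(2000, 1000, 1e5, 1e5, scoring_params(pseudocount = 10))
  expect_equal(fc_b, fc_a)
  # with the pseudocount held at 1 the effect is only the pseudocount's
  fc_c <- compute_fc(2000, 1000, 1e5, 1e5, scoring_params(pseudocount = 1))
  expect_equal(fc_c, fc_a, tolerance = 0.01)
  expect_false(identical(fc_c, fc_a))
  # and the inversion identity: FC = 2^(GI * g) for a single generation
  for (fc in c(0.1, 0.5, 1, 3, 32)) {
    gi <- gi_score(c(`4` = fc), c(`4` = 1))
    expect_equal(2^(gi * 4), fc)
  }
})
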