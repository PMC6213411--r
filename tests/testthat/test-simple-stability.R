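test_that("BestKeeper descriptives match first-principles computation", {
  ct <- matrix(c(20, 21, 22, 23, 24,
                 30, 29, 31, 30, 30,
                 25, 25, 26, 24, 25), 5, 3,
               dimnames = list(paste0("s", 1:5), c("gA", "gB", "gC")))
  es <- toy_ct_set(ct, genes = colnames(ct))
  bk <- bestkeeper(es)
  oracle <- bf_bestkeeper(ct)
  expect_equal(bk$gene_stats$geo_mean_ct, unname(oracle$geo_mean),
               tolerance = 1e-12)
  expect_equal(bk$gene_stats$ar_mean_ct, unname(oracle$ar_mean),
               tolerance = 1e-12)
  expect_equal(bk$gene_stats$sd_ct, unname(oracle$mad), tolerance = 1e-12)
  expect_equal(bk$gene_stats$cv_pct, unname(oracle$cv_pct), tolerance = 1e-12)
  expect_equal(unname(bk$index), unname(oracle$index), tolerance = 1e-12)
  expect_equal(bk$gene_stats$pearson_r, unname(oracle$r), tolerance = 1e-12)
  expect_true(all(bk$gene_stats$min_ct <= bk$gene_stats$geo_mean_ct &
                    bk$gene_stats$geo_mean_ct <= bk$gene_stats$max_ct))

  # and on 100 random instances
  for (s in 1:100) {
    ct <- rand_ct(6, 4, seed = 300 + s)
    bk <- bestkeeper(toy_ct_set(ct))
    oracle <- bf_bestkeeper(ct)
    expect_equal(bk$gene_stats$sd_ct, unname(oracle$mad), tolerance = 1e-12)
    expect_equal(bk$gene_stats$pearson_r, unname(oracle$r), tolerance = 1e-12)
  }
})

test_that("the index log equals the mean per-gene log Ct", {
  es <- toy_ct_set(rand_ct(8, 5, seed = 77))
  bk <- bestkeeper(es)
  expect_equal(log(unname(bk$index)), unname(rowMeans(log(es$ct))),
               tolerance = 1e-12)
})

test_that("constant and duplicated genes behave at the edges", {
  ct <- cbind(flat = rep(22, 5), gB = c(20, 21, 22, 23, 24),
              gC = c(25, 24.5, 26, 25.5, 24))
  es <- toy_ct_set(ct)
  bk <- bestkeeper(es)
  flat <- bk$gene_stats[bk$gene_stats$gene == "flat", ]
  expect_equal(flat$sd_ct, 0)
  expect_equal(flat$cv_pct, 0)
  expect_false(flat$unstable)
  expect_true(is.na(flat$pearson_r))

  # a gene duplicated across the whole panel IS the index: r = 1 exactly
  dup <- toy_ct_set(cbind(d1 = ct[, "gB"], d2 = ct[, "gB"], d3 = ct[, "gB"]))
  expect_equal(bestkeeper(dup)$gene_stats$pearson_r, rep(1, 3),
               tolerance = 1e-12)

  expect_error(bestkeeper(toy_ct_set(cbind(c(-1, 2, 3), c(1, 2, 3)))),
               "nonpositive")
})

test_that("the dispersion flag, convention switch and filtered index work", {
  set.seed(10)
  ct <- cbind(stable = rnorm(10, 20, 0.2), wild = rnorm(10, 30, 3),
              mid = rnorm(10, 25, 0.5))
  es <- toy_ct_set(ct, genes = colnames(ct))
  bk <- bestkeeper(es)
  expect_identical(bk$gene_stats$unstable, bk$gene_stats$sd_ct > 1)

  bk_sd <- bestkeeper(es, sd_method = "sd")
  expect_equal(bk_sd$gene_stats$sd_ct, apply(ct, 2, sd),
               tolerance = 1e-12, ignore_attr = TRUE)

  bk_f <- bestkeeper(es, filtered = TRUE)
  keep <- bk_f$gene_stats$gene[!bk_f$gene_stats$unstable]
  expect_equal(log(unname(bk_f$index)),
               unname(rowMeans(log(ct[, keep, drop = FALSE]))),
               tolerance = 1e-12)
})

test_that("delta-Ct scores match brute force and are shift-invariant", {
  for (s in 1:100) {
    ct <- rand_ct(6, 4, seed = 400 + s)
    res <- delta_ct_stability(toy_ct_set(ct))
    expect_equal(res$scores, bf_delta_ct(ct), tolerance = 1e-12)
    expect_equal(res$pair_sd, t(res$pair_sd))
  }
  ct <- rand_ct(8, 5, seed = 9)
  set.seed(9); shifts <- runif(8, -4, 4)
  expect_equal(delta_ct_stability(toy_ct_set(ct))$scores,
               delta_ct_stability(toy_ct_set(ct + shifts))$scores,
               tolerance = 1e-12)

  # genes differing by a constant have pair SD zero
  ct2 <- cbind(g1 = c(20, 22, 21), g2 = c(23, 25, 24), g3 = c(20, 25, 22))
  res2 <- delta_ct_stability(toy_ct_set(ct2, genes = colnames(ct2)))
  expect_equal(res2$pair_sd["g1", "g2"], 0, tolerance = 1e-12)

  expect_error(delta_ct_stability(toy_ct_set(rand_ct(5, 2, 1))), ">= 3 genes")
})

test_that("CV reproduces the published worked examples at 3 decimals", {
  pooled <- panel_two_point_set("pooled")
  cv_pooled <- cv_stability(pooled)
  expect_equal(round(cv_pooled$cv[cv_pooled$gene == "YWHAZ"], 3), 0.046)
  acid <- panel_two_point_set("acidic")
  cv_acid <- cv_stability(acid)
  expect_equal(round(cv_acid$cv[cv_acid$gene == "GAPDH"], 3), 0.034)
})

test_that("CV is scale-invariant but not shift-invariant", {
  ct <- rand_ct(9, 4, seed = 12)
  base <- cv_stability(toy_ct_set(ct))$cv
  expect_equal(cv_stability(toy_ct_set(ct * 3.7))$cv, base,
               tolerance = 1e-12)
  shifted <- cv_stability(toy_ct_set(ct + 5))$cv
  expect_true(all(shifted < base))  # larger mean, same SD

  flat <- cv_stability(toy_ct_set(cbind(rep(20, 4), 21:24)))
  expect_equal(flat$cv[1], 0)
})
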