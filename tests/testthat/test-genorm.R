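test_that("the comparative-Ct transform calibrates to the per-gene minimum", {
  es <- toy_ct_set(cbind(c(10, 11, 12), c(20, 21, 22)))
  rq <- relative_quantities(es)
  expect_equal(unname(rq$q[, 1]), c(1, 0.5, 0.25))
  expect_equal(unname(rq$q[, 2]), c(1, 0.5, 0.25))
  expect_equal(apply(rq$q, 2, max), c(g1 = 1, g2 = 1))

  # efficiency other than 2 changes the base, not the calibrator
  rq10 <- relative_quantities(es, efficiency = 10)
  expect_equal(unname(rq10$q[, 1]), 10^-(0:2))

  es_na <- toy_ct_set(cbind(c(10, NA), c(20, 21)))
  expect_error(relative_quantities(es_na), "missing Ct")
  expect_error(relative_quantities(es, efficiency = 1), "> 1")
})

test_that("perfectly co-varying genes have M = 0", {
  es <- toy_ct_set(cbind(c(10, 11, 12), c(20, 21, 22)))
  m <- genorm_m(relative_quantities(es))
  expect_equal(unname(m), c(0, 0), tolerance = 1e-12)
})

test_that("M matches the brute-force pairwise definition", {
  # the fixed 4-sample x 3-gene worked example
  q <- rbind(c(1, 1, 1), c(.5, .5, 1), c(.25, 1, 1), c(1, .5, .5))
  es <- toy_ct_set(20 - log2(q))
  rq <- relative_quantities(es)
  expect_equal(rq$q, es$ct * 0 + q, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(genorm_m(rq), bf_genorm_m(rq$q), tolerance = 1e-12)

  # and 100 random instances
  for (s in 1:100) {
    es <- toy_ct_set(rand_ct(5, 6, seed = s))
    rq <- relative_quantities(es)
    expect_equal(genorm_m(rq), bf_genorm_m(rq$q), tolerance = 1e-12)
  }
})

test_that("stepwise exclusion performs k-2 removals and finds planted pairs", {
  set.seed(99)
  base <- matrix(runif(30, 18, 30), 6, 5)
  base[, 2] <- base[, 1] - 3        # exact noise-free proportional pair
  es <- toy_ct_set(base)
  rk <- genorm_ranking(relative_quantities(es))
  expect_length(rk$removal_order, 3)   # k - 2
  expect_setequal(rk$ranking[1:2], c("g1", "g2"))
  expect_equal(unname(rk$ranks[c("g1", "g2")]), c(1.5, 1.5))

  # with k = 3 the single removal is the highest-M gene of the full panel
  es3 <- toy_ct_set(rand_ct(8, 3, seed = 4))
  rq3 <- relative_quantities(es3)
  rk3 <- genorm_ranking(rq3)
  expect_identical(rk3$removal_order, names(which.max(genorm_m(rq3))))
})

test_that("a spiked condition shift is removed first on homoscedastic panels", {
  base <- homoscedastic_config()
  hits <- 0
  for (s in 1:100) {
    es <- simulate_ct(spike_unstable_gene(base, "PPIA", 3), seed = s)
    rk <- genorm_ranking(relative_quantities(es))
    hits <- hits + (rk$removal_order[1] == "PPIA")
  }
  expect_gte(hits, 95)
})

test_that("M grows with the noise injected into a single gene", {
  avg_m <- sapply(c(0.2, 0.8, 2), function(extra_sd) {
    mean(sapply(1:30, function(s) {
      cfg <- homoscedastic_config(sd = 0.3)
      cfg$sd_ct["YWHAZ", ] <- sqrt(0.3^2 + extra_sd^2)
      genorm_m(relative_quantities(simulate_ct(cfg, seed = s)))["YWHAZ"]
    }))
  })
  expect_true(all(diff(avg_m) > 0))
})

test_that("pairwise variation matches brute force and kills proportionality", {
  for (s in 1:100) {
    es <- toy_ct_set(rand_ct(5, 4, seed = 1000 + s))
    rq <- relative_quantities(es)
    rk <- genorm_ranking(rq)$ranking
    v <- pairwise_variation(rq, rk)
    expect_equal(v$v, bf_pairwise_variation(rq$q, rk), tolerance = 1e-12)
  }

  # gene 3's quantity is an exact scalar multiple of NF_2 (its Ct is the
  # arithmetic mean of genes 1-2 plus a constant), so V_2/3 vanishes
  ct <- rand_ct(6, 2, seed = 1)
  ct <- cbind(ct, g3 = rowMeans(ct) + 2, g4 = rand_ct(6, 1, seed = 2)[, 1])
  colnames(ct) <- paste0("g", 1:4)
  rq <- relative_quantities(toy_ct_set(ct))
  v <- pairwise_variation(rq, c("g1", "g2", "g3", "g4"))
  expect_equal(v$v[1], 0, tolerance = 1e-12)
})

test_that("M and V are invariant to global per-sample Ct shifts", {
  for (s in 1:10) {
    ct <- rand_ct(6, 5, seed = 200 + s)
    set.seed(s)
    shifts <- runif(6, -3, 3)
    rq1 <- relative_quantities(toy_ct_set(ct))
    rq2 <- relative_quantities(toy_ct_set(ct + shifts))
    expect_equal(genorm_m(rq1), genorm_m(rq2), tolerance = 1e-10)
    rk <- genorm_ranking(rq1)$ranking
    expect_equal(pairwise_variation(rq1, rk)$v,
                 pairwise_variation(rq2, rk)$v, tolerance = 1e-10)
  }
})

test_that("the optimal-n rule reads the V series with its tolerance", {
  series <- data.frame(n = 2:5, v = c(0.30, 0.20, 0.155, 0.12))
  expect_identical(optimal_gene_count(series), 4L)
  expect_identical(optimal_gene_count(series, tolerance = 0), 5L)
  expect_identical(optimal_gene_count(data.frame(n = 2, v = 0.10)), 2L)
  expect_warning(
    res <- optimal_gene_count(data.frame(n = 2:4, v = c(0.4, 0.3, 0.2))),
    "full panel")
  expect_identical(res, 5L)
})

test_that("the full geNorm wrapper flags M > 1.5 and assembles the pieces", {
  es <- simulate_ct(default_synthetic_config(seed = 8))
  g <- suppressWarnings(genorm(es))
  expect_length(g$m_values, 15)
  expect_identical(nrow(g$v_series), 13L)
  expect_setequal(names(g$ranks), ct_genes(es))
  expect_equal(sort(unname(g$ranks)), c(1.5, 1.5, 3:15))
  expect_identical(g$unstable, g$m_values > 1.5)
})
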