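test_that("construction validates dimensions, identifiers and annotations", {
  m <- matrix(1:6 + 0.5, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ann <- data.frame(sample = c("s1", "s2"), group = c("x", "y"))
  es <- ct_set(m, ann)
  expect_identical(dim(es), c(2L, 3L))
  expect_identical(ct_genes(es), c("a", "b", "c"))

  m2 <- m; colnames(m2) <- c("a", "a", "c")
  expect_error(ct_set(m2, ann), "duplicate gene")
  m3 <- m; m3[1, 1] <- Inf
  expect_error(ct_set(m3, ann), "finite")
  expect_error(ct_set(m, data.frame(sample = "s1", group = "x")),
               "without annotation")
  expect_error(ct_set(m, data.frame(sample = c("s1", "s2"),
                                    group = c("x", NA))),
               "group")
  # annotations matched by sample id, not row order
  es2 <- ct_set(m, ann[2:1, ])
  expect_identical(es2$annotations$group, c("x", "y"))
})

test_that("delimited round trip preserves genes, samples, Ct and annotations", {
  cfg <- default_synthetic_config(seed = 42)
  es <- simulate_ct(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(es, path)
  back <- read_ct_table(path)
  expect_identical(ct_genes(back), ct_genes(es))
  expect_identical(ct_samples(back), ct_samples(es))
  expect_equal(back$ct, es$ct, tolerance = 1e-12)
  expect_identical(back$annotations$group, es$annotations$group)
  expect_identical(back$annotations$cell_line, es$annotations$cell_line)
})

test_that("missing and malformed cells are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gA,gB",
               "s1,ctrl,20.1,NA",
               "s2,acid,21.0,22.5",
               "s3,acid,20.5,23.0"), path)
  expect_warning(es <- read_ct_table(path), "missing")
  expect_true(is.na(es$ct["s1", "gB"]))
  expect_false(anyNA(es$ct[, "gA"]))

  writeLines(c("sample,group,gA", "s1,ctrl,20.1", "s2,ctrl,oops"), path)
  expect_error(read_ct_table(path), "row 's2', column 'gA'")
})

test_that("genes-in-rows orientation with a sidecar reads the transpose", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "gA\t20\t21", "gB\t30\t31"), path)
  ann <- data.frame(sample = c("s1", "s2"), group = c("x", "y"))
  es <- read_ct_table(path, sep = "\t", orientation = "genes_in_rows",
                      annotations = ann)
  expect_identical(dim(es), c(2L, 2L))
  expect_equal(es$ct["s2", "gB"], 31)
  # no annotations anywhere is an error
  writeLines(c("sample\tgA", "s1\t20", "s2\t21"), path)
  expect_error(read_ct_table(path, sep = "\t"), "annotations")
})

test_that("group subsetting keeps exactly the requested samples in order", {
  es <- simulate_ct(default_synthetic_config(seed = 7))
  acid <- subset_by_group(es, "pH6.5")
  expect_identical(nrow(acid$ct), 9L)
  expect_true(all(acid$annotations$group == "pH6.5"))

  both <- subset_by_group(es, c("pH6.5", "pH7.4"))
  expect_identical(ct_samples(both), ct_samples(es))
  expect_equal(both$ct, es$ct)

  expect_error(subset_by_group(es, "pH9"), "available: pH6.5, pH7.4")
})

test_that("summaries reproduce condition means, SDs and their difference", {
  es <- panel_two_point_set("both")
  s <- summarize_ct(es, treatment = "pH6.5")
  panel <- hkg_reference_panel()

  g65 <- s$summary[s$summary$group == "pH6.5", ]
  expect_equal(g65$mean_ct[match(panel$gene, g65$gene)], panel$mean_ph65,
               tolerance = 1e-12)
  expect_equal(g65$sd_ct[match(panel$gene, g65$gene)], panel$sd_ph65,
               tolerance = 1e-12)

  d <- s$delta
  expect_equal(d$delta_ct[d$gene == "GAPDH"], 20.95 - 20.63, tolerance = 1e-9)
  expect_equal(d$delta_ct[d$gene == "B2M"], 20.15 - 21.35, tolerance = 1e-9)

  # antisymmetry of the delta under swapping the treatment designation
  d2 <- summarize_ct(es, treatment = "pH7.4")$delta
  expect_equal(d2$delta_ct, -d$delta_ct, tolerance = 1e-12)
})

test_that("summaries are invariant to sample order and pool consistently", {
  es <- simulate_ct(default_synthetic_config(seed = 3))
  s1 <- summarize_ct(es)
  perm <- sample(nrow(es$ct))
  es2 <- ct_set(es$ct[perm, ], es$annotations[perm, ])
  s2 <- summarize_ct(es2)
  key <- function(s) s[order(s$gene, s$group), ]
  expect_equal(key(s1$summary), key(s2$summary), tolerance = 1e-12,
               ignore_attr = TRUE)

  # pooled mean equals the n-weighted mean of group means
  for (g in ct_genes(es)) {
    rows <- s1$summary[s1$summary$gene == g, ]
    grp <- rows[rows$group != "pooled", ]
    pooled <- rows[rows$group == "pooled", ]
    expect_equal(pooled$mean_ct,
                 sum(grp$mean_ct * grp$n) / sum(grp$n), tolerance = 1e-12)
  }
})

test_that("a constant gene has zero SD and zero delta; n<2 flags missing SD", {
  ct <- cbind(flat = rep(21, 4), noisy = c(20, 22, 19, 23))
  es <- toy_ct_set(ct, groups = c("a", "a", "b", "b"))
  s <- summarize_ct(es, treatment = "a")
  flat <- s$summary[s$summary$gene == "flat", ]
  expect_true(all(flat$sd_ct == 0))
  expect_equal(s$delta$delta_ct[s$delta$gene == "flat"], 0)

  es2 <- toy_ct_set(ct, groups = c("a", "a", "a", "b"))
  expect_warning(s2 <- summarize_ct(es2, treatment = "a"), "n < 2")
  noisy_b <- s2$summary[s2$summary$gene == "noisy" & s2$summary$group == "b", ]
  expect_true(is.na(noisy_b$sd_ct))
})
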