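# Shared fixtures and independent brute-force oracles.
# Oracles are written as direct transliterations of each statistic's
# definition (explicit loops, no reuse of package internals).

# quick ct_set from a bare matrix
toy_ct_set <- function(ct, groups = NULL, genes = NULL, samples = NULL) {
  if (is.null(genes))
    genes <- if (!is.null(colnames(ct))) colnames(ct) else
      paste0("g", seq_len(ncol(ct)))
  if (is.null(samples))
    samples <- if (!is.null(rownames(ct))) rownames(ct) else
      paste0("s", seq_len(nrow(ct)))
  dimnames(ct) <- list(samples, genes)
  if (is.null(groups)) groups <- rep("all", nrow(ct))
  ct_set(ct, data.frame(sample = samples, group = groups,
                        stringsAsFactors = FALSE))
}

# two observations with exactly the requested sample mean and SD
two_point <- function(mean, sd) c(mean + sd / sqrt(2), mean - sd / sqrt(2))

# ct_set whose per-condition sample moments equal the published panel
# summaries (two samples per condition per gene)
panel_two_point_set <- function(condition = c("acidic", "physiological",
                                              "pooled", "both")) {
  condition <- match.arg(condition)
  panel <- hkg_reference_panel()
  build <- function(means, sds, group) {
    ct <- vapply(seq_len(nrow(panel)),
                 function(i) two_point(means[i], sds[i]), numeric(2))
    colnames(ct) <- panel$gene
    rownames(ct) <- paste0(group, c("_a", "_b"))
    list(ct = ct, group = rep(group, 2))
  }
  parts <- switch(condition,
    acidic = list(build(panel$mean_ph65, panel$sd_ph65, "pH6.5")),
    physiological = list(build(panel$mean_ph74, panel$sd_ph74, "pH7.4")),
    pooled = list(build(panel$mean_pooled, panel$sd_pooled, "pooled")),
    both = list(build(panel$mean_ph65, panel$sd_ph65, "pH6.5"),
                build(panel$mean_ph74, panel$sd_ph74, "pH7.4")))
  ct <- do.call(rbind, lapply(parts, `[[`, "ct"))
  groups <- unlist(lapply(parts, `[[`, "group"))
  ct_set(ct, data.frame(sample = rownames(ct), group = groups,
                        stringsAsFactors = FALSE))
}

# random Ct matrix in a plausible cycle range
rand_ct <- function(n, k, seed) {
  set.seed(seed)
  matrix(stats::runif(n * k, 15, 35), n, k,
         dimnames = list(paste0("s", 1:n), paste0("g", 1:k)))
}

# 15-gene homoscedastic two-condition config: equal condition means per gene,
# every SD 1 cycle -- a spiked gene is the unique ground-truth unstable gene
homoscedastic_config <- function(sd = 1) {
  panel <- hkg_reference_panel()
  synthetic_config(panel$gene,
                   cbind(panel$mean_pooled, panel$mean_pooled),
                   matrix(sd, nrow(panel), 2),
                   conditions = c("pH6.5", "pH7.4"),
                   cell_lines = c(HOS = 0, `MG-63` = 0, `Saos-2` = 0),
                   replicates = 3L)
}

# ---- brute-force oracles ----

# geNorm M by explicit double loop over gene pairs
bf_genorm_m <- function(q) {
  k <- ncol(q)
  m <- numeric(k)
  for (j in 1:k) {
    vs <- c()
    for (l in setdiff(1:k, j))
      vs <- c(vs, stats::sd(log2(q[, j] / q[, l])))
    m[j] <- mean(vs)
  }
  names(m) <- colnames(q)
  m
}

# pairwise variation by direct geometric means
bf_pairwise_variation <- function(q, ranking) {
  k <- length(ranking)
  sapply(2:(k - 1), function(n) {
    nf_n <- apply(q[, ranking[1:n], drop = FALSE], 1,
                  function(v) prod(v)^(1 / n))
    nf_n1 <- apply(q[, ranking[1:(n + 1)], drop = FALSE], 1,
                   function(v) prod(v)^(1 / (n + 1)))
    stats::sd(log2(nf_n / nf_n1))
  })
}

# comparative delta-Ct scores by explicit double loop
bf_delta_ct <- function(ct) {
  k <- ncol(ct)
  scores <- numeric(k)
  for (j in 1:k) {
    s <- c()
    for (l in setdiff(1:k, j))
      s <- c(s, stats::sd(ct[, j] - ct[, l]))
    scores[j] <- mean(s)
  }
  names(scores) <- colnames(ct)
  scores
}

# BestKeeper descriptives + index correlation, from first principles
bf_bestkeeper <- function(ct) {
  geo <- apply(ct, 2, function(v) prod(v)^(1 / length(v)))
  ar <- apply(ct, 2, mean)
  mad_ <- apply(ct, 2, function(v) mean(abs(v - mean(v))))
  index <- apply(ct, 1, function(v) prod(v)^(1 / length(v)))
  r <- apply(ct, 2, function(v) stats::cor(v, index))
  list(geo_mean = geo, ar_mean = ar, mad = mad_, cv_pct = 100 * mad_ / ar,
       index = index, r = r)
}

# Mann-Whitney U and exact one-sided p by enumeration of all assignments
bf_mwu <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  us <- apply(idx, 2, function(i) {
    aa <- pooled[i]; bb <- pooled[-i]
    s <- 0
    for (x in aa) for (y in bb) s <- s + (x > y) + 0.5 * (x == y)
    s
  })
  list(u = u, p_greater = mean(us >= u))
}
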