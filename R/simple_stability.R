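#' BestKeeper descriptive statistics and index correlation
#'
#' Per-gene descriptives of raw Ct (geometric mean, arithmetic mean, min, max,
#' dispersion, CV%) plus the BestKeeper index — the per-sample geometric mean
#' of Ct across candidate genes — and each gene's Pearson correlation with
#' that index. The classical dispersion statistic ("ST.DEV [+/- CP]") is the
#' mean absolute deviation of Ct about the gene's arithmetic mean; a gene with
#' dispersion above 1.0 cycle is flagged unstable and conventionally excluded
#' from normalization.
#'
#' @param x A [ct_set()] with >= 2 genes and >= 3 samples; all Ct must be
#'   positive (the geometric mean is undefined otherwise). Missing values are
#'   dropped per gene for descriptives but samples with any missing Ct are
#'   excluded from the index.
#' @param sd_method `"mad"` (mean absolute deviation about the mean; the
#'   legacy convention, default) or `"sd"` (sample SD).
#' @param filtered If `TRUE`, the index is computed only over genes passing
#'   the dispersion cutoff (<= 1.0); default uses all genes.
#' @return Object of class `bestkeeper_result`: list with `gene_stats` (data
#'   frame: gene, geo_mean_ct, ar_mean_ct, min_ct, max_ct, sd_ct, cv_pct,
#'   unstable, pearson_r, p_value), `index` (named per-sample vector),
#'   `sd_method`, `filtered`.
#' @export
bestkeeper <- function(x, sd_method = c("mad", "sd"), filtered = FALSE) {
  stopifnot(inherits(x, "ct_set"))
  sd_method <- match.arg(sd_method)
  ct <- x$ct
  if (ncol(ct) < 2 || nrow(ct) < 3)
    stop("BestKeeper requires >= 2 genes and >= 3 samples")
  if (any(ct <= 0, na.rm = TRUE))
    stop("nonpositive Ct values: geometric mean undefined")

  disp <- function(v) {
    v <- v[!is.na(v)]
    if (sd_method == "mad") mean(abs(v - mean(v))) else stats::sd(v)
  }
  stats_df <- data.frame(
    gene = colnames(ct),
    geo_mean_ct = apply(ct, 2, function(v) exp(mean(log(v[!is.na(v)])))),
    ar_mean_ct = colMeans(ct, na.rm = TRUE),
    min_ct = apply(ct, 2, min, na.rm = TRUE),
    max_ct = apply(ct, 2, max, na.rm = TRUE),
    sd_ct = apply(ct, 2, disp),
    stringsAsFactors = FALSE)
  stats_df$cv_pct <- 100 * stats_df$sd_ct / stats_df$ar_mean_ct
  stats_df$unstable <- stats_df$sd_ct > 1.0

  idx_genes <- if (filtered) stats_df$gene[!stats_df$unstable] else stats_df$gene
  if (!length(idx_genes)) stop("no gene passes the SD <= 1.0 filter")
  complete <- stats::complete.cases(ct[, idx_genes, drop = FALSE])
  index <- exp(rowMeans(log(ct[complete, idx_genes, drop = FALSE])))

  cors <- lapply(colnames(ct), function(g) {
    ok <- complete & !is.na(ct[, g])
    v <- ct[ok, g]
    w <- index[rownames(ct)[ok]]
    if (stats::sd(v) == 0 || stats::sd(w) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct_test <- stats::cor.test(v, w, method = "pearson")
    c(r = unname(ct_test$estimate), p = ct_test$p.value)
  })
  stats_df$pearson_r <- vapply(cors, `[[`, numeric(1), "r")
  stats_df$p_value <- vapply(cors, `[[`, numeric(1), "p")
  rownames(stats_df) <- NULL

  structure(list(gene_stats = stats_df, index = index,
                 sd_method = sd_method, filtered = filtered),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat(sprintf("<bestkeeper_result> dispersion = %s%s\n", x$sd_method,
              if (x$filtered) ", filtered index" else ""))
  df <- x$gene_stats
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df[order(x$gene_stats$sd_ct), ], row.names = FALSE)
  invisible(x)
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) computes delta-Ct(i) = Ct(i, j) -
#' Ct(i, k) across samples and its sample SD; a gene's stability score is the
#' mean of its pair SDs over all partners. Two genes whose expression moves in
#' parallel across samples have pair SD 0; a gene with a low average pair SD
#' tracks the rest of the panel and is considered stable. Scores are invariant
#' to global per-sample Ct shifts.
#'
#' @param x A [ct_set()] with >= 3 genes and >= 2 samples.
#' @return Object of class `delta_ct_result`: list with `scores` (named
#'   per-gene mean pair SD, cycles) and `pair_sd` (symmetric gene x gene
#'   matrix, diagonal `NA`).
#' @export
delta_ct_stability <- function(x) {
  stopifnot(inherits(x, "ct_set"))
  ct <- x$ct
  if (ncol(ct) < 3 || nrow(ct) < 2)
    stop("the delta-Ct method requires >= 3 genes and >= 2 samples")
  k <- ncol(ct)
  pair_sd <- matrix(NA_real_, k, k, dimnames = list(colnames(ct), colnames(ct)))
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      d <- ct[, j] - ct[, l]
      s <- stats::sd(d[!is.na(d)])
      pair_sd[j, l] <- pair_sd[l, j] <- s
    }
  }
  scores <- rowMeans(pair_sd, na.rm = TRUE)
  structure(list(scores = scores, pair_sd = pair_sd),
            class = "delta_ct_result")
}

#' Coefficient-of-variation stability
#'
#' cv(g) = sample SD of Ct over mean Ct, per gene, over whichever samples the
#' input contains (subset by condition first for per-condition CVs). The CV is
#' invariant to multiplying all Ct by a positive constant but, unlike the
#' ratio-based methods, not to additive shifts.
#'
#' @param x A [ct_set()].
#' @return Data frame with columns `gene`, `mean_ct`, `sd_ct`, `cv`.
#' @export
cv_stability <- function(x) {
  stopifnot(inherits(x, "ct_set"))
  m <- colMeans(x$ct, na.rm = TRUE)
  if (any(m == 0)) stop("zero mean Ct: CV undefined")
  s <- apply(x$ct, 2, function(v) stats::sd(v[!is.na(v)]))
  data.frame(gene = colnames(x$ct), mean_ct = m, sd_ct = s, cv = s / m,
             row.names = NULL, stringsAsFactors = FALSE)
}
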