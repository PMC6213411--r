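#' Multi-gene normalization factor
#'
#' The per-sample normalization factor is the geometric mean of the
#' comparative-Ct relative quantities of the selected reference genes —
#' equivalently 2^(mean of per-gene calibrated -delta-Ct). Using the geometric
#' mean of several validated reference genes buffers the normalizer against
#' any single gene's residual instability.
#'
#' @param x A [ct_set()] containing the reference genes with no missing Ct in
#'   them.
#' @param reference_genes Character vector of reference gene names (>= 1).
#' @param efficiency Amplification base, default 2.
#' @return Named numeric vector (one positive factor per sample) with
#'   attributes `reference_genes` and `efficiency`.
#' @export
normalization_factor <- function(x, reference_genes, efficiency = 2) {
  stopifnot(inherits(x, "ct_set"))
  if (!length(reference_genes)) stop("empty reference gene list")
  missing <- setdiff(reference_genes, ct_genes(x))
  if (length(missing))
    stop("reference gene(s) not in panel: ", paste(missing, collapse = ", "))
  refs <- unique(reference_genes)
  sub <- ct_set(x$ct[, refs, drop = FALSE], x$annotations)
  q <- relative_quantities(sub, efficiency)$q
  nf <- exp(rowMeans(log(q)))
  attr(nf, "reference_genes") <- refs
  attr(nf, "efficiency") <- efficiency
  nf
}

#' Relative expression of a target gene by the delta-delta-Ct model
#'
#' delta-Ct(i) = Ct_target(i) - mean(Ct of the reference genes in sample i);
#' delta-delta-Ct(i) = delta-Ct(i) - delta-Ct(calibrator); fold(i) =
#' E^-delta-delta-Ct(i). Averaging reference Ct arithmetically is algebraically
#' identical to normalizing by the geometric mean of the reference genes'
#' linear quantities. The calibrator can be a single sample (whose fold is 1
#' by construction) or a group label, in which case the group's mean delta-Ct
#' is the baseline.
#'
#' @param x A [ct_set()] containing target and reference genes.
#' @param target Target gene name (must not be among the references).
#' @param reference_genes Character vector of reference gene names.
#' @param calibrator Sample id or group label serving as the expression
#'   baseline.
#' @param efficiency Amplification base, default 2.
#' @return Object of class `relative_expression`: data frame with columns
#'   `sample`, `group`, `delta_ct`, `ddct`, `fold`, plus attributes `target`
#'   and `calibrator`.
#' @export
relative_expression <- function(x, target, reference_genes, calibrator,
                                efficiency = 2) {
  stopifnot(inherits(x, "ct_set"))
  if (target %in% reference_genes)
    stop("target gene must not be in the reference list")
  need <- c(target, reference_genes)
  missing <- setdiff(need, ct_genes(x))
  if (length(missing))
    stop("gene(s) not in panel: ", paste(missing, collapse = ", "))
  if (anyNA(x$ct[, need]))
    stop("missing Ct among target/reference genes")

  ref_mean <- rowMeans(x$ct[, unique(reference_genes), drop = FALSE])
  dct <- x$ct[, target] - ref_mean

  if (calibrator %in% ct_samples(x)) {
    baseline <- dct[calibrator]
  } else if (calibrator %in% ct_groups(x)) {
    baseline <- mean(dct[x$annotations$group == calibrator])
  } else {
    stop("calibrator `", calibrator, "` is neither a sample nor a group")
  }
  ddct <- dct - baseline
  out <- data.frame(sample = ct_samples(x), group = x$annotations$group,
                    delta_ct = unname(dct), ddct = unname(ddct),
                    fold = unname(efficiency^(-ddct)),
                    stringsAsFactors = FALSE)
  structure(out, target = target, calibrator = calibrator,
            reference_genes = unique(reference_genes),
            class = c("relative_expression", "data.frame"))
}

#' Compare the precision of two normalizers
#'
#' Given the fold-change values of the same target under two different
#' normalization strategies, reports each list's standard error of the mean
#' and a one-tailed Mann-Whitney (Wilcoxon rank-sum) test of the alternative
#' that the first list's values are stochastically larger. A noisier
#' normalizer inflates the spread (hence the SE) of the folds it produces.
#'
#' The exact U distribution is used when there are no ties; otherwise the
#' normal approximation with continuity correction.
#'
#' @param folds_a,folds_b Numeric vectors of fold values, each of length >= 3.
#' @param alternative Passed to [stats::wilcox.test()]; default `"greater"`.
#' @return List with `p_value`, `statistic` (the U statistic for
#'   `folds_a`), `se_a`, `se_b`.
#' @export
compare_normalizer_precision <- function(folds_a, folds_b,
                                         alternative = "greater") {
  if (length(folds_a) < 3 || length(folds_b) < 3)
    stop("each fold list needs at least 3 values")
  se <- function(v) stats::sd(v) / sqrt(length(v))
  has_ties <- anyDuplicated(c(folds_a, folds_b)) > 0
  wt <- stats::wilcox.test(folds_a, folds_b, alternative = alternative,
                           exact = !has_ties, correct = TRUE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       se_a = se(folds_a), se_b = se(folds_b))
}
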