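#' Model-based (NormFinder-style) stability estimation
#'
#' Decomposes log2 relative expression into sample effects, gene effects, and
#' gene-specific residual variation — plus, when condition groups are given,
#' systematic gene-by-group deviations — and scores each candidate reference
#' gene by how much expression variation it carries. Lower stability values
#' indicate more stable genes.
#'
#' Ungrouped model: y(i, g) double-centered over samples and genes leaves
#' residuals whose per-gene variance is estimated with the small-panel
#' correction sigma2_g = k/(k-2) * (s2_g - sum(s2)/(k*(k-1))), where s2_g is
#' the raw per-gene residual mean square and k the panel size; the subtraction
#' removes the shared variance every residual inherits from the per-sample
#' gene average. Stability is the square root of the variance floored at zero.
#'
#' Grouped model: residual variances are estimated within each group as above.
#' The gene-by-group interaction d(g, gamma) — the gene's group mean of
#' sample-centered expression minus its overall mean — estimates systematic
#' condition dependence, exactly the defect disqualifying a reference gene.
#' Across genes, d is shrunk toward zero by the empirical-Bayes factor
#' tau2 / (tau2 + sigma2/n), where tau2 is the method-of-moments estimate of
#' the true interaction variance. The per-gene stability value is the average
#' over groups of |shrunken d| plus the posterior sampling SD, so both bias
#' and noise count against a gene.
#'
#' @param rq A [relative_quantities()] object (or a [ct_set()], which is
#'   linearized with base-2 efficiency first).
#' @param groups Optional per-sample group labels (character vector aligned
#'   with the samples, or the name of an annotation column, e.g. `"group"`).
#'   `NULL` (default) runs the ungrouped model.
#' @return Object of class `normfinder_result`: list with `stability` (named,
#'   lower = more stable), `variance` (uncorrected-sign per-gene variance
#'   estimates; ungrouped) or `intragroup_var` (gene x group matrix) and
#'   `intergroup_diff` (gene x group matrix of shrunken deviations), plus
#'   `grouped` flag.
#' @export
normfinder <- function(rq, groups = NULL) {
  if (inherits(rq, "ct_set")) rq <- relative_quantities(rq)
  stopifnot(inherits(rq, "rel_quantities"))
  y <- log2(rq$q)
  k <- ncol(y)
  if (k <= 2) stop("the variance correction requires more than 2 genes")

  if (is.character(groups) && length(groups) == 1 &&
      groups %in% names(rq$annotations))
    groups <- rq$annotations[[groups]]

  if (is.null(groups)) {
    est <- .nf_residual_var(y)
    stability <- sqrt(pmax(est, 0))
    return(structure(list(stability = stability, variance = est,
                          grouped = FALSE),
                     class = "normfinder_result"))
  }

  groups <- as.character(groups)
  if (length(groups) != nrow(y))
    stop("`groups` must supply one label per sample")
  glev <- unique(groups)
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2)) stop("every group needs at least 2 samples")

  # per-group residual variances
  sig2 <- sapply(glev, function(g) .nf_residual_var(y[groups == g, , drop = FALSE]))
  sig2 <- matrix(sig2, nrow = k, dimnames = list(colnames(y), glev))
  sig2_pos <- pmax(sig2, 0)

  # gene-by-group deviations on sample-centered data
  z <- y - rowMeans(y)
  gene_means <- colMeans(z)
  d <- sapply(glev, function(g) colMeans(z[groups == g, , drop = FALSE]) - gene_means)
  d <- matrix(d, nrow = k, dimnames = list(colnames(y), glev))

  # empirical-Bayes shrinkage of d toward 0
  samp_var <- sweep(sig2_pos, 2, as.numeric(ng), "/")
  tau2 <- max(0, mean(d^2) - mean(samp_var))
  shrink <- if (tau2 > 0) tau2 / (tau2 + samp_var) else 0 * samp_var
  d_shrunk <- d * shrink
  post_sd <- sqrt(samp_var * shrink)

  stability <- rowMeans(abs(d_shrunk) + post_sd)
  structure(list(stability = stability, intragroup_var = sig2,
                 intergroup_diff = d_shrunk, tau2 = tau2, grouped = TRUE),
            class = "normfinder_result")
}

# Per-gene residual variance of a double-centered log-expression matrix,
# with the heteroscedastic small-panel correction: solving
# E[s2_g] = sigma2_g (1 - 2/k) + sum(sigma2)/k^2 for sigma2_g.
.nf_residual_var <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  if (n < 2) stop("residual variance needs at least 2 samples")
  r <- y - rowMeans(y)
  r <- sweep(r, 2, colMeans(r))
  s2 <- colSums(r^2) / (n - 1)
  (k / (k - 2)) * (s2 - sum(s2) / (k * (k - 1)))
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("<normfinder_result> %s model\n",
              if (x$grouped) "grouped" else "ungrouped"))
  ord <- order(x$stability)
  print(round(x$stability[ord], 4))
  invisible(x)
}
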