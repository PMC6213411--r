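#' Comparative-Ct linearization
#'
#' Converts raw Ct to linear-scale relative quantities with the comparative-Ct
#' transform, q(i, g) = E^(min_i' Ct(i', g) - Ct(i, g)), calibrated per gene to
#' the sample with the lowest Ct (highest expression), so every gene's maximum
#' quantity is exactly 1. E is the amplification base (2 for the ideal
#' doubling per cycle).
#'
#' @param x A [ct_set()] with no missing Ct among its genes/samples (subset or
#'   impute upstream first).
#' @param efficiency Amplification base E, > 1.
#' @return Object of class `rel_quantities`: list with `q` (samples x genes
#'   matrix, values in (0, 1]), `efficiency`, and the sample `annotations`.
#' @export
relative_quantities <- function(x, efficiency = 2) {
  stopifnot(inherits(x, "ct_set"))
  if (efficiency <= 1) stop("`efficiency` must be > 1")
  if (anyNA(x$ct))
    stop("missing Ct values present; subset to complete samples/genes or ",
         "impute before linearization")
  mins <- apply(x$ct, 2, min)
  q <- efficiency^(rep(mins, each = nrow(x$ct)) - x$ct)
  dimnames(q) <- dimnames(x$ct)
  structure(list(q = q, efficiency = efficiency, annotations = x$annotations),
            class = "rel_quantities")
}

#' geNorm expression-stability measure M
#'
#' For each gene j, M_j is the arithmetic mean over all other genes k of the
#' sample SD of the pairwise log2 expression ratio log2(q_j / q_k). A gene
#' whose expression is proportional to every other gene's across samples has
#' M = 0; larger M means less stable. M above 1.5 is conventionally flagged as
#' unacceptably unstable.
#'
#' @param rq A [relative_quantities()] object.
#' @param genes Optional subset of genes to evaluate (default: all).
#' @return Named numeric vector of M values.
#' @export
genorm_m <- function(rq, genes = NULL) {
  stopifnot(inherits(rq, "rel_quantities"))
  q <- rq$q
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(q))
    if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
    q <- q[, genes, drop = FALSE]
  }
  k <- ncol(q)
  if (k < 2) stop("geNorm M requires at least 2 genes")
  if (nrow(q) < 2) stop("geNorm M requires at least 2 samples")
  a <- log2(q)
  # V[j, k] = sd over samples of (a_j - a_k); M_j = mean over k != j
  v <- matrix(0, k, k)
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      s <- stats::sd(a[, j] - a[, l])
      v[j, l] <- v[l, j] <- s
    }
  }
  m <- rowSums(v) / (k - 1)
  names(m) <- colnames(q)
  m
}

#' geNorm stepwise-exclusion stability ranking
#'
#' Repeatedly removes the gene with the highest M among those remaining and
#' recomputes M, until two genes remain; that final pair cannot be resolved by
#' the pairwise measure and is reported as tied for the top (both get rank
#' 1.5, the average-rank convention). Ties in the highest M at a removal step
#' are broken deterministically: the gene with larger log-expression SD is
#' removed, then alphabetically; each tie-break is reported via `message()`.
#'
#' @param rq A [relative_quantities()] object with >= 3 genes.
#' @return List with `ranking` (gene names, most stable first; first two
#'   tied), `ranks` (named numeric; final pair 1.5, then 3..k by reverse
#'   removal order), `removal_order` (least stable first), `m_full` (M on the
#'   full panel), and `m_at_removal` (each gene's M at the step it was
#'   removed; final pair at the two-gene step).
#' @export
genorm_ranking <- function(rq) {
  stopifnot(inherits(rq, "rel_quantities"))
  genes <- colnames(rq$q)
  k <- length(genes)
  if (k < 3) stop("stepwise ranking requires at least 3 genes")
  m_full <- genorm_m(rq)
  sd_log <- apply(log2(rq$q), 2, stats::sd)

  remaining <- genes
  removal_order <- character(0)
  m_at_removal <- numeric(0)
  while (length(remaining) > 2) {
    m <- genorm_m(rq, remaining)
    worst <- remaining[m >= max(m) - 1e-12]
    if (length(worst) > 1) {
      worst <- worst[order(-sd_log[worst], worst)]
      message("geNorm tie at M = ", format(max(m)), " between ",
              paste(worst, collapse = ", "), "; removing ", worst[1])
    }
    removal_order <- c(removal_order, worst[1])
    m_at_removal <- c(m_at_removal, m[worst[1]])
    remaining <- setdiff(remaining, worst[1])
  }
  final_m <- genorm_m(rq, remaining)
  ranking <- c(remaining, rev(removal_order))
  ranks <- c(1.5, 1.5, seq(3, k))
  names(ranks) <- ranking
  m_at_removal <- c(stats::setNames(final_m[remaining], remaining),
                    rev(stats::setNames(m_at_removal, removal_order)))
  list(ranking = ranking, ranks = ranks[genes],
       removal_order = removal_order, m_full = m_full,
       m_at_removal = m_at_removal)
}

#' geNorm pairwise variation V between nested normalization factors
#'
#' NF_n(i) is the geometric mean over the n most stable genes of q(i, g);
#' V_{n/n+1} is the sample SD over samples of log2(NF_n / NF_{n+1}), for
#' n = 2 .. k-1. A small V means adding the (n+1)-th gene barely changes the
#' normalization factor, so n genes suffice.
#'
#' @param rq A [relative_quantities()] object.
#' @param ranking Gene names ordered most stable first (e.g.
#'   `genorm_ranking(rq)$ranking`); computed if omitted.
#' @return Data frame with columns `n` and `v`.
#' @export
pairwise_variation <- function(rq, ranking = NULL) {
  stopifnot(inherits(rq, "rel_quantities"))
  if (is.null(ranking)) ranking <- genorm_ranking(rq)$ranking
  k <- length(ranking)
  if (k < 3) stop("pairwise variation requires at least 3 ranked genes")
  a <- log2(rq$q[, ranking, drop = FALSE])
  # log2 NF_n = row mean of log2 q over the n most stable genes
  v <- vapply(2:(k - 1), function(n) {
    nf_n <- rowMeans(a[, seq_len(n), drop = FALSE])
    nf_n1 <- rowMeans(a[, seq_len(n + 1), drop = FALSE])
    stats::sd(nf_n - nf_n1)
  }, numeric(1))
  data.frame(n = 2:(k - 1), v = v)
}

#' Optimal number of reference genes from the V series
#'
#' The smallest n whose V_{n/n+1} reaches the cutoff (0.15 by convention).
#' A small tolerance (default 0.005) reproduces the field's reading that
#' values such as 0.155 "reach" 0.15; set `tolerance = 0` for the strict rule.
#' If no n qualifies, the full panel size k is returned with a warning.
#'
#' @param v_series Data frame with columns `n`, `v` (from
#'   [pairwise_variation()]).
#' @param cutoff V cutoff, default 0.15.
#' @param tolerance Acceptance slack added to the cutoff, default 0.005.
#' @return Integer: the recommended number of reference genes.
#' @export
optimal_gene_count <- function(v_series, cutoff = 0.15, tolerance = 0.005) {
  stopifnot(is.data.frame(v_series), all(c("n", "v") %in% names(v_series)),
            nrow(v_series) >= 1)
  ok <- v_series$n[v_series$v <= cutoff + tolerance]
  if (length(ok)) return(as.integer(min(ok)))
  k <- as.integer(max(v_series$n) + 1L)
  warning("no pairwise variation at or below ", cutoff + tolerance,
          "; returning the full panel size k = ", k)
  k
}

#' Full geNorm analysis of a Ct expression set
#'
#' Runs the comparative-Ct linearization, M-values, stepwise-exclusion
#' ranking, pairwise variation and optimal-gene-count rule in one call.
#'
#' @param x A [ct_set()].
#' @param efficiency Amplification base, default 2.
#' @param cutoff,tolerance Passed to [optimal_gene_count()].
#' @return Object of class `genorm_result`: list with `m_values` (full-panel
#'   M), `ranking`, `ranks` (final pair 1.5/1.5), `removal_order`,
#'   `m_at_removal`, `v_series`, `optimal_n`, and `unstable` (logical flags,
#'   full-panel M > 1.5).
#' @export
genorm <- function(x, efficiency = 2, cutoff = 0.15, tolerance = 0.005) {
  rq <- relative_quantities(x, efficiency)
  rk <- genorm_ranking(rq)
  v <- pairwise_variation(rq, rk$ranking)
  structure(list(m_values = rk$m_full, ranking = rk$ranking,
                 ranks = rk$ranks, removal_order = rk$removal_order,
                 m_at_removal = rk$m_at_removal, v_series = v,
                 optimal_n = optimal_gene_count(v, cutoff, tolerance),
                 unstable = rk$m_full > 1.5),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result>\n")
  cat("ranking (most stable first):", paste(x$ranking, collapse = " > "), "\n")
  cat("optimal number of reference genes:", x$optimal_n, "\n")
  if (any(x$unstable))
    cat("genes with M > 1.5:",
        paste(names(x$m_values)[x$unstable], collapse = ", "), "\n")
  invisible(x)
}
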