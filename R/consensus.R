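#' Tie-averaged ascending ranks of stability scores
#'
#' Ranks genes from most stable (rank 1, lowest score) to least stable; exact
#' ties receive the average of the tied positions (so a tied best pair gets
#' 1.5/1.5, preserving rank sums).
#'
#' @param scores Named numeric vector; all five stability methods here are
#'   lower-is-better.
#' @return Named numeric vector of ranks.
#' @export
rank_scores <- function(scores) {
  if (is.null(names(scores))) stop("`scores` must be named by gene")
  if (any(!is.finite(scores))) stop("non-finite stability score")
  rank(scores, ties.method = "average")
}

#' Bundle one method's stability scores and ranks
#'
#' @param method Method label, one of `"genorm"`, `"normfinder"`,
#'   `"bestkeeper"`, `"delta_ct"`, `"cv"` (free labels allowed).
#' @param scores Named numeric vector of per-gene scores (lower = more
#'   stable). May be `NULL` when only ranks exist (e.g. published tables).
#' @param ranks Optional explicit ranks (named); needed for geNorm, whose
#'   ordering comes from stepwise exclusion rather than from sorting a single
#'   score, and for rank columns taken from the literature. Computed from
#'   `scores` with [rank_scores()] when omitted.
#' @return Object of class `stability_result`.
#' @export
stability_result <- function(method, scores = NULL, ranks = NULL) {
  if (is.null(ranks)) {
    if (is.null(scores)) stop("supply `scores` or `ranks`")
    ranks <- rank_scores(scores)
  }
  if (is.null(names(ranks))) stop("`ranks` must be named by gene")
  k <- length(ranks)
  if (abs(sum(ranks) - k * (k + 1) / 2) > 1e-9)
    stop("`ranks` must be a tie-averaged permutation of 1..k")
  structure(list(method = method, scores = scores, ranks = ranks,
                 direction = "lower-is-better"),
            class = "stability_result")
}

#' Geometric-mean-of-ranks consensus across stability methods
#'
#' Combines the per-method rankings into a single comprehensive ranking: each
#' gene's consensus statistic is the geometric mean of its ranks across
#' methods, and the final ordering sorts it ascending (smaller = more stable).
#' Ties in the geometric mean are broken by arithmetic mean rank, then
#' alphabetically, and reported via `message()`.
#'
#' @param results List of [stability_result()] objects covering the same gene
#'   set (>= 2 methods).
#' @param optimal_n Optional number of reference genes to recommend (e.g. the
#'   geNorm pairwise-variation result); the top `optimal_n` consensus genes
#'   are returned as `recommended`.
#' @return Object of class `consensus_table`: list with `table` (data frame:
#'   gene, one rank column per method, geo_mean_rank, final_rank, sorted by
#'   final rank) and `recommended` (character vector or `NULL`).
#' @export
comprehensive_ranking <- function(results, optimal_n = NULL) {
  if (length(results) < 2) stop("need at least 2 method results")
  ok <- vapply(results, inherits, logical(1), "stability_result")
  if (!all(ok)) stop("all elements must be `stability_result` objects")
  genes <- sort(names(results[[1]]$ranks))
  for (r in results)
    if (!identical(sort(names(r$ranks)), genes))
      stop("method `", r$method, "` covers a different gene set")

  rank_mat <- vapply(results, function(r) r$ranks[genes],
                     numeric(length(genes)))
  colnames(rank_mat) <- vapply(results, `[[`, character(1), "method")
  geo <- exp(rowMeans(log(rank_mat)))
  mean_rank <- rowMeans(rank_mat)

  ord <- order(geo, mean_rank, genes)
  tied <- duplicated(round(geo, 12)) | duplicated(round(geo, 12), fromLast = TRUE)
  if (any(tied))
    message("consensus ties broken by mean rank, then name: ",
            paste(genes[tied], collapse = ", "))

  tab <- data.frame(gene = genes, rank_mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab$geo_mean_rank <- geo
  tab <- tab[ord, , drop = FALSE]
  tab$final_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  recommended <- NULL
  if (!is.null(optimal_n)) {
    if (optimal_n < 1 || optimal_n > nrow(tab))
      stop("`optimal_n` out of range")
    recommended <- tab$gene[seq_len(optimal_n)]
  }
  structure(list(table = tab, recommended = recommended),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("<consensus_table>\n")
  tab <- x$table
  tab$geo_mean_rank <- round(tab$geo_mean_rank, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$recommended))
    cat("recommended reference genes:",
        paste(x$recommended, collapse = ", "), "\n")
  invisible(x)
}
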