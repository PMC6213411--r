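#' Run the full reference-gene stability pipeline
#'
#' Orchestrates every stage on a Ct expression set: per-gene condition
#' summaries, the five stability methods per condition subset (each single
#' condition plus, when two or more conditions exist, the combined set), the
#' geNorm pairwise-variation series and optimal gene count, and the
#' geometric-mean-of-ranks consensus with a recommended reference-gene set.
#' NormFinder runs ungrouped within a single condition and with
#' condition-as-group on the combined subset.
#'
#' All tables are written as TSV at full precision plus a machine-readable
#' JSON manifest (inputs, parameters, per-subset optimal n and
#' recommendations, package version). Outputs are deterministic: the same
#' input produces byte-identical tables.
#'
#' @param x A [ct_set()].
#' @param out_dir Output directory (created if needed).
#' @param treatment Group treated as the "treatment" arm of the summary delta
#'   (default: first group).
#' @param efficiency Amplification base for the comparative-Ct transform.
#' @param cutoff,tolerance geNorm pairwise-variation rule parameters.
#' @param sd_method BestKeeper dispersion convention, see [bestkeeper()].
#' @return Invisibly, a list with `summary`, and per subset: `methods` (the
#'   five `stability_result`s), `genorm`, `consensus`; plus `manifest`.
#' @export
run_stability_pipeline <- function(x, out_dir, treatment = NULL,
                                   efficiency = 2, cutoff = 0.15,
                                   tolerance = 0.005,
                                   sd_method = c("mad", "sd")) {
  stopifnot(inherits(x, "ct_set"))
  sd_method <- match.arg(sd_method)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  groups <- ct_groups(x)

  summ <- summarize_ct(x, treatment = treatment)
  .write_tsv(.summary_wide(summ), file.path(out_dir, "summary.tsv"))

  subsets <- as.list(groups)
  names(subsets) <- groups
  if (length(groups) >= 2) subsets$combined <- groups

  results <- list(summary = summ, subsets = list())
  manifest_subsets <- list()
  for (s in names(subsets)) {
    sub <- subset_by_group(x, subsets[[s]])
    res <- analyze_subset(sub,
                          grouped = length(subsets[[s]]) > 1,
                          efficiency = efficiency, cutoff = cutoff,
                          tolerance = tolerance, sd_method = sd_method)
    tag <- gsub("[^A-Za-z0-9._-]", "", s)
    .write_tsv(.methods_table(res), file.path(out_dir, paste0("methods_", tag, ".tsv")))
    .write_tsv(res$genorm$v_series, file.path(out_dir, paste0("vseries_", tag, ".tsv")))
    .write_tsv(res$consensus$table, file.path(out_dir, paste0("consensus_", tag, ".tsv")))
    results$subsets[[s]] <- res
    manifest_subsets[[s]] <- list(
      groups = subsets[[s]],
      n_samples = nrow(sub$ct),
      optimal_n = res$genorm$optimal_n,
      recommended = res$consensus$recommended)
  }

  manifest <- list(
    tool = "refstab",
    version = as.character(utils::packageVersion("refstab")),
    n_samples = nrow(x$ct), n_genes = ncol(x$ct),
    groups = groups,
    parameters = list(efficiency = efficiency, cutoff = cutoff,
                      tolerance = tolerance, bestkeeper_sd = sd_method),
    subsets = manifest_subsets)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Run the five stability methods and consensus on one condition subset
#'
#' @param x A [ct_set()] (already subset to the samples of interest).
#' @param grouped Run NormFinder with the `group` annotation as its group
#'   factor (the combined-conditions analysis); otherwise ungrouped.
#' @param efficiency,cutoff,tolerance,sd_method See
#'   [run_stability_pipeline()].
#' @return List with `genorm` (a `genorm_result`), `normfinder`,
#'   `bestkeeper`, `delta_ct`, `cv` (raw method outputs), `methods` (the five
#'   [stability_result()]s) and `consensus` (a `consensus_table` with the
#'   geNorm optimal n driving the recommendation).
#' @export
analyze_subset <- function(x, grouped = FALSE, efficiency = 2, cutoff = 0.15,
                           tolerance = 0.005, sd_method = "mad") {
  gn <- genorm(x, efficiency = efficiency, cutoff = cutoff,
               tolerance = tolerance)
  rq <- relative_quantities(x, efficiency)
  nf <- normfinder(rq, groups = if (grouped) "group" else NULL)
  bk <- bestkeeper(x, sd_method = sd_method)
  dct <- delta_ct_stability(x)
  cv <- cv_stability(x)

  methods <- list(
    stability_result("normfinder", scores = nf$stability),
    stability_result("genorm", scores = gn$m_values, ranks = gn$ranks),
    stability_result("bestkeeper",
                     scores = stats::setNames(bk$gene_stats$sd_ct,
                                              bk$gene_stats$gene)),
    stability_result("delta_ct", scores = dct$scores),
    stability_result("cv", scores = stats::setNames(cv$cv, cv$gene)))
  consensus <- comprehensive_ranking(methods, optimal_n = gn$optimal_n)
  list(genorm = gn, normfinder = nf, bestkeeper = bk, delta_ct = dct,
       cv = cv, methods = methods, consensus = consensus)
}

# wide, table-style view of a ct_summary (pooled, per-group, delta columns)
.summary_wide <- function(summ) {
  s <- summ$summary
  genes <- unique(s$gene)
  grps <- setdiff(unique(s$group), "pooled")
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (g in c("pooled", grps)) {
    rows <- s[s$group == g, ]
    rows <- rows[match(genes, rows$gene), ]
    out[[paste0("mean_", g)]] <- rows$mean_ct
    out[[paste0("sd_", g)]] <- rows$sd_ct
    out[[paste0("n_", g)]] <- rows$n
  }
  if (!is.null(summ$delta)) {
    d <- summ$delta[match(genes, summ$delta$gene), ]
    out$delta_ct <- d$delta_ct
    out$sd_pooled2 <- d$sd_pooled
  }
  out
}

# per-gene score + rank of each method, consensus appended
.methods_table <- function(res) {
  genes <- sort(names(res$methods[[1]]$ranks))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (m in res$methods) {
    if (!is.null(m$scores)) out[[paste0(m$method, "_score")]] <- m$scores[genes]
    out[[paste0(m$method, "_rank")]] <- m$ranks[genes]
  }
  cons <- res$consensus$table
  out$geo_mean_rank <- cons$geo_mean_rank[match(genes, cons$gene)]
  out$final_rank <- cons$final_rank[match(genes, cons$gene)]
  out[order(out$final_rank), ]
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
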