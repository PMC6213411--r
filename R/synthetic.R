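#' Configure a synthetic RT-qPCR study
#'
#' Full parameterization of a simulated two-condition qPCR experiment: per-gene
#' per-condition Ct means and SDs (cycles), additive cell-line offsets shared
#' by all genes of a sample (mimicking global input-amount differences), the
#' number of biological replicates per cell line per condition, and a root
#' seed. Noise is additive Gaussian on the Ct scale: Ct is already logarithmic
#' in template amount, so this corresponds to log-normal abundance noise, the
#' regime all five stability estimators assume.
#'
#' An optional `sample_offset_sd` adds a shared Normal(0, sd) offset to every
#' gene of a sample (simulating loading / reverse-transcription efficiency
#' differences); ratio-based stability methods are expected to cancel it.
#'
#' @param genes Character vector of gene names.
#' @param mean_ct Numeric matrix, genes x conditions, of mean Ct (cycles).
#' @param sd_ct Numeric matrix, genes x conditions, of Ct SDs (cycles, >= 0).
#' @param conditions Character vector of condition labels (matrix columns).
#' @param cell_lines Named numeric vector of per-cell-line Ct offsets (cycles).
#' @param replicates Biological replicates per cell line per condition (>= 1).
#' @param seed Root integer seed; together with gene names it fully determines
#'   the generated matrix.
#' @param sample_offset_sd SD (cycles) of the optional shared per-sample
#'   offset; 0 (default) disables it.
#' @return An object of class `synthetic_config`.
#' @seealso [default_synthetic_config()], [simulate_ct()],
#'   [spike_unstable_gene()]
#' @export
synthetic_config <- function(genes, mean_ct, sd_ct, conditions,
                             cell_lines = c(line1 = 0),
                             replicates = 3L, seed = 0L,
                             sample_offset_sd = 0) {
  genes <- as.character(genes)
  mean_ct <- as.matrix(mean_ct)
  sd_ct <- as.matrix(sd_ct)
  if (anyDuplicated(genes)) stop("duplicate gene names")
  if (!all(dim(mean_ct) == c(length(genes), length(conditions))) ||
      !all(dim(sd_ct) == dim(mean_ct)))
    stop("`mean_ct` and `sd_ct` must be genes x conditions matrices")
  if (any(sd_ct < 0)) stop("all sd_ct must be >= 0")
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (is.null(names(cell_lines))) stop("`cell_lines` must be named")
  dimnames(mean_ct) <- dimnames(sd_ct) <- list(genes, conditions)
  structure(list(genes = genes, mean_ct = mean_ct, sd_ct = sd_ct,
                 conditions = as.character(conditions),
                 cell_lines = cell_lines,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 sample_offset_sd = sample_offset_sd),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d genes, %d conditions (%s), %d cell lines x %d replicates, seed %d\n",
    length(x$genes), length(x$conditions),
    paste(x$conditions, collapse = ", "),
    length(x$cell_lines), x$replicates, x$seed))
  invisible(x)
}

#' Default synthetic study: the osteosarcoma pH panel
#'
#' Builds a [synthetic_config()] emulating the reference study design: the 15
#' housekeeping genes of [hkg_reference_panel()], two conditions (pH 6.5 and
#' pH 7.4) with each gene's per-condition mean/SD taken from the published
#' summaries, three cell lines (HOS, MG-63, Saos-2) with configurable additive
#' offsets (default 0), and three biological replicates per cell line per
#' condition (9 samples per condition, 18 total).
#'
#' The published SDs conflate between-cell-line and residual variance; the
#' default treats the whole SD as residual (offsets 0), which is the
#' conservative choice when no separate variance components are reported.
#'
#' @param seed Root seed.
#' @param cell_line_offsets Named numeric vector of Ct offsets for the three
#'   cell lines.
#' @param replicates Biological replicates per cell line per condition.
#' @param sample_offset_sd See [synthetic_config()].
#' @return A `synthetic_config` with conditions `c("pH6.5", "pH7.4")`.
#' @export
default_synthetic_config <- function(seed = 0L,
                                     cell_line_offsets = c(HOS = 0,
                                                           `MG-63` = 0,
                                                           `Saos-2` = 0),
                                     replicates = 3L,
                                     sample_offset_sd = 0) {
  panel <- hkg_reference_panel()
  synthetic_config(
    genes = panel$gene,
    mean_ct = cbind(panel$mean_ph65, panel$mean_ph74),
    sd_ct = cbind(panel$sd_ph65, panel$sd_ph74),
    conditions = c("pH6.5", "pH7.4"),
    cell_lines = cell_line_offsets,
    replicates = replicates,
    seed = seed,
    sample_offset_sd = sample_offset_sd)
}

# Deterministic 31-bit substream seed from the root seed and a label, so that
# adding or removing a gene never perturbs another gene's draws.
.substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 2654435 + h + 1) %% 2147483647)
}

#' Generate a synthetic Ct expression set
#'
#' Draws Ct(sample, gene) = mean_ct(gene, condition) + offset(cell line) +
#' shared sample offset (if configured) + Normal(0, sd_ct(gene, condition))
#' noise, independently across genes. Each gene consumes its own random
#' substream derived from the root seed and the gene's name, so the same seed
#' always reproduces the same matrix and genes do not perturb one another.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return A validated [ct_set()] with annotations `group` (condition),
#'   `cell_line` and `replicate`, samples ordered condition-major.
#' @export
simulate_ct <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  root <- if (is.null(seed)) config$seed else as.integer(seed)

  lines <- names(config$cell_lines)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      cell_line = lines,
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("condition", "cell_line", "replicate")]
  sample_ids <- sprintf("%s_%s_r%d", grid$condition, grid$cell_line,
                        grid$replicate)
  n <- nrow(grid)
  k <- length(config$genes)

  ct <- matrix(NA_real_, nrow = n, ncol = k,
               dimnames = list(sample_ids, config$genes))
  for (g in config$genes) {
    set.seed(.substream_seed(root, g))
    noise <- stats::rnorm(n, 0, config$sd_ct[g, grid$condition])
    ct[, g] <- config$mean_ct[g, grid$condition] +
      config$cell_lines[grid$cell_line] + noise
  }
  if (config$sample_offset_sd > 0) {
    set.seed(.substream_seed(root, "..sample_offset.."))
    ct <- ct + stats::rnorm(n, 0, config$sample_offset_sd)
  }

  ct_set(ct, data.frame(sample = sample_ids, group = grid$condition,
                        cell_line = grid$cell_line,
                        replicate = grid$replicate,
                        stringsAsFactors = FALSE))
}

#' Shift one gene's mean under the second condition
#'
#' Returns a copy of the configuration in which the named gene's mean Ct under
#' the final configured condition is shifted by `condition_shift` cycles, all
#' else unchanged. This plants ground-truth condition-dependent instability
#' (the signature of a bad reference gene) for parameter-recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param gene Gene name to destabilize.
#' @param condition_shift Shift in cycles (one cycle is about a twofold
#'   expression change).
#' @return The modified `synthetic_config`.
#' @export
spike_unstable_gene <- function(config, gene, condition_shift) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!gene %in% config$genes)
    stop("unknown gene: ", gene)
  cond <- config$conditions[length(config$conditions)]
  config$mean_ct[gene, cond] <- config$mean_ct[gene, cond] + condition_shift
  config
}
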