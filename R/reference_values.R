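#' Reference Ct summaries for a 15-gene housekeeping panel
#'
#' Per-gene summary statistics (mean and sample SD of raw Ct, in cycles) for a
#' widely used panel of 15 candidate housekeeping genes measured by RT-qPCR in
#' three human osteosarcoma cell lines (HOS, MG-63, Saos-2) cultured for 24 h
#' at acidic (pH 6.5) and physiological (pH 7.4) extracellular pH, with three
#' biological replicates per cell line per condition (n = 9 per condition,
#' n = 18 pooled). These published summary values are the default
#' parameterization of [default_synthetic_config()] and the inputs of the
#' worked examples; the underlying replicate-level Ct data are not public.
#'
#' `delta_ct` is the difference of condition means (pH 6.5 minus pH 7.4): a
#' negative value means lower Ct, i.e. higher expression, under acidosis.
#'
#' @return Data frame with columns `gene`, `mean_pooled`, `sd_pooled`,
#'   `mean_ph65`, `sd_ph65`, `mean_ph74`, `sd_ph74`, `delta_ct`.
#' @export
hkg_reference_panel <- function() {
  tab <- c(
    "18S rRNA",  9.64, 0.91,  9.48, 0.80,  9.79, 1.04, -0.32,
    "ACTB",     20.47, 1.38, 20.35, 1.10, 20.58, 1.68, -0.24,
    "B2M",      20.75, 1.25, 20.15, 0.89, 21.35, 1.30, -1.20,
    "G6PD",     30.39, 1.55, 30.48, 1.76, 30.31, 1.39,  0.17,
    "GAPDH",    20.79, 0.77, 20.95, 0.71, 20.63, 0.84,  0.32,
    "GUSB",     30.23, 1.27, 30.07, 1.41, 30.39, 1.16, -0.33,
    "HMBS",     27.34, 1.41, 27.54, 1.43, 27.14, 1.45,  0.40,
    "HPRT1",    26.95, 1.60, 26.93, 1.75, 26.96, 1.54, -0.04,
    "PGK1",     22.41, 1.33, 22.43, 1.39, 22.39, 1.35,  0.04,
    "PPIA",     21.08, 1.35, 21.41, 1.25, 20.75, 1.43,  0.66,
    "RPL13a",   20.12, 1.02, 20.28, 1.05, 19.97, 1.03,  0.30,
    "SDHA",     25.04, 1.58, 24.84, 1.84, 25.24, 1.36, -0.40,
    "TBP",      27.59, 2.68, 26.87, 3.06, 28.31, 2.19, -1.43,
    "TUBB",     22.72, 1.59, 23.22, 1.65, 22.23, 1.44,  1.00,
    "YWHAZ",    23.12, 1.07, 23.39, 0.94, 22.85, 1.17,  0.54)
  m <- matrix(tab, ncol = 8, byrow = TRUE)
  out <- data.frame(gene = m[, 1], stringsAsFactors = FALSE)
  num <- c("mean_pooled", "sd_pooled", "mean_ph65", "sd_ph65",
           "mean_ph74", "sd_ph74", "delta_ct")
  for (i in seq_along(num)) out[[num[i]]] <- as.numeric(m[, i + 1])
  out
}

#' Published per-method stability ranks for the reference panel
#'
#' The rank columns assigned to the 15-gene panel by the five stability
#' methods (NormFinder, geNorm, BestKeeper, comparative delta-Ct, CV) in the
#' acidic-only, physiological-only, and combined analyses of the study behind
#' [hkg_reference_panel()]. geNorm's final most-stable pair is reported as a
#' tie and encoded here as 1.5/1.5 (average-rank convention).
#'
#' These printed ranks are inputs for the rank-aggregation worked examples:
#' the replicate-level scores behind them are not reproducible from public
#' data, but the consensus built from them is.
#'
#' @param condition One of `"acidic"` (pH 6.5), `"physiological"` (pH 7.4),
#'   `"combined"` (both conditions).
#' @return Data frame with columns `gene`, `normfinder`, `genorm`,
#'   `bestkeeper`, `delta_ct`, `cv` (numeric ranks, 1 = most stable).
#' @export
hkg_reference_ranks <- function(condition = c("acidic", "physiological",
                                              "combined")) {
  condition <- match.arg(condition)
  g <- function(...) data.frame(..., stringsAsFactors = FALSE)
  out <- switch(condition,
    acidic = g(
      gene = c("YWHAZ", "RPL13a", "PPIA", "18S rRNA", "GUSB", "ACTB", "HMBS",
               "GAPDH", "PGK1", "HPRT1", "TUBB", "SDHA", "B2M", "G6PD", "TBP"),
      normfinder = 1:15,
      genorm = c(1.5, 5, 4, 1.5, 6, 8, 7, 3, 11, 9, 10, 13, 12, 14, 15),
      bestkeeper = c(4, 6, 7, 2, 9, 5, 10, 1, 8, 13, 12, 11, 3, 14, 15),
      delta_ct = c(1, 5, 4, 3, 2, 10, 6, 7, 8, 9, 11, 12, 13, 14, 15),
      cv = c(2, 6, 9, 14, 4, 7, 5, 1, 10, 11, 12, 13, 3, 8, 15)),
    physiological = g(
      gene = c("YWHAZ", "TUBB", "ACTB", "PPIA", "SDHA", "RPL13a", "GUSB",
               "HPRT1", "18S rRNA", "B2M", "PGK1", "HMBS", "GAPDH", "G6PD",
               "TBP"),
      normfinder = 1:15,
      genorm = c(3, 8, 5, 4, 11, 1.5, 7, 6, 10, 1.5, 12, 13, 9, 14, 15),
      bestkeeper = c(4, 11, 14, 7, 10, 2, 5, 13, 3, 9, 8, 12, 1, 6, 15),
      delta_ct = c(1, 2, 3, 4, 6, 9, 7, 5, 10, 8, 12, 13, 11, 14, 15),
      cv = c(4, 11, 14, 12, 7, 5, 1, 8, 15, 10, 9, 6, 2, 3, 13)),
    combined = g(
      gene = c("YWHAZ", "18S rRNA", "GUSB", "PPIA", "ACTB", "RPL13a", "PGK1",
               "HPRT1", "TUBB", "GAPDH", "HMBS", "SDHA", "B2M", "G6PD", "TBP"),
      normfinder = 1:15,
      genorm = c(6, 8, 1.5, 4, 9, 5, 11, 3, 10, 7, 1.5, 12, 13, 14, 15),
      bestkeeper = c(4, 2, 9, 7, 8, 3, 6, 13, 14, 1, 10, 11, 5, 12, 15),
      delta_ct = c(1, 3, 2, 5, 7, 4, 8, 6, 11, 9, 10, 12, 13, 14, 15),
      cv = c(3, 14, 2, 11, 12, 4, 8, 7, 13, 1, 6, 10, 9, 5, 15)))
  out
}

#' Published coefficient-of-variation values for the reference panel
#'
#' The CV (sample SD of Ct divided by mean Ct) printed for each gene in the
#' acidic, physiological and combined analyses of the study behind
#' [hkg_reference_panel()], rounded to 3 decimals as published. Used as
#' worked-example expectations: recomputing SD/mean from the panel summaries
#' reproduces these to the printed precision for all but a handful of entries
#' whose inputs lose the third decimal to rounding.
#'
#' @return Data frame with columns `gene`, `cv_acidic`, `cv_physiological`,
#'   `cv_combined`.
#' @export
hkg_reference_cv <- function() {
  panel <- hkg_reference_panel()
  cv <- c(
    "18S rRNA", 0.084, 0.106, 0.095,
    "ACTB",     0.054, 0.082, 0.068,
    "B2M",      0.044, 0.061, 0.061,
    "G6PD",     0.058, 0.046, 0.051,
    "GAPDH",    0.034, 0.040, 0.037,
    "GUSB",     0.047, 0.038, 0.042,
    "HMBS",     0.052, 0.053, 0.051,
    "HPRT1",    0.065, 0.057, 0.059,
    "PGK1",     0.062, 0.060, 0.059,
    "PPIA",     0.058, 0.069, 0.064,
    "RPL13a",   0.052, 0.052, 0.051,
    "SDHA",     0.074, 0.054, 0.063,
    "TBP",      0.114, 0.077, 0.097,
    "TUBB",     0.071, 0.065, 0.070,
    "YWHAZ",    0.040, 0.051, 0.046)
  m <- matrix(cv, ncol = 4, byrow = TRUE)
  out <- data.frame(gene = m[, 1],
                    cv_acidic = as.numeric(m[, 2]),
                    cv_physiological = as.numeric(m[, 3]),
                    cv_combined = as.numeric(m[, 4]),
                    stringsAsFactors = FALSE)
  stopifnot(identical(sort(out$gene), sort(panel$gene)))
  out
}
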