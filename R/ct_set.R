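#' Construct a validated Ct expression set
#'
#' The single input currency of all downstream stability analyses: a
#' samples-by-genes matrix of raw threshold-cycle (Ct) values together with
#' per-sample annotations. Ct is the PCR cycle at which a gene's amplification
#' signal crosses threshold and is inversely proportional to log template
#' abundance (one cycle is roughly a twofold change).
#'
#' @param ct Numeric matrix of Ct values, samples in rows, genes in columns.
#'   Both dimensions must be named. Values must be finite; missing entries are
#'   carried as `NA` (never silently coerced to zero).
#' @param annotations Data frame with one row per sample, containing at least
#'   columns `sample` and `group` (condition label); optional columns
#'   `cell_line` and `replicate` are kept and filled with `NA` when absent.
#'   Rows are matched to the matrix by the `sample` column.
#' @return An object of class `ct_set`: a list with elements `ct` (the matrix)
#'   and `annotations` (the data frame, reordered to match the matrix rows).
#' @examples
#' m <- matrix(c(20, 21, 30, 31), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("gA", "gB")))
#' ann <- data.frame(sample = c("s1", "s2"), group = c("ctrl", "acid"))
#' es <- ct_set(m, ann)
#' ct_genes(es)
#' @export
ct_set <- function(ct, annotations) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have sample row names and gene column names")
  if (anyDuplicated(rownames(ct)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  if (any(is.infinite(ct)))
    stop("Ct values must be finite (use NA for missing entries)")

  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(annotations)))
    stop("`annotations` must contain columns `sample` and `group`")
  if (anyDuplicated(annotations$sample))
    stop("duplicate sample identifiers in annotations")
  missing_ann <- setdiff(rownames(ct), annotations$sample)
  if (length(missing_ann))
    stop("samples without annotation row: ", paste(missing_ann, collapse = ", "))
  annotations <- annotations[match(rownames(ct), annotations$sample), , drop = FALSE]
  rownames(annotations) <- NULL
  if (any(is.na(annotations$group)) || any(annotations$group == ""))
    stop("every sample must have a non-empty `group` annotation")
  for (col in c("cell_line", "replicate"))
    if (is.null(annotations[[col]])) annotations[[col]] <- NA
  annotations <- annotations[, c("sample", "group", "cell_line", "replicate")]

  structure(list(ct = ct, annotations = annotations), class = "ct_set")
}

#' @export
print.ct_set <- function(x, ...) {
  cat(sprintf("<ct_set> %d samples x %d genes\n", nrow(x$ct), ncol(x$ct)))
  grp <- table(x$annotations$group)
  cat("groups: ", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "), "\n")
  n_na <- sum(is.na(x$ct))
  if (n_na > 0) cat("missing Ct entries:", n_na, "\n")
  invisible(x)
}

#' @export
dim.ct_set <- function(x) dim(x$ct)

#' @export
as.matrix.ct_set <- function(x, ...) x$ct

#' Gene and sample identifiers of a `ct_set`
#' @param x A `ct_set`.
#' @return Character vector of identifiers, in storage order.
#' @export
ct_genes <- function(x) colnames(x$ct)

#' @rdname ct_genes
#' @export
ct_samples <- function(x) rownames(x$ct)

#' Group labels of a `ct_set`, in first-appearance order
#' @param x A `ct_set`.
#' @return Character vector of unique condition labels.
#' @export
ct_groups <- function(x) unique(x$annotations$group)

#' Read a Ct table from delimited text
#'
#' Reads a rectangular Ct table plus per-sample annotations. In the default
#' orientation, samples are rows: the first column holds sample identifiers and
#' the reserved columns `group`, `cell_line`, `replicate` hold annotations;
#' all remaining columns are genes. With `orientation = "genes_in_rows"` the
#' table is transposed on read (first column gene ids, remaining columns
#' samples) and annotations must come from the `annotations` sidecar.
#'
#' Cells that read as `NA` (or are empty) become missing Ct entries and raise a
#' warning; any other non-numeric cell is an error naming the offending
#' row and column.
#'
#' @param path Path to the delimited file (UTF-8).
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @param annotations Optional sidecar: a data frame or path to a delimited
#'   file with columns `sample`, `group` (and optionally `cell_line`,
#'   `replicate`). Required when the main table carries no annotation columns.
#' @return A validated [ct_set()].
#' @export
read_ct_table <- function(path, sep = ",",
                          orientation = c("samples_in_rows", "genes_in_rows"),
                          annotations = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stop("table must have an identifier column plus data columns")
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]

  reserved <- c("group", "cell_line", "replicate")
  if (orientation == "samples_in_rows") {
    ann_cols <- intersect(reserved, names(body))
    ann_tab <- NULL
    if (length(ann_cols)) {
      ann_tab <- cbind(data.frame(sample = ids, stringsAsFactors = FALSE),
                       body[, ann_cols, drop = FALSE])
      body <- body[, setdiff(names(body), ann_cols), drop = FALSE]
    }
    mat <- .parse_ct_cells(body, row_ids = ids, col_ids = names(body))
    rownames(mat) <- ids
  } else {
    mat <- .parse_ct_cells(body, row_ids = ids, col_ids = names(body))
    rownames(mat) <- ids
    mat <- t(mat)
    ann_tab <- NULL
  }

  if (!is.null(annotations)) {
    ann_tab <- if (is.character(annotations)) {
      utils::read.table(annotations, sep = sep, header = TRUE,
                        check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      as.data.frame(annotations, stringsAsFactors = FALSE)
    }
  }
  if (is.null(ann_tab))
    stop("no annotations found: supply reserved columns (group, cell_line, ",
         "replicate) or an `annotations` sidecar")
  ct_set(mat, ann_tab)
}

# parse a character data frame into a numeric matrix with per-cell errors
.parse_ct_cells <- function(body, row_ids, col_ids) {
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(NULL, col_ids))
  n_missing <- 0L
  for (j in seq_along(body)) {
    cell <- trimws(body[[j]])
    empty <- is.na(cell) | cell == "" | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': \"%s\"",
                   row_ids[bad[1]], col_ids[j], cell[bad[1]]))
    n_missing <- n_missing + sum(empty)
    mat[, j] <- num
  }
  if (n_missing > 0)
    warning(sprintf("%d Ct cell(s) read as missing (NA)", n_missing))
  mat
}

#' Write a `ct_set` to delimited text
#'
#' Writes samples in rows with annotation columns `group`, `cell_line`,
#' `replicate` after the sample-id column, so that [read_ct_table()] round
#' trips the object.
#'
#' @param x A `ct_set`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "ct_set"))
  out <- cbind(x$annotations, as.data.frame(x$ct, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a `ct_set` to selected condition groups
#'
#' @param x A `ct_set`.
#' @param groups Character vector of condition labels to keep.
#' @return A `ct_set` containing exactly the samples whose group is in
#'   `groups`, sample and gene order preserved.
#' @export
subset_by_group <- function(x, groups) {
  stopifnot(inherits(x, "ct_set"))
  available <- ct_groups(x)
  unknown <- setdiff(groups, available)
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "))
  keep <- x$annotations$group %in% groups
  ct_set(x$ct[keep, , drop = FALSE], x$annotations[keep, , drop = FALSE])
}

#' Per-gene, per-condition Ct summaries
#'
#' Computes, for every gene, the mean and sample SD of Ct within each condition
#' group and pooled over all samples. When exactly two groups are present it
#' also reports the difference of condition means (treatment minus reference,
#' i.e. a positive delta means higher Ct, hence lower expression, under
#' treatment) together with the pooled two-group SD
#' sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)).
#'
#' Missing Ct entries are dropped pairwise per statistic; a group reduced to
#' fewer than two observations for a gene gets `NA` SD with a warning.
#'
#' @param x A `ct_set`.
#' @param treatment Group label to treat as the "treatment" arm of the delta
#'   (defaults to the first group in annotation order).
#' @return An object of class `ct_summary`: list with `summary` (long data
#'   frame: gene, group incl. `"pooled"`, mean_ct, sd_ct, n) and `delta`
#'   (data frame gene, delta_ct, sd_pooled, or `NULL` unless exactly two
#'   groups).
#' @export
summarize_ct <- function(x, treatment = NULL) {
  stopifnot(inherits(x, "ct_set"))
  groups <- ct_groups(x)
  if (is.null(treatment)) treatment <- groups[1]
  if (!treatment %in% groups)
    stop("unknown treatment group: ", treatment)

  one <- function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
      n = length(v))
  }
  rows <- list()
  low_n <- character(0)
  for (g in ct_genes(x)) {
    for (grp in c(groups, "pooled")) {
      v <- if (grp == "pooled") x$ct[, g] else x$ct[x$annotations$group == grp, g]
      s <- one(v)
      if (grp != "pooled" && s["n"] < 2) low_n <- c(low_n, paste0(g, "/", grp))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group = grp, mean_ct = s[["mean"]], sd_ct = s[["sd"]],
        n = as.integer(s[["n"]]), stringsAsFactors = FALSE)
    }
  }
  if (length(low_n))
    warning("SD reported as missing for gene/group cells with n < 2: ",
            paste(low_n, collapse = ", "))
  summary <- do.call(rbind, rows)

  delta <- NULL
  if (length(groups) == 2) {
    other <- setdiff(groups, treatment)
    a <- summary[summary$group == treatment, ]
    b <- summary[summary$group == other, ]
    a <- a[match(ct_genes(x), a$gene), ]
    b <- b[match(ct_genes(x), b$gene), ]
    sd_pooled <- sqrt(((a$n - 1) * a$sd_ct^2 + (b$n - 1) * b$sd_ct^2) /
                        (a$n + b$n - 2))
    delta <- data.frame(gene = ct_genes(x),
                        delta_ct = a$mean_ct - b$mean_ct,
                        sd_pooled = sd_pooled,
                        stringsAsFactors = FALSE)
    attr(delta, "treatment") <- treatment
    attr(delta, "reference") <- other
  }
  structure(list(summary = summary, delta = delta), class = "ct_summary")
}

#' @export
print.ct_summary <- function(x, digits = 2, ...) {
  s <- x$summary
  wide <- stats::reshape(
    s, direction = "wide", idvar = "gene", timevar = "group",
    v.names = c("mean_ct", "sd_ct", "n"))
  if (!is.null(x$delta)) {
    wide$delta_ct <- x$delta$delta_ct[match(wide$gene, x$delta$gene)]
    wide$sd_pooled <- x$delta$sd_pooled[match(wide$gene, x$delta$gene)]
  }
  num <- vapply(wide, is.numeric, logical(1))
  wide[num] <- lapply(wide[num], round, digits)
  print(wide, row.names = FALSE)
  invisible(x)
}
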