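#' Differential-expression calling configuration
#'
#' Settings for the per-contrast DEG caller used by [call_degs()]. The caller
#' is a Welch t-test on log2-scale values with Benjamini-Hochberg adjustment
#' and a fold-change floor; all thresholds are configurable so that the
#' downstream co-regulation statistics, which consume only the binary and
#' signed matrices, remain independent of the DE method. Precomputed calls
#' from an external DE tool can be imported directly with
#' [read_deg_matrix()].
#'
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param min_lfc minimum absolute log2 fold change (default 1).
#' @param logged logical; `TRUE` (default) if expression values are already on
#'   log2 scale, `FALSE` to apply `log2(x + pseudocount)` first.
#' @param pseudocount added before logging when `logged = FALSE`.
#' @return a list of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, min_lfc = 1.0, logged = TRUE,
                      pseudocount = 1) {
  stopifnot(alpha > 0, alpha <= 1, min_lfc >= 0, pseudocount >= 0)
  structure(list(alpha = alpha, min_lfc = min_lfc, logged = logged,
                 pseudocount = pseudocount),
            class = "de_config")
}

#' Construct a two-group contrast
#'
#' A contrast is one two-group comparison (treatment vs control) within a
#' study: a genes x samples expression matrix plus a binary group label per
#' sample. Contrasts are the unit columns of the binary DEG matrix.
#'
#' @param contrast_id character scalar identifier.
#' @param expression numeric matrix, genes in rows (rownames required),
#'   samples in columns.
#' @param group_labels vector of 0/1 labels, one per sample (0 = reference
#'   group, 1 = comparison group). At least 2 samples per group.
#' @return a list of class `contrast_set`.
#' @export
contrast_set <- function(contrast_id, expression, group_labels) {
  stopifnot(is.character(contrast_id), length(contrast_id) == 1L)
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)))
    stop("expression matrix must have gene identifiers as rownames")
  if (length(group_labels) != ncol(expression))
    stop("one group label required per sample")
  group_labels <- as.integer(group_labels)
  if (!all(group_labels %in% c(0L, 1L)))
    stop("group labels must be 0 or 1")
  tab <- tabulate(group_labels + 1L, nbins = 2L)
  if (any(tab < 2L))
    stop("degenerate contrast '", contrast_id,
         "': fewer than 2 samples in a group")
  structure(list(contrast_id = contrast_id, expression = expression,
                 group_labels = group_labels),
            class = "contrast_set")
}

# Row-wise sample variance of a matrix (denominator n - 1).
.row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Call differentially expressed genes in one contrast
#'
#' Vectorised Welch (unequal-variance) t-test per gene between the two
#' groups, BH adjustment across genes, and a log2 fold-change floor. A gene
#' is a DEG iff its adjusted p-value is below `config$alpha` and
#' `|log2FC| >= config$min_lfc`; the sign is the sign of
#' `mean(group 1) - mean(group 0)` on log2 scale. All-constant genes get
#' indicator 0 and sign 0.
#'
#' @param contrast a [contrast_set()].
#' @param config a [de_config()].
#' @return list with elements `deg` (0/1 integer vector), `sign`
#'   ({-1, 0, +1} integer vector), `lfc`, `p_value`, `p_adjusted`, all named
#'   by gene.
#' @export
call_degs <- function(contrast, config = de_config()) {
  stopifnot(inherits(contrast, "contrast_set"))
  x <- contrast$expression
  if (!config$logged) x <- log2(x + config$pseudocount)
  g <- contrast$group_labels
  x0 <- x[, g == 0L, drop = FALSE]
  x1 <- x[, g == 1L, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  if (n0 < 2L || n1 < 2L)
    stop("degenerate contrast: fewer than 2 samples in a group")

  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- .row_vars(x0); v1 <- .row_vars(x1)
  lfc <- m1 - m0
  se2 <- v0 / n0 + v1 / n1
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(-abs(tt), df)
  # zero within-group variance: identical groups are never DEGs, separated
  # constant groups always are
  flat <- se2 == 0
  p[flat & lfc == 0] <- 1
  p[flat & lfc != 0] <- 0
  padj <- p.adjust(p, method = "BH")
  deg <- as.integer(padj < config$alpha & abs(lfc) >= config$min_lfc)
  sgn <- ifelse(deg == 1L, sign(lfc), 0)
  genes <- rownames(x)
  list(deg = setNames(deg, genes),
       sign = setNames(as.integer(sgn), genes),
       lfc = setNames(lfc, genes),
       p_value = setNames(p, genes),
       p_adjusted = setNames(padj, genes))
}

#' Build the binary and signed DEG matrices from a list of contrasts
#'
#' Column k of the binary matrix is the 0/1 DEG indicator of contrast k; the
#' signed companion holds the direction of change ({-1, 0, +1}) and is
#' nonzero exactly where the binary matrix is 1. All contrasts must share the
#' same ordered gene universe.
#'
#' @param contrast_list list of [contrast_set()] objects.
#' @param config a [de_config()].
#' @return list with integer matrices `binary` (0/1) and `signed`
#'   ({-1,0,+1}), genes x contrasts, with dimnames.
#' @export
build_deg_matrices <- function(contrast_list, config = de_config()) {
  stopifnot(length(contrast_list) >= 1L)
  genes <- rownames(contrast_list[[1L]]$expression)
  for (cs in contrast_list) {
    g <- rownames(cs$expression)
    if (!identical(g, genes)) {
      bad <- union(setdiff(g, genes), setdiff(genes, g))
      if (length(bad) == 0L) bad <- "(same set, different order)"
      stop("gene universes disagree across contrasts; offending ",
           "identifiers: ", paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  ids <- vapply(contrast_list, function(cs) cs$contrast_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicated contrast_id")
  calls <- lapply(contrast_list, call_degs, config = config)
  binary <- vapply(calls, function(z) z$deg, integer(length(genes)))
  signed <- vapply(calls, function(z) z$sign, integer(length(genes)))
  binary <- matrix(binary, nrow = length(genes),
                   dimnames = list(genes, ids))
  signed <- matrix(signed, nrow = length(genes),
                   dimnames = list(genes, ids))
  list(binary = binary, signed = signed)
}

#' Read per-contrast expression tables and a design table
#'
#' Expects one TSV per contrast (first column gene id, remaining columns
#' samples) and a design TSV with columns `sample`, `contrast_id`, `group`
#' (0/1). Expression files are looked up as `<contrast_id>.tsv` under `dir`.
#'
#' @param design_path path to the design TSV.
#' @param dir directory holding `<contrast_id>.tsv` expression files.
#' @return list of [contrast_set()] objects, in design order of first
#'   appearance.
#' @export
read_expression_contrasts <- function(design_path, dir) {
  design <- read.delim(design_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "contrast_id", "group")
  if (!all(need %in% names(design)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  ids <- unique(design$contrast_id)
  lapply(ids, function(id) {
    path <- file.path(dir, paste0(id, ".tsv"))
    tab <- read.delim(path, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(mat) <- tab[[1L]]
    d <- design[design$contrast_id == id, , drop = FALSE]
    missing <- setdiff(d$sample, colnames(mat))
    if (length(missing))
      stop("samples in design but not in ", path, ": ",
           paste(missing, collapse = ", "))
    mat <- mat[, d$sample, drop = FALSE]
    contrast_set(id, mat, d$group)
  })
}

#' Write a binary or signed DEG matrix to TSV
#'
#' @param mat genes x contrasts matrix with dimnames.
#' @param path output file.
#' @export
write_deg_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary or signed DEG matrix from TSV
#'
#' @param path TSV with gene rows (first column gene id) and contrast
#'   columns.
#' @param signed logical; if `TRUE`, values must be in \{-1, 0, 1\},
#'   otherwise in \{0, 1\}.
#' @return integer matrix with dimnames.
#' @export
read_deg_matrix <- function(path, signed = FALSE) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  storage.mode(mat) <- "integer"
  allowed <- if (signed) c(-1L, 0L, 1L) else c(0L, 1L)
  if (!all(mat %in% allowed))
    stop("matrix values outside ", if (signed) "{-1,0,1}" else "{0,1}")
  mat
}
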