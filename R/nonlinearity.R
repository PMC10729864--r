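#' Non-linear score of a co-regulated gene pair
#'
#' `1 - |1 - 2 * n_discordant / n|`: 1 when a pair's co-regulated contrasts
#' split evenly between concordant and discordant changes, 0 when they are
#' entirely one or entirely the other. Symmetric in concordant/discordant
#' counts.
#'
#' @param n co-regulated contrast count(s), `N >= 1`.
#' @param n_discordant discordant co-regulation count(s) `N+/-`,
#'   `0 <= n_discordant <= n`.
#' @return score(s) in `[0, 1]`.
#' @export
nonlinear_score <- function(n, n_discordant) {
  if (any(n < 1)) stop("undefined score: pair not co-regulated (n = 0)")
  if (any(n_discordant < 0 | n_discordant > n))
    stop("n_discordant must lie in 0..n")
  1 - abs(1 - 2 * n_discordant / n)
}

#' Categorise a pair by its concordance mixture
#'
#' `nonlinear` when the score reaches `score_cutoff`; otherwise
#' `linear_concordant` when fewer than half of the co-regulated contrasts
#' are discordant, `linear_discordant` when more.
#'
#' @param n,n_discordant as in [nonlinear_score()].
#' @param score_cutoff non-linear threshold (default 0.5).
#' @return character vector of categories.
#' @export
categorize_pair <- function(n, n_discordant, score_cutoff = 0.5) {
  score <- nonlinear_score(n, n_discordant)
  ifelse(score >= score_cutoff, "nonlinear",
         ifelse(n_discordant / n < 0.5, "linear_concordant",
                "linear_discordant"))
}

#' Annotate a pair-statistics table with non-linearity scores
#'
#' @param pair_stats data frame with `n` and `n_discordant` columns.
#' @param score_cutoff passed to [categorize_pair()].
#' @return `pair_stats` with `nonlinear_score` and `category` columns.
#' @export
annotate_nonlinearity <- function(pair_stats, score_cutoff = 0.5) {
  if (nrow(pair_stats) == 0L) {
    pair_stats$nonlinear_score <- numeric(0L)
    pair_stats$category <- character(0L)
    return(pair_stats)
  }
  pair_stats$nonlinear_score <-
    nonlinear_score(pair_stats$n, pair_stats$n_discordant)
  pair_stats$category <-
    categorize_pair(pair_stats$n, pair_stats$n_discordant, score_cutoff)
  pair_stats
}

#' Detect Simpson's-paradox geometry for a gene pair
#'
#' A pair follows Simpson's paradox when its two genes are correlated with
#' one sign within every contrast but with the opposite sign when the
#' contrasts' samples are pooled — the pooled trend is a between-contrast
#' confounder, not the genes' relationship. The flag is raised iff all
#' within-contrast Pearson correlations share one sign with
#' `|r| >= r_within` across at least `min_contrasts` contrasts, and the
#' pooled correlation over those contrasts' samples has the opposite sign
#' with `|r| >= r_pooled`.
#'
#' @param contrasts list of [contrast_set()] objects holding the expression.
#' @param gene_i,gene_j gene identifiers (must be rownames in every used
#'   contrast).
#' @param contrast_ids optional subset of contrast ids to use (e.g. the
#'   contrasts in which the pair co-regulates); default all.
#' @param r_within minimum within-contrast `|r|` (default 0.3).
#' @param r_pooled minimum pooled `|r|` (default 0.3).
#' @param min_contrasts minimum number of qualifying contrasts (default 3).
#' @return list with `simpson_flag`, `pooled_r`, `per_contrast_r` (named by
#'   contrast id).
#' @export
detect_simpson <- function(contrasts, gene_i, gene_j, contrast_ids = NULL,
                           r_within = 0.3, r_pooled = 0.3,
                           min_contrasts = 3L) {
  ids <- vapply(contrasts, function(cs) cs$contrast_id, character(1L))
  if (!is.null(contrast_ids)) {
    keep <- ids %in% contrast_ids
    contrasts <- contrasts[keep]
    ids <- ids[keep]
  }
  rs <- numeric(0L)
  xi_all <- xj_all <- numeric(0L)
  for (k in seq_along(contrasts)) {
    ex <- contrasts[[k]]$expression
    if (!all(c(gene_i, gene_j) %in% rownames(ex)))
      stop("gene not present in contrast ", ids[k])
    if (ncol(ex) < 3L) next
    xi <- ex[gene_i, ]; xj <- ex[gene_j, ]
    if (sd(xi) == 0 || sd(xj) == 0) {
      warning("constant expression in contrast ", ids[k], "; excluded")
      next
    }
    rs <- c(rs, setNames(cor(xi, xj), ids[k]))
    xi_all <- c(xi_all, xi); xj_all <- c(xj_all, xj)
  }
  pooled <- if (length(xi_all) >= 3L && sd(xi_all) > 0 && sd(xj_all) > 0)
    cor(xi_all, xj_all) else NA_real_
  qual <- length(rs) >= min_contrasts &&
    all(abs(rs) >= r_within) &&
    (all(rs > 0) || all(rs < 0))
  flag <- isTRUE(qual) && !is.na(pooled) &&
    abs(pooled) >= r_pooled && sign(pooled) != sign(rs[1L])
  list(simpson_flag = flag, pooled_r = pooled, per_contrast_r = rs)
}
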