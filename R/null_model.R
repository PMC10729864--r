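#' Sample a random binary matrix with the observed margins
#'
#' Draws one 0/1 matrix with exactly the row sums and column sums of
#' `observed`, by running curveball trades from the observed matrix. Under
#' the null every gene keeps its chance of being a DEG and every contrast
#' keeps its number of DEGs; only the joint placement is randomised.
#'
#' @param observed 0/1 integer matrix (genes x contrasts).
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   first. Leave `NULL` to use the current RNG stream.
#' @param n_swaps number of curveball trades; default `5 * sum(observed)`
#'   (five trades per nonzero entry), enough to decorrelate sparse matrices
#'   from their start state.
#' @return 0/1 integer matrix with the same dimnames and margins.
#' @export
sample_fixed_margins <- function(observed, seed = NULL, n_swaps = NULL) {
  .check_binary(observed)
  if (!is.null(seed)) set.seed(seed)
  nnz <- sum(observed != 0)
  if (nnz == 0L || nrow(observed) < 2L || ncol(observed) < 2L)
    return(observed)
  if (is.null(n_swaps)) n_swaps <- 5L * nnz
  m <- observed
  storage.mode(m) <- "integer"
  out <- curveball_trades(m, as.integer(n_swaps))
  dimnames(out) <- dimnames(observed)
  out
}

.check_binary <- function(m) {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L)))
    stop("expected a 0/1 matrix")
  invisible(m)
}

#' Build the per-pair null co-regulation ensemble
#'
#' Samples `n_samplings` fixed-margin matrices (independent curveball
#' restarts from the observed matrix, sub-seeded deterministically from
#' `seed`) and records, for every retained gene pair, the number of contrasts
#' in which both genes are DEGs in each sampling. These count vectors are the
#' per-pair null random variables to which the beta-binomial is fitted.
#'
#' Samplings are processed one at a time; only the per-pair counts are kept.
#'
#' @param observed 0/1 integer matrix (genes x contrasts) with rownames.
#' @param n_samplings number of random matrices (default 1000).
#' @param seed master seed; sub-seeds for each sampling are drawn from it.
#' @param min_obs retain pairs whose observed co-regulation count is at least
#'   this (default 2). Pairs never observed together cannot reach
#'   significance; set to 0 to keep all pairs on small inputs.
#' @param pairs optional data frame with columns `gene_i`, `gene_j` naming
#'   the pairs to track, overriding the `min_obs` filter.
#' @param n_swaps trades per sampling; see [sample_fixed_margins()].
#' @return list of class `null_ensemble`: `pairs` (data frame `gene_i`,
#'   `gene_j`), `counts` (pairs x samplings integer matrix), `K`, `
#'   n_samplings`, `seed`.
#' @export
build_null_ensemble <- function(observed, n_samplings = 1000L, seed = 1L,
                                min_obs = 2L, pairs = NULL, n_swaps = NULL) {
  .check_binary(observed)
  stopifnot(n_samplings >= 2L)
  if (is.null(rownames(observed)))
    stop("observed matrix must have gene rownames")
  genes <- rownames(observed)

  if (is.null(pairs)) {
    cc <- tcrossprod(observed)
    ut <- which(upper.tri(cc) & cc >= min_obs, arr.ind = TRUE)
    pairs <- data.frame(gene_i = genes[ut[, 1L]], gene_j = genes[ut[, 2L]],
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L) {
    warning("no gene pairs retained by the pair filter; empty null ensemble")
    return(structure(list(pairs = pairs,
                          counts = matrix(0L, 0L, n_samplings),
                          K = ncol(observed), n_samplings = n_samplings,
                          seed = seed),
                     class = "null_ensemble"))
  }

  ia <- match(pairs$gene_i, genes)
  ja <- match(pairs$gene_j, genes)
  if (anyNA(ia) || anyNA(ja)) stop("pair gene not found in matrix rownames")
  used <- sort(unique(c(ia, ja)))
  ia2 <- match(ia, used); ja2 <- match(ja, used)
  idx <- cbind(ia2, ja2)

  nnz <- sum(observed != 0)
  if (is.null(n_swaps)) n_swaps <- 5L * nnz
  m <- observed
  storage.mode(m) <- "integer"

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_samplings)
  counts <- matrix(0L, nrow(pairs), n_samplings)
  for (s in seq_len(n_samplings)) {
    set.seed(sub_seeds[s])
    samp <- if (nnz == 0L) m else curveball_trades(m, as.integer(n_swaps))
    cc <- tcrossprod(samp[used, , drop = FALSE])
    counts[, s] <- as.integer(cc[idx])
  }
  structure(list(pairs = pairs, counts = counts, K = ncol(observed),
                 n_samplings = n_samplings, seed = seed),
            class = "null_ensemble")
}

#' Write a null ensemble's pair counts to TSV
#'
#' Plain-text lossless dump for re-use across FDR runs: columns `gene_i`,
#' `gene_j`, then one integer column per sampling.
#'
#' @param ensemble a `null_ensemble` from [build_null_ensemble()].
#' @param path output file.
#' @export
write_null_counts <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  cnt <- ensemble$counts
  colnames(cnt) <- paste0("s", seq_len(ncol(cnt)))
  df <- data.frame(ensemble$pairs, cnt, K = ensemble$K,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a null ensemble written by [write_null_counts()]
#'
#' @param path TSV produced by [write_null_counts()].
#' @return a `null_ensemble` (with `seed = NA`).
#' @export
read_null_counts <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  scol <- grep("^s[0-9]+$", names(df))
  counts <- as.matrix(df[, scol, drop = FALSE])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  structure(list(pairs = df[, c("gene_i", "gene_j"), drop = FALSE],
                 counts = counts, K = df$K[1L],
                 n_samplings = length(scol), seed = NA_integer_),
            class = "null_ensemble")
}
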