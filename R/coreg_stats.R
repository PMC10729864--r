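#' Count observed co-regulation per gene pair
#'
#' For every unordered gene pair, `n` is the number of contrasts in which
#' both genes are DEGs and `n_discordant` the number of those contrasts in
#' which they change in opposite directions. Pairs are reported in canonical
#' order (`gene_i < gene_j` by identifier sort); self-pairs are excluded.
#'
#' @param binary 0/1 genes x contrasts matrix with rownames.
#' @param signed \{-1,0,+1\} companion matrix, nonzero exactly where
#'   `binary` is 1.
#' @param min_obs report only pairs with `n >= min_obs` (default 2).
#' @return data frame with columns `gene_i`, `gene_j`, `n`, `n_discordant`,
#'   `K`.
#' @export
count_coregulation <- function(binary, signed, min_obs = 2L) {
  .check_binary(binary)
  if (!identical(dim(binary), dim(signed)) ||
      !identical(dimnames(binary), dimnames(signed)))
    stop("binary and signed matrices are not aligned")
  if (!all(signed %in% c(-1L, 0L, 1L)))
    stop("signed matrix values must be in {-1,0,1}")
  if (!identical(unname(binary != 0L), unname(signed != 0L)))
    stop("signed matrix must be nonzero exactly where binary is 1")
  genes <- rownames(binary)
  if (is.null(genes)) stop("matrices must have gene rownames")

  cc <- tcrossprod(binary)                 # co-DEG counts
  ss <- tcrossprod(signed)                 # concordant - discordant
  ut <- which(upper.tri(cc) & cc >= min_obs, arr.ind = TRUE)
  n <- as.integer(cc[ut])
  n_disc <- as.integer((n - ss[ut]) / 2)

  gi <- genes[ut[, 1L]]; gj <- genes[ut[, 2L]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  out <- data.frame(gene_i = gi, gene_j = gj, n = n,
                    n_discordant = n_disc, K = ncol(binary),
                    stringsAsFactors = FALSE)
  out[order(out$gene_i, out$gene_j), , drop = FALSE]
}

#' Beta-binomial parameters
#'
#' The per-contrast co-regulation probability is modelled as a latent
#' Beta(alpha, beta) draw; the co-regulation count over K contrasts is then
#' beta-binomial. `degenerate = TRUE` marks a null vector with no variation
#' (point mass at `point_mass`), for which no beta fit exists.
#'
#' @param alpha,beta positive shape parameters.
#' @param K number of contrasts (trials).
#' @param degenerate logical point-mass flag.
#' @param point_mass location of the point mass when degenerate.
#' @return list of class `betabinom_params`.
#' @export
betabinom_params <- function(alpha, beta, K, degenerate = FALSE,
                             point_mass = NA_real_) {
  stopifnot(K >= 1)
  if (!degenerate && (alpha <= 0 || beta <= 0))
    stop("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta, K = as.integer(K),
                 degenerate = degenerate, point_mass = point_mass),
            class = "betabinom_params")
}

# vectorised pmf over n, with scalar K and vector-or-scalar alpha, beta
.bb_pmf <- function(n, K, alpha, beta) {
  exp(lchoose(K, n) + lbeta(n + alpha, K - n + beta) - lbeta(alpha, beta))
}

# vectorised inclusive upper tail P(X >= n) per pair
.bb_upper_tail <- function(n, K, alpha, beta) {
  p <- numeric(length(n))
  for (j in 0:K) {
    pj <- .bb_pmf(j, K, alpha, beta)
    hit <- j >= n
    p[hit] <- p[hit] + (if (length(pj) == 1L) pj else pj[hit])
  }
  pmin(pmax(p, 0), 1)
}

#' Beta-binomial probability mass function
#'
#' `P(X = n | K, alpha, beta) = C(K,n) B(n+alpha, K-n+beta) / B(alpha,beta)`.
#'
#' @param n count(s) in `0..K`.
#' @param params a [betabinom_params()].
#' @return probability vector, summing to 1 over `n = 0..K`.
#' @export
betabinom_pmf <- function(n, params) {
  stopifnot(inherits(params, "betabinom_params"))
  if (params$degenerate) stop("degenerate null has no beta-binomial pmf")
  if (params$alpha <= 0 || params$beta <= 0)
    stop("alpha and beta must be positive")
  if (any(n < 0 | n > params$K)) stop("n must be in 0..K")
  .bb_pmf(n, params$K, params$alpha, params$beta)
}

#' Fit a beta-binomial to a null count vector by method of moments
#'
#' With sample mean `m` and variance `v`, solves `m = K a/(a+b)` and the
#' beta-binomial variance identity
#' `v = K p (1-p) (1 + (K-1)/(a+b+1))`, `p = m/K`, for `(a, b)`. When the
#' vector shows no overdispersion (`v` at or below the binomial variance),
#' the fit falls back to a binomial-matching limit: `a + b = 1e6` at the
#' observed mean. An all-constant vector is flagged degenerate (point mass);
#' the pair's p-value is then 1 when the observation does not exceed the
#' mass point and the machine floor otherwise.
#'
#' @param null_counts integer vector of null co-regulation counts
#'   (length >= 2).
#' @param K number of contrasts.
#' @return a [betabinom_params()].
#' @export
fit_betabinom <- function(null_counts, K) {
  stopifnot(length(null_counts) >= 2L, K >= 1)
  if (any(null_counts < 0 | null_counts > K))
    stop("null counts must lie in 0..K")
  f <- .fit_bb_moments(mean(null_counts), var(null_counts), K)
  betabinom_params(f$alpha, f$beta, K, degenerate = f$degenerate,
                   point_mass = f$point_mass)
}

# moment fit shared by the scalar and the per-pair vectorised paths;
# m, v may be vectors. Returns alpha, beta, degenerate, point_mass vectors.
.fit_bb_moments <- function(m, v, K, scale_cap = 1e6) {
  p <- m / K
  degen <- v == 0 & (m == 0 | m == K)
  point <- ifelse(degen, m, NA_real_)
  alpha <- beta <- rep(NA_real_, length(m))
  ok <- !degen
  if (any(ok)) {
    pk <- p[ok]
    vb <- K * pk * (1 - pk)                       # binomial variance
    rho <- (v[ok] / vb - 1) / max(K - 1, 1)       # intra-class correlation
    s <- ifelse(is.finite(rho) & rho > 0,
                pmax(1 / pmin(rho, 1 - 1e-12) - 1, 1e-8),
                scale_cap)
    alpha[ok] <- pk * s
    beta[ok] <- (1 - pk) * s
  }
  list(alpha = alpha, beta = beta, degenerate = degen, point_mass = point)
}

#' Upper-tail p-value of an observed co-regulation count
#'
#' Inclusive upper tail `P(X >= n_observed)` under the fitted beta-binomial
#' null; for a degenerate (point-mass) fit, 1 when `n_observed` does not
#' exceed the mass point and the machine floor otherwise.
#'
#' @param n_observed observed count in `0..K`.
#' @param params a [betabinom_params()].
#' @return p-value in `[0, 1]`.
#' @export
pair_pvalue <- function(n_observed, params) {
  stopifnot(inherits(params, "betabinom_params"))
  if (any(n_observed < 0 | n_observed > params$K))
    stop("n_observed must be in 0..K")
  if (params$degenerate)
    return(ifelse(n_observed <= params$point_mass, 1,
                  .Machine$double.xmin))
  .bb_upper_tail(n_observed, params$K, params$alpha, params$beta)
}

#' Benjamini-Hochberg FDR for a pair-statistics table
#'
#' Adds an `fdr` column. `m` is the size of the hypothesis family; the
#' default is the number of rows, but when the table was filtered by a
#' minimum observed count the family of all gene pairs should be passed
#' (filtered-out pairs count as non-rejections), as [coreg_pair_stats()]
#' does.
#'
#' @param pair_stats data frame with a `p_value` column.
#' @param m hypothesis family size (default `nrow(pair_stats)`).
#' @return `pair_stats` with an `fdr` column.
#' @export
compute_fdr <- function(pair_stats, m = nrow(pair_stats)) {
  if (nrow(pair_stats) == 0L) {
    pair_stats$fdr <- numeric(0L)
    return(pair_stats)
  }
  pair_stats$fdr <- p.adjust(pair_stats$p_value, method = "BH",
                             n = max(m, nrow(pair_stats)))
  pair_stats
}

#' Full per-pair co-regulation statistics
#'
#' Runs the complete statistical stage: observed co-regulation counts, the
#' fixed-margin null ensemble, a per-pair beta-binomial moment fit, inclusive
#' upper-tail p-values and BH FDR. The FDR family defaults to all
#' `choose(G, 2)` gene pairs, so pairs excluded by `min_obs` are treated as
#' non-rejections rather than silently shrinking the family.
#'
#' @param binary,signed DEG matrices from [build_deg_matrices()].
#' @param n_samplings fixed-margin samplings (default 1000).
#' @param seed master seed for the null ensemble.
#' @param min_obs minimum observed co-regulation count (default 2).
#' @param n_swaps curveball trades per sampling (default 5 x nonzeros).
#' @param m_total FDR family size; default `choose(nrow(binary), 2)`.
#' @return data frame with columns `gene_i`, `gene_j`, `n`, `n_discordant`,
#'   `K`, `alpha`, `beta`, `p_value`, `fdr`.
#' @export
coreg_pair_stats <- function(binary, signed, n_samplings = 1000L, seed = 1L,
                             min_obs = 2L, n_swaps = NULL, m_total = NULL) {
  pairs <- count_coregulation(binary, signed, min_obs = min_obs)
  if (is.null(m_total)) m_total <- choose(nrow(binary), 2)
  if (nrow(pairs) == 0L) {
    pairs$alpha <- pairs$beta <- pairs$p_value <- pairs$fdr <- numeric(0L)
    return(pairs)
  }
  ens <- build_null_ensemble(binary, n_samplings = n_samplings, seed = seed,
                             pairs = pairs[, c("gene_i", "gene_j")],
                             n_swaps = n_swaps)
  K <- ens$K
  mm <- rowMeans(ens$counts)
  vv <- apply(ens$counts, 1L, var)
  fit <- .fit_bb_moments(mm, vv, K)

  p <- rep(NA_real_, nrow(pairs))
  dg <- fit$degenerate
  if (any(dg))
    p[dg] <- ifelse(pairs$n[dg] <= fit$point_mass[dg], 1,
                    .Machine$double.xmin)
  if (any(!dg))
    p[!dg] <- .bb_upper_tail(pairs$n[!dg], K, fit$alpha[!dg], fit$beta[!dg])

  pairs$alpha <- fit$alpha
  pairs$beta <- fit$beta
  pairs$p_value <- p
  compute_fdr(pairs, m = m_total)
}

#' Write a pair-statistics table to TSV
#'
#' @param pair_stats data frame from [coreg_pair_stats()].
#' @param path output file.
#' @export
write_pair_stats <- function(pair_stats, path) {
  write.table(pair_stats, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
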