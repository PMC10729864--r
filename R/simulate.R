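#' Simulation configuration for synthetic contrast sets
#'
#' Describes the heterogeneous multi-study setting the generator emulates:
#' many contrasts, each a small two-group comparison, with background genes
#' perturbed independently and planted gene pairs perturbed jointly.
#'
#' Planted pair types:
#' \describe{
#'   \item{concordant}{joint DEG events always share the sign.}
#'   \item{discordant}{joint events always have opposite signs.}
#'   \item{mixed}{same sign with probability 1/2 per joint event — the
#'     non-linear pattern.}
#'   \item{simpson}{discordant within every contrast, with a shared baseline
#'     drift along the contrast index so that pooled expression correlates
#'     positively — Simpson's-paradox geometry.}
#' }
#'
#' Defaults emulate the public-repository regime the method targets: K = 100
#' contrasts with 5 samples per group, a 5% background DEG rate, and effects
#' (3 log2 units against within-group noise sd 0.5) large enough that the
#' default DE caller has essentially complete per-gene power, making the DEG
#' truth table deterministic in practice.
#'
#' @param n_genes number of genes (default 200).
#' @param n_contrasts number of contrasts K (default 100).
#' @param samples_per_group samples in each of the two groups (default 5).
#' @param background_deg_rate per-gene per-contrast DEG probability for
#'   unplanted genes (default 0.05).
#' @param planted_pairs data frame with columns `type` (one of
#'   `"concordant"`, `"discordant"`, `"mixed"`, `"simpson"`) and
#'   `co_deg_rate`; pair p occupies genes `2p-1` and `2p`. May be empty.
#' @param effect_size_log2fc log2 fold change of a DEG (default 3).
#' @param noise_sd within-group expression sd on log2 scale (default 0.5).
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression.
#' @param simpson_drift total baseline drift (log2 units) across the
#'   contrast axis for simpson pairs; default `5 * effect_size_log2fc`.
#' @param seed fixes all randomness.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, n_contrasts = 100L,
                              samples_per_group = 5L,
                              background_deg_rate = 0.05,
                              planted_pairs = NULL,
                              effect_size_log2fc = 3, noise_sd = 0.5,
                              baseline_mean = 7, baseline_sd = 1,
                              simpson_drift = NULL, seed = 1L) {
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(type = character(0L),
                                co_deg_rate = numeric(0L))
  planted_pairs <- as.data.frame(planted_pairs)
  stopifnot(background_deg_rate >= 0, background_deg_rate <= 1,
            effect_size_log2fc > 0, noise_sd > 0,
            samples_per_group >= 2L, n_contrasts >= 1L,
            all(planted_pairs$co_deg_rate >= 0),
            all(planted_pairs$co_deg_rate <= 1),
            all(planted_pairs$type %in%
                  c("concordant", "discordant", "mixed", "simpson")),
            2L * nrow(planted_pairs) <= n_genes)
  if (is.null(simpson_drift)) simpson_drift <- 5 * effect_size_log2fc
  structure(list(n_genes = as.integer(n_genes),
                 n_contrasts = as.integer(n_contrasts),
                 samples_per_group = as.integer(samples_per_group),
                 background_deg_rate = background_deg_rate,
                 planted_pairs = planted_pairs,
                 effect_size_log2fc = effect_size_log2fc,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, simpson_drift = simpson_drift,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a set of heterogeneous two-group contrasts with planted truth
#'
#' Background genes are DEGs independently per contrast with probability
#' `background_deg_rate` and random sign. Each planted pair is jointly DEG
#' with probability `co_deg_rate` per contrast, with signs set by its type;
#' outside joint events its genes fall back to the background rate.
#' Expression is Gaussian on log2 scale: group means separated by
#' `effect_size_log2fc` where a gene is a DEG, within-group sd `noise_sd`.
#' Simpson pairs additionally drift along the contrast index.
#'
#' @param config a [simulation_config()].
#' @return list with `contrasts` (list of [contrast_set()]) and `truth`
#'   (list: `sign_truth` genes x contrasts \{-1,0,1\} matrix, `pairs` data
#'   frame with planted pair bookkeeping, `config`).
#' @export
simulate_contrast_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$n_genes; K <- config$n_contrasts
  spg <- config$samples_per_group
  genes <- sprintf("G%04d", seq_len(G))
  cids <- sprintf("C%03d", seq_len(K))
  pp <- config$planted_pairs
  n_pp <- nrow(pp)
  planted_idx <- if (n_pp) lapply(seq_len(n_pp),
                                  function(p) c(2L * p - 1L, 2L * p))
                 else list()
  is_planted <- rep(FALSE, G)
  for (ix in planted_idx) is_planted[ix] <- TRUE

  S <- matrix(0L, G, K, dimnames = list(genes, cids))
  joint <- matrix(FALSE, max(n_pp, 1L), K)
  for (k in seq_len(K)) {
    bg <- !is_planted & runif(G) < config$background_deg_rate
    S[bg, k] <- sample(c(-1L, 1L), sum(bg), replace = TRUE)
    for (p in seq_len(n_pp)) {
      ix <- planted_idx[[p]]
      if (runif(1L) < pp$co_deg_rate[p]) {
        joint[p, k] <- TRUE
        s1 <- sample(c(-1L, 1L), 1L)
        s2 <- switch(pp$type[p],
                     concordant = s1,
                     discordant = -s1,
                     simpson = -s1,
                     mixed = s1 * sample(c(-1L, 1L), 1L))
        S[ix[1L], k] <- s1
        S[ix[2L], k] <- s2
      } else {
        for (g in ix) {
          if (runif(1L) < config$background_deg_rate)
            S[g, k] <- sample(c(-1L, 1L), 1L)
        }
      }
    }
  }

  base <- rnorm(G, config$baseline_mean, config$baseline_sd)
  drift_gene <- rep(0, G)
  for (p in seq_len(n_pp))
    if (pp$type[p] == "simpson") drift_gene[planted_idx[[p]]] <- 1
  drift_frac <- if (K > 1L) (seq_len(K) - 1L) / (K - 1L) else rep(0, 1L)

  ns <- 2L * spg
  labels <- c(rep(0L, spg), rep(1L, spg))
  contrasts <- vector("list", K)
  for (k in seq_len(K)) {
    centre <- base + drift_gene * config$simpson_drift * drift_frac[k]
    mu <- matrix(centre, G, ns)
    shift <- S[, k] * config$effect_size_log2fc
    mu[, labels == 1L] <- mu[, labels == 1L] + shift
    x <- mu + matrix(rnorm(G * ns, 0, config$noise_sd), G, ns)
    dimnames(x) <- list(genes, sprintf("%s_s%02d", cids[k], seq_len(ns)))
    contrasts[[k]] <- contrast_set(cids[k], x, labels)
  }

  pair_truth <- if (n_pp) {
    data.frame(
      gene_i = genes[vapply(planted_idx, `[`, integer(1L), 1L)],
      gene_j = genes[vapply(planted_idx, `[`, integer(1L), 2L)],
      type = pp$type,
      co_deg_rate = pp$co_deg_rate,
      n_planted = rowSums(joint[seq_len(n_pp), , drop = FALSE]),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_i = character(0L), gene_j = character(0L),
               type = character(0L), co_deg_rate = numeric(0L),
               n_planted = integer(0L))
  }
  list(contrasts = contrasts,
       truth = list(sign_truth = S, pairs = pair_truth, config = config))
}

#' Simulate a Simpson's-paradox gene-pair geometry
#'
#' Contrast c is centred at `(c * between_trend, c * between_trend)`;
#' within a contrast, points follow `y = within_slope * x` around the centre
#' plus noise. With a negative within-slope and positive between-trend the
#' construction gives negative within-contrast correlations and a positive
#' pooled correlation in expectation.
#'
#' @param n_contrasts number of contrasts (default 5).
#' @param samples_per_contrast points per contrast (default 20).
#' @param within_slope within-contrast slope (default -1; sign must oppose
#'   `between_trend` for a paradox).
#' @param between_trend spacing of contrast centres (default 3).
#' @param noise_sd residual sd around the within-contrast line (default
#'   0.3).
#' @param seed RNG seed.
#' @return data frame with columns `contrast_id`, `x`, `y`.
#' @export
simulate_simpson_pair <- function(n_contrasts = 5L,
                                  samples_per_contrast = 20L,
                                  within_slope = -1, between_trend = 3,
                                  noise_sd = 0.3, seed = 1L) {
  stopifnot(n_contrasts >= 1L, samples_per_contrast >= 3L, noise_sd > 0)
  set.seed(seed)
  # expected pooled covariance: between-centre variance + within slope term
  vc <- between_trend^2 * var(seq_len(n_contrasts))
  if (within_slope < 0 && between_trend != 0 && vc + within_slope <= 0)
    warning("noise/trend balance gives no expected paradox: ",
            "expected pooled covariance ", signif(vc + within_slope, 3),
            " shares the within-slope sign (signal-to-noise too low)")
  out <- do.call(rbind, lapply(seq_len(n_contrasts), function(cc) {
    u <- rnorm(samples_per_contrast)
    centre <- cc * between_trend
    data.frame(contrast_id = sprintf("C%03d", cc),
               x = centre + u,
               y = centre + within_slope * u +
                 rnorm(samples_per_contrast, 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a pair table with a planted power-law subgraph
#'
#' Fixture for the scale-free cutoff scan: edges of a power-law
#' (configuration-model) graph are injected at `signal_fdr` and
#' Erdos-Renyi noise edges at `noise_fdr`, so a threshold between the two
#' isolates the scale-free subgraph.
#'
#' @param n_nodes nodes in the power-law graph (default 2000).
#' @param exponent power-law degree exponent (default 2.5).
#' @param n_noise_edges Erdos-Renyi noise edges (default `2 * n_nodes`).
#' @param signal_fdr fdr attached to power-law edges (default 1e-4).
#' @param noise_fdr fdr attached to noise edges (default 0.2).
#' @param seed RNG seed.
#' @return data frame `gene_i`, `gene_j`, `fdr`.
#' @export
simulate_powerlaw_pairs <- function(n_nodes = 2000L, exponent = 2.5,
                                    n_noise_edges = 2L * n_nodes,
                                    signal_fdr = 1e-4, noise_fdr = 0.2,
                                    seed = 1L) {
  set.seed(seed)
  # discrete power law by inverse transform, capped to keep the sequence
  # graphical
  deg <- pmin(floor(runif(n_nodes)^(-1 / (exponent - 1))),
              floor(sqrt(n_nodes)))
  if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
  g <- tryCatch(
    igraph::sample_degseq(deg, method = "vl"),
    error = function(e)
      igraph::simplify(igraph::sample_degseq(deg, method = "configuration")))
  nodes <- sprintf("N%05d", seq_len(n_nodes))
  el <- igraph::as_edgelist(g, names = FALSE)
  signal <- data.frame(gene_i = nodes[el[, 1L]], gene_j = nodes[el[, 2L]],
                       fdr = signal_fdr, stringsAsFactors = FALSE)
  out <- signal
  if (n_noise_edges > 0L) {
    gn <- igraph::sample_gnm(n_nodes, n_noise_edges)
    eln <- igraph::as_edgelist(gn, names = FALSE)
    noise <- data.frame(gene_i = nodes[eln[, 1L]],
                        gene_j = nodes[eln[, 2L]],
                        fdr = noise_fdr, stringsAsFactors = FALSE)
    out <- rbind(signal, noise)
  }
  # canonical order, drop noise duplicates of signal edges
  swap <- out$gene_i > out$gene_j
  tmp <- out$gene_i[swap]
  out$gene_i[swap] <- out$gene_j[swap]
  out$gene_j[swap] <- tmp
  out[!duplicated(out[, c("gene_i", "gene_j")]), , drop = FALSE]
}

#' Write a simulated contrast set to disk
#'
#' One expression TSV per contrast plus a design TSV and the truth tables,
#' in the layout read back by [read_expression_contrasts()].
#'
#' @param sim result of [simulate_contrast_set()].
#' @param dir output directory (created if missing).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- do.call(rbind, lapply(sim$contrasts, function(cs) {
    data.frame(sample = colnames(cs$expression),
               contrast_id = cs$contrast_id,
               group = cs$group_labels, stringsAsFactors = FALSE)
  }))
  write.table(design, file.path(dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cs in sim$contrasts) {
    df <- data.frame(gene = rownames(cs$expression), cs$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, file.path(dir, paste0(cs$contrast_id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_deg_matrix(sim$truth$sign_truth,
                   file.path(dir, "truth_signs.tsv"))
  write.table(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
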