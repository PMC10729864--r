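#' Build a co-regulation network at an FDR cutoff
#'
#' Undirected graph whose edges are the pairs with `fdr <= fdr_cutoff`; edge
#' attributes carry `fdr`, `n` and, when present, `nonlinear_score`.
#'
#' @param pair_stats data frame with `gene_i`, `gene_j`, `fdr` (and
#'   optionally `n`, `nonlinear_score`).
#' @param fdr_cutoff edge inclusion threshold.
#' @return an [igraph::igraph] object with graph attribute `fdr_cutoff`.
#' @export
build_coreg_network <- function(pair_stats, fdr_cutoff) {
  keep <- pair_stats$fdr <= fdr_cutoff
  edges <- pair_stats[keep, , drop = FALSE]
  attrs <- intersect(c("fdr", "n", "nonlinear_score", "n_discordant"),
                     names(edges))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_i", "gene_j", attrs), drop = FALSE],
    directed = FALSE)
  igraph::graph_attr(g, "fdr_cutoff") <- fdr_cutoff
  g
}

#' Scale-free topology fit of a degree sequence
#'
#' Logarithmically bins the degrees (powers of 2), regresses
#' `log10(frequency density)` on `log10(bin centre)` and reports the R
#' squared and slope. A power-law degree distribution gives a straight line
#' with negative slope; Poisson (random-graph) degrees fit poorly.
#'
#' @param degrees integer vector of node degrees.
#' @return list with `r_squared`, `slope`, `n_bins` (`NA`s when fewer than 3
#'   occupied bins).
#' @export
scale_free_fit <- function(degrees) {
  d <- degrees[degrees > 0]
  if (length(d) == 0L)
    return(list(r_squared = NA_real_, slope = NA_real_, n_bins = 0L))
  breaks <- 2^(0:(ceiling(log2(max(d))) + 1L))
  bin <- findInterval(d, breaks)
  cnt <- tabulate(bin, nbins = length(breaks) - 1L)
  lo <- breaks[-length(breaks)]; hi <- breaks[-1L]
  keep <- cnt > 0
  if (sum(keep) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_,
                n_bins = sum(keep)))
  dens <- cnt[keep] / (hi[keep] - lo[keep])
  centre <- sqrt(lo[keep] * hi[keep])
  fit <- lm(log10(dens) ~ log10(centre))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2L]),
       n_bins = sum(keep))
}

#' Choose the FDR cutoff that yields a scale-free network
#'
#' For each candidate threshold, builds the network of pairs with
#' `fdr <= candidate` and measures the scale-free topology fit of its degree
#' distribution ([scale_free_fit()]). Returns the candidate with the highest
#' R squared among those with a negative slope; ties break toward the
#' stricter (smaller) cutoff. Candidates yielding fewer than 10 nodes are
#' skipped.
#'
#' @param pair_stats data frame with `gene_i`, `gene_j`, `fdr`.
#' @param candidate_fdrs numeric vector of thresholds to scan.
#' @return list with `fdr_cutoff` and `fit_report` (data frame: `candidate`,
#'   `n_nodes`, `n_edges`, `r_squared`, `slope`).
#' @export
select_scale_free_cutoff <- function(pair_stats, candidate_fdrs) {
  stopifnot(length(candidate_fdrs) >= 1L)
  cand <- sort(unique(candidate_fdrs))
  rows <- lapply(cand, function(f) {
    g <- build_coreg_network(pair_stats, f)
    nn <- igraph::vcount(g)
    if (nn < 10L)
      return(data.frame(candidate = f, n_nodes = nn,
                        n_edges = igraph::ecount(g),
                        r_squared = NA_real_, slope = NA_real_))
    sf <- scale_free_fit(igraph::degree(g))
    data.frame(candidate = f, n_nodes = nn, n_edges = igraph::ecount(g),
               r_squared = sf$r_squared, slope = sf$slope)
  })
  report <- do.call(rbind, rows)
  ok <- !is.na(report$r_squared) & !is.na(report$slope) & report$slope < 0
  if (!any(ok)) {
    if (all(report$n_nodes < 10L))
      stop("insufficient network: every candidate cutoff yields < 10 nodes")
    stop("no candidate cutoff gives a decreasing degree distribution fit")
  }
  best_r2 <- max(report$r_squared[ok])
  # ties toward the stricter (smaller) cutoff
  best <- which(ok & report$r_squared >= best_r2 - 1e-12)[1L]
  list(fdr_cutoff = report$candidate[best], fit_report = report)
}

#' Detect network modules by recursive Louvain
#'
#' Louvain community detection; any module larger than `max_module_size` is
#' re-partitioned on its induced subgraph, recursively, until no module
#' exceeds the bound or a subgraph no longer splits. Modules smaller than
#' `min_module_size` are labelled unassigned (module id 0).
#'
#' @param network an [igraph::igraph] object.
#' @param min_module_size smallest reported module (default 3).
#' @param max_module_size recursion bound (default 1000).
#' @param seed RNG seed; fixes the (stochastic) Louvain result.
#' @return data frame `gene`, `module` (integer; 0 = unassigned), with the
#'   module size table as attribute `sizes`.
#' @export
detect_modules <- function(network, min_module_size = 3L,
                           max_module_size = 1000L, seed = 1L) {
  if (igraph::vcount(network) == 0L) {
    out <- data.frame(gene = character(0L), module = integer(0L))
    attr(out, "sizes") <- integer(0L)
    return(out)
  }
  set.seed(seed)
  memb <- igraph::membership(igraph::cluster_louvain(network))
  memb <- as.integer(factor(memb))
  names(memb) <- igraph::V(network)$name

  done <- integer(0L)   # oversized modules that refused to split further
  repeat {
    sizes <- table(memb)
    big <- setdiff(as.integer(names(sizes)[sizes > max_module_size]), done)
    if (length(big) == 0L) break
    for (mod in big) {
      nodes <- names(memb)[memb == mod]
      sub <- igraph::induced_subgraph(network, nodes)
      sm <- igraph::membership(igraph::cluster_louvain(sub))
      if (length(unique(sm)) > 1L) {
        memb[names(sm)] <- max(memb) + as.integer(factor(sm))
      } else {
        done <- c(done, mod)
      }
    }
  }
  memb <- as.integer(factor(memb))
  names(memb) <- igraph::V(network)$name
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  memb[memb %in% small] <- 0L
  keep <- memb != 0L
  memb[keep] <- as.integer(factor(memb[keep]))
  out <- data.frame(gene = names(memb), module = unname(memb),
                    stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(out$module[out$module != 0L])
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set name, description, member
#'   genes).
#' @return named list, term -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

#' Invert a term -> genes map into a gene -> terms annotation map
#'
#' @param gmt named list from [read_gmt()].
#' @return named list, gene -> character vector of term identifiers.
#' @export
annotation_map <- function(gmt) {
  gene <- unlist(gmt, use.names = FALSE)
  term <- rep(names(gmt), lengths(gmt))
  split(term, gene)
}

#' Annotation interaction density of a network
#'
#' Fraction of edges whose endpoint genes share at least one annotation
#' term, among edges with both endpoints annotated.
#'
#' @param network an [igraph::igraph] object.
#' @param annotation gene -> terms map ([annotation_map()]).
#' @return density in `[0, 1]`.
#' @export
annotation_interaction_density <- function(network, annotation) {
  el <- igraph::as_edgelist(network)
  if (nrow(el) == 0L) stop("undefined density: network has no edges")
  ti <- annotation[el[, 1L]]
  tj <- annotation[el[, 2L]]
  both <- !vapply(ti, is.null, logical(1L)) &
    !vapply(tj, is.null, logical(1L))
  if (!any(both))
    stop("undefined density: no edge has both endpoints annotated")
  shared <- mapply(function(a, b) length(intersect(a, b)) > 0L,
                   ti[both], tj[both])
  sum(shared) / sum(both)
}

#' Compare interaction density against random networks
#'
#' Null networks are Erdos-Renyi graphs on the same node set with the same
#' edge count (same genes, same interaction density); a degree-preserving
#' rewiring null is available for sensitivity analysis. The empirical
#' p-value is `(1 + #{null >= observed}) / (1 + n_random)`.
#'
#' @param network an [igraph::igraph] object.
#' @param annotation gene -> terms map.
#' @param n_random number of null networks (default 100, minimum 10).
#' @param seed RNG seed.
#' @param null one of `"gnm"` (default; same nodes and edge count) or
#'   `"rewire"` (degree-preserving edge switching).
#' @return list with `observed`, `null_densities`, `p_value`.
#' @export
density_null_test <- function(network, annotation, n_random = 100L,
                              seed = 1L, null = c("gnm", "rewire")) {
  null <- match.arg(null)
  stopifnot(n_random >= 10L)
  observed <- annotation_interaction_density(network, annotation)
  set.seed(seed)
  nn <- igraph::vcount(network); ne <- igraph::ecount(network)
  nulls <- vapply(seq_len(n_random), function(i) {
    g0 <- if (null == "gnm") {
      g <- igraph::sample_gnm(nn, ne)
      igraph::V(g)$name <- igraph::V(network)$name
      g
    } else {
      igraph::rewire(network,
                     igraph::keeping_degseq(niter = 10L * ne))
    }
    annotation_interaction_density(g0, annotation)
  }, numeric(1L))
  list(observed = observed, null_densities = nulls,
       p_value = (1 + sum(nulls >= observed)) / (1 + n_random))
}

#' Export a network as edge-list TSV or GraphML
#'
#' @param network an [igraph::igraph] object.
#' @param path output file.
#' @param format `"tsv"` (edge list with attributes) or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(network, what = "edges")
    names(df)[1:2] <- c("gene_i", "gene_j")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a module partition to TSV
#'
#' @param partition data frame from [detect_modules()].
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  write.table(partition, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
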