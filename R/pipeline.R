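#' Run the full co-regulation pipeline on DEG matrices
#'
#' Convenience wrapper chaining [coreg_pair_stats()],
#' [annotate_nonlinearity()], [select_scale_free_cutoff()],
#' [build_coreg_network()] and [detect_modules()].
#'
#' @param binary,signed DEG matrices (from [build_deg_matrices()] or
#'   [read_deg_matrix()]).
#' @param n_samplings fixed-margin samplings for the null (default 1000).
#' @param seed master seed.
#' @param min_obs minimum observed co-regulation count (default 2).
#' @param fdr_scan candidate FDR cutoffs for the scale-free scan (default
#'   `10^-(1:4)`).
#' @param score_cutoff non-linear category threshold (default 0.5).
#' @param min_module_size,max_module_size module detection bounds.
#' @return list with `pair_stats`, `fdr_cutoff`, `fit_report` (`NULL` when
#'   the scan could not run and the most permissive candidate was used),
#'   `network`, `modules`.
#' @export
coregnet_run <- function(binary, signed, n_samplings = 1000L, seed = 1L,
                         min_obs = 2L, fdr_scan = 10^-(1:4),
                         score_cutoff = 0.5, min_module_size = 3L,
                         max_module_size = 1000L) {
  stats <- coreg_pair_stats(binary, signed, n_samplings = n_samplings,
                            seed = seed, min_obs = min_obs)
  stats <- annotate_nonlinearity(stats, score_cutoff = score_cutoff)
  scan <- tryCatch(select_scale_free_cutoff(stats, fdr_scan),
                   error = function(e) {
                     warning("scale-free scan failed (", conditionMessage(e),
                             "); falling back to the most permissive ",
                             "candidate cutoff", call. = FALSE)
                     list(fdr_cutoff = max(fdr_scan), fit_report = NULL)
                   })
  network <- build_coreg_network(stats, scan$fdr_cutoff)
  modules <- detect_modules(network, min_module_size = min_module_size,
                            max_module_size = max_module_size, seed = seed)
  list(pair_stats = stats, fdr_cutoff = scan$fdr_cutoff,
       fit_report = scan$fit_report, network = network, modules = modules)
}
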